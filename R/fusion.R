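# Feature-level fusion of the two cepstral views: plain concatenation and
# canonical correlation analysis (CCA) producing canonical correlation
# discriminant features (CCDFs).
#
# Convention: feature matrices are p x n / q x n with COLUMNS as episodes,
# the standard orientation for the CCA covariance blocks.

#' Row-stack two aligned feature sets
#'
#' @param x p x n matrix (columns are episodes).
#' @param y q x n matrix over the same episodes.
#' @return (p + q) x n matrix, `x` rows first.
#' @export
concat_features <- function(x, y) {
  if (ncol(x) != ncol(y))
    stop("feature sets must cover the same episodes (equal n)", call. = FALSE)
  rbind(x, y)
}

#' Fit a canonical correlation analysis transform
#'
#' Column-centres both views, forms the covariance blocks Sxx, Sxy, Syx, Syy
#' (with a trace-scaled ridge added to the diagonals of Sxx and Syy for
#' stability), and solves the whitened cross-covariance SVD for projection
#' pairs `Wx`, `Wy` that maximize the correlation of successive, mutually
#' uncorrelated projections. Projections have unit sample variance. Each
#' canonical pair is oriented so that the first nonzero element of the `Wx`
#' column is positive, for reproducibility across linear-algebra backends.
#'
#' The transform is meant to be fitted on training episodes only and then
#' frozen; [cca_fuse()] re-applies the fit-time centring offsets.
#'
#' @param x p x n matrix (first view, e.g. GFCC; columns are episodes).
#' @param y q x n matrix (second view, e.g. MFCC).
#' @param d number of retained canonical pairs (<= min(p, q)). The default
#'   retains up to 30 pairs so that the fused width is 60 for two 39-dim
#'   views.
#' @param ridge ridge coefficient; the diagonal of each within-view
#'   covariance is inflated by `ridge * mean(diag(S))`. Set 0 to disable
#'   (rank-deficient inputs then raise an error).
#' @return an object of class `cca_transform` with `Wx` (p x d), `Wy`
#'   (q x d), `correlations` (length d, non-increasing, in [0, 1]), centring
#'   offsets, and `d`.
#' @export
cca_fit <- function(x, y, d = NULL, ridge = 1e-6) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- ncol(x)
  if (ncol(y) != n) stop("x and y must have the same number of columns", call. = FALSE)
  if (n < 2) stop("CCA needs at least 2 samples", call. = FALSE)
  p <- nrow(x); q <- nrow(y)
  d <- d %||% min(30L, p, q)
  if (d < 1 || d > min(p, q))
    stop("`d` must be between 1 and min(p, q)", call. = FALSE)
  assert_scalar_num(ridge, "ridge", lo = 0)

  mx <- rowMeans(x); my <- rowMeans(y)
  xc <- x - mx; yc <- y - my
  Sxx <- tcrossprod(xc) / (n - 1)
  Syy <- tcrossprod(yc) / (n - 1)
  Sxy <- tcrossprod(xc, yc) / (n - 1)
  if (ridge > 0) {
    diag(Sxx) <- diag(Sxx) + ridge * mean(diag(Sxx))
    diag(Syy) <- diag(Syy) + ridge * mean(diag(Syy))
  }

  isqrt <- function(S, name) {
    e <- eigen(S, symmetric = TRUE)
    tol <- max(e$values) * 1e-12
    if (min(e$values) < tol)
      stop(sprintf("covariance of %s is rank-deficient; use ridge > 0", name),
           call. = FALSE)
    e$vectors %*% (t(e$vectors) / sqrt(e$values))
  }
  isx <- isqrt(Sxx, "x"); isy <- isqrt(Syy, "y")
  sv <- svd(isx %*% Sxy %*% isy, nu = d, nv = d)
  Wx <- isx %*% sv$u
  Wy <- isy %*% sv$v
  for (k in seq_len(d)) {
    nz <- which(abs(Wx[, k]) > 1e-12)
    s <- if (length(nz)) sign(Wx[nz[1], k]) else 1
    if (s < 0) { Wx[, k] <- -Wx[, k]; Wy[, k] <- -Wy[, k] }
  }
  structure(list(Wx = Wx, Wy = Wy,
                 correlations = pmin(pmax(sv$d[seq_len(d)], 0), 1),
                 center_x = mx, center_y = my, d = d,
                 fitted_on = sprintf("n=%d p=%d q=%d", n, p, q)),
            class = "cca_transform")
}

#' @export
print.cca_transform <- function(x, ...) {
  cat(sprintf("<cca_transform> %d canonical pairs (%s); top correlations: %s\n",
              x$d, x$fitted_on,
              paste(sprintf("%.3f", utils::head(x$correlations, 4)),
                    collapse = ", ")))
  invisible(x)
}

#' Apply a fitted CCA transform: canonical correlation discriminant features
#'
#' Projects both views with the frozen transform and stacks them:
#' `Z = [Wx' (x - mx); Wy' (y - my)]`, a `2d x n` fused representation
#' (60-dim for the default d = 30 on two 39-dim views).
#'
#' @param transform a fitted [cca_fit()] result.
#' @param x,y views with the fit-time row dimensions; columns are episodes.
#' @return `2d x n` matrix of fused features.
#' @export
cca_fuse <- function(transform, x, y) {
  if (!inherits(transform, "cca_transform"))
    stop("`transform` must come from cca_fit()", call. = FALSE)
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != length(transform$center_x) ||
      nrow(y) != length(transform$center_y))
    stop("view dimensions do not match the fitted transform", call. = FALSE)
  if (ncol(x) != ncol(y)) stop("x and y must have equal n", call. = FALSE)
  rbind(crossprod(transform$Wx, x - transform$center_x),
        crossprod(transform$Wy, y - transform$center_y))
}

#' Serialize a CCA transform to JSON
#'
#' @param transform a `cca_transform`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cca_json <- function(transform, path) {
  obj <- list(Wx = transform$Wx, Wy = transform$Wy,
              correlations = transform$correlations,
              center_x = transform$center_x, center_y = transform$center_y,
              d = transform$d, fitted_on = transform$fitted_on)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a CCA transform back from JSON
#' @param path JSON path written by [write_cca_json()].
#' @return a `cca_transform`.
#' @export
read_cca_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(Wx = as.matrix(obj$Wx), Wy = as.matrix(obj$Wy),
                 correlations = as.numeric(obj$correlations),
                 center_x = as.numeric(obj$center_x),
                 center_y = as.numeric(obj$center_y),
                 d = as.integer(obj$d), fitted_on = obj$fitted_on),
            class = "cca_transform")
}
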