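# Hyperparameter optimization: exhaustive grid search, i.i.d. random search,
# and Bayesian optimization with a Gaussian-process surrogate and
# expected-improvement acquisition. The objective is always MAXIMIZED
# (validation accuracy); all three methods share the trial/result bookkeeping.

#' Continuous search-space parameter
#'
#' @param name parameter name.
#' @param lo,hi bounds (lo < hi; log scale requires lo > 0).
#' @param scale `"linear"` or `"log"`.
#' @return a parameter descriptor.
#' @export
param_continuous <- function(name, lo, hi, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (!(lo < hi)) stop("`lo` must be < `hi`", call. = FALSE)
  if (scale == "log" && lo <= 0)
    stop("log scale requires lo > 0", call. = FALSE)
  list(name = name, type = "continuous", lo = lo, hi = hi, scale = scale)
}

#' Integer search-space parameter
#' @inheritParams param_continuous
#' @export
param_integer <- function(name, lo, hi) {
  if (!(lo < hi)) stop("`lo` must be < `hi`", call. = FALSE)
  list(name = name, type = "integer", lo = as.integer(lo), hi = as.integer(hi))
}

#' Categorical search-space parameter
#' @param name parameter name.
#' @param values vector of admissible values.
#' @export
param_categorical <- function(name, values) {
  if (length(values) < 2) stop("need at least two categories", call. = FALSE)
  list(name = name, type = "categorical", values = values)
}

#' Assemble a search space
#' @param ... parameter descriptors from [param_continuous()],
#'   [param_integer()], [param_categorical()].
#' @return an object of class `search_space`.
#' @export
search_space <- function(...) {
  params <- list(...)
  nm <- vapply(params, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate parameter names", call. = FALSE)
  names(params) <- nm
  structure(params, class = "search_space")
}

# unit-cube <-> native coordinates ------------------------------------------

space_from_unit <- function(space, u) {
  cfg <- list()
  for (j in seq_along(space)) {
    p <- space[[j]]; uj <- min(max(u[j], 0), 1)
    cfg[[p$name]] <- switch(p$type,
      continuous = if (p$scale == "log")
        exp(log(p$lo) + uj * (log(p$hi) - log(p$lo)))
      else p$lo + uj * (p$hi - p$lo),
      integer = as.integer(round(p$lo + uj * (p$hi - p$lo))),
      categorical = p$values[[min(length(p$values),
                                  1L + floor(uj * length(p$values)))]]
    )
  }
  cfg
}

param_grid_values <- function(p, points) {
  switch(p$type,
    continuous = if (p$scale == "log")
      exp(seq(log(p$lo), log(p$hi), length.out = points))
    else seq(p$lo, p$hi, length.out = points),
    integer = {
      all_vals <- seq(p$lo, p$hi)
      if (length(all_vals) <= points) all_vals
      else unique(as.integer(round(seq(p$lo, p$hi, length.out = points))))
    },
    categorical = p$values
  )
}

new_hpo_result <- function(history, method, budget) {
  ok <- which(is.finite(history$objective))
  if (!length(ok)) stop("all trials failed (non-finite objective)", call. = FALSE)
  best_i <- ok[which.max(history$objective[ok])]
  structure(list(
    best_config = as.list(history[best_i,
                                  setdiff(names(history),
                                          c("index", "objective")),
                                  drop = FALSE]),
    best_objective = history$objective[best_i],
    history = history, method = method, budget = budget),
    class = "hpo_result")
}

#' @export
print.hpo_result <- function(x, ...) {
  cat(sprintf("<hpo_result> %s: %d trials, best objective %.4f\n",
              x$method, nrow(x$history), x$best_objective))
  cat("  best config:",
      paste(names(x$best_config),
            vapply(x$best_config, function(v) format(v, digits = 4),
                   character(1)),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

run_trials <- function(space, objective_fn, configs, method, budget) {
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    obj <- tryCatch(objective_fn(cfg), error = function(e) NA_real_)
    if (!is.numeric(obj) || length(obj) != 1 || !is.finite(obj))
      obj <- NA_real_
    c(list(index = i), cfg, list(objective = obj))
  })
  history <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  new_hpo_result(history, method, budget)
}

#' Exhaustive grid search
#'
#' Evaluates the full Cartesian product of per-parameter grids (log-spaced
#' where the parameter is log-scaled; small integer ranges are enumerated
#' exactly) in a fixed deterministic order and returns the exact argmax over
#' the evaluated points.
#'
#' @param space a [search_space()].
#' @param objective_fn function taking a named config list, returning a
#'   scalar objective to maximize.
#' @param points_per_dim grid resolution per parameter.
#' @param max_grid refuse grids larger than this, suggesting a coarser
#'   resolution.
#' @return an `hpo_result`.
#' @export
grid_search <- function(space, objective_fn, points_per_dim = 10,
                        max_grid = 100000) {
  stopifnot(inherits(space, "search_space"))
  vals <- lapply(space, param_grid_values, points = points_per_dim)
  total <- prod(vapply(vals, length, numeric(1)))
  if (total > max_grid)
    stop(sprintf("grid of %d points exceeds the cap (%d); use a coarser resolution",
                 total, max_grid), call. = FALSE)
  grid <- expand.grid(vals, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  configs <- lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
  run_trials(space, objective_fn, configs, "grid", nrow(grid))
}

#' Random search
#'
#' i.i.d. uniform draws on each parameter's scale (log-uniform for
#' log-scaled parameters).
#'
#' @inheritParams grid_search
#' @param n_iter number of evaluations (>= 1).
#' @param seed integer seed; a fixed seed reproduces the draw sequence.
#' @return an `hpo_result`.
#' @export
random_search <- function(space, objective_fn, n_iter, seed = 1) {
  stopifnot(inherits(space, "search_space"))
  if (n_iter < 1) stop("`n_iter` must be >= 1", call. = FALSE)
  U <- withr::with_seed(as.integer(seed),
                        matrix(runif(n_iter * length(space)), n_iter))
  configs <- lapply(seq_len(n_iter), function(i) space_from_unit(space, U[i, ]))
  run_trials(space, objective_fn, configs, "random", n_iter)
}

# Gaussian-process surrogate ------------------------------------------------

gp_fit <- function(U, y) {
  ys <- sd(y)
  if (!is.finite(ys) || ys < 1e-12) ys <- 1
  ym <- mean(y)
  z <- (y - ym) / ys
  n <- nrow(U)
  D2 <- as.matrix(stats::dist(U))^2
  best <- NULL
  for (ell in c(0.1, 0.2, 0.5, 1, 2)) {
    for (noise in c(1e-6, 1e-4, 1e-2)) {
      K <- exp(-0.5 * D2 / ell^2) + diag(noise, n)
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) next
      alpha <- backsolve(ch, forwardsolve(t(ch), z))
      mll <- -0.5 * sum(z * alpha) - sum(log(diag(ch))) - n / 2 * log(2 * pi)
      if (is.null(best) || mll > best$mll)
        best <- list(ell = ell, noise = noise, chol = ch, alpha = alpha,
                     mll = mll, U = U, ym = ym, ys = ys)
    }
  }
  best
}

gp_predict <- function(gp, Unew) {
  D2 <- outer(rowSums(Unew^2), rowSums(gp$U^2), `+`) -
    2 * Unew %*% t(gp$U)
  Ks <- exp(-0.5 * pmax(D2, 0) / gp$ell^2)
  mu <- drop(Ks %*% gp$alpha) * gp$ys + gp$ym
  v <- forwardsolve(t(gp$chol), t(Ks))
  s2 <- pmax(1 - colSums(v^2), 0)
  list(mu = mu, sd = sqrt(s2) * gp$ys)
}

expected_improvement <- function(mu, s, incumbent, xi = 0.01) {
  imp <- mu - incumbent - xi
  ei <- numeric(length(mu))
  pos <- s > 1e-12
  z <- imp[pos] / s[pos]
  ei[pos] <- imp[pos] * pnorm(z) + s[pos] * dnorm(z)
  ei[!pos] <- pmax(imp[!pos], 0)
  ei
}

#' Bayesian hyperparameter optimization
#'
#' Sequential model-based search: a Gaussian-process surrogate (squared-
#' exponential kernel on the unit-cube-rescaled space, length-scale and noise
#' chosen by marginal likelihood) is fitted to the completed trials, and the
#' next configuration maximizes expected improvement over a random candidate
#' set. The first `n_init` trials come from a Latin hypercube design. Exactly
#' `n_iter` evaluations are performed; a trial whose objective is non-finite
#' is recorded as failed and excluded from the surrogate. Reproducible per
#' `seed`.
#'
#' @inheritParams random_search
#' @param n_init number of initial space-filling trials.
#' @param n_candidates random candidates scored by the acquisition per
#'   iteration.
#' @return an `hpo_result`.
#' @export
bayesian_search <- function(space, objective_fn, n_iter = 30, seed = 1,
                            n_init = 5, n_candidates = 512) {
  stopifnot(inherits(space, "search_space"))
  if (n_iter < 2) stop("`n_iter` must be >= 2", call. = FALSE)
  dims <- length(space)
  n_init <- min(n_init, n_iter)

  withr::with_seed(as.integer(seed), {
    U <- lhs::randomLHS(n_init, dims)
    y <- numeric(0)
    configs <- list()
    for (i in seq_len(n_init)) {
      cfg <- space_from_unit(space, U[i, ])
      obj <- tryCatch(objective_fn(cfg), error = function(e) NA_real_)
      if (!is.numeric(obj) || length(obj) != 1 || !is.finite(obj))
        obj <- NA_real_
      configs[[i]] <- cfg
      y <- c(y, obj)
    }
    while (length(y) < n_iter) {
      ok <- is.finite(y)
      u_new <- if (sum(ok) >= 2) {
        gp <- gp_fit(U[ok, , drop = FALSE], y[ok])
        cand <- matrix(runif(n_candidates * dims), n_candidates)
        # local refinement candidates around the incumbent
        inc_u <- U[ok, , drop = FALSE][which.max(y[ok]), ]
        local <- matrix(rep(inc_u, each = 32), 32) +
          matrix(rnorm(32 * dims, 0, 0.05), 32)
        cand <- rbind(cand, pmin(pmax(local, 0), 1))
        if (is.null(gp)) cand[1, ] else {
          pr <- gp_predict(gp, cand)
          ei <- expected_improvement(pr$mu, pr$sd, max(y[ok]))
          cand[which.max(ei), ]
        }
      } else runif(dims)
      # re-sample once if the proposal duplicates an existing point
      if (nrow(U) && min(colSums((t(U) - u_new)^2)) < 1e-16)
        u_new <- runif(dims)
      cfg <- space_from_unit(space, u_new)
      obj <- tryCatch(objective_fn(cfg), error = function(e) NA_real_)
      if (!is.numeric(obj) || length(obj) != 1 || !is.finite(obj))
        obj <- NA_real_
      U <- rbind(U, u_new)
      configs[[length(configs) + 1L]] <- cfg
      y <- c(y, obj)
    }
  })

  history <- do.call(rbind, lapply(seq_along(configs), function(i)
    as.data.frame(c(list(index = i), configs[[i]],
                    list(objective = y[i])), stringsAsFactors = FALSE)))
  new_hpo_result(history, "bayesian", n_iter)
}

#' Running incumbent (best-so-far) trajectory of an HPO run
#'
#' @param result an `hpo_result`.
#' @return numeric vector of the running maximum objective; non-decreasing
#'   by construction.
#' @export
incumbent_trajectory <- function(result) {
  obj <- result$history$objective
  obj[!is.finite(obj)] <- -Inf
  cummax(obj)
}

#' Write an HPO trial history to CSV
#' @param result an `hpo_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hpo_csv <- function(result, path) {
  utils::write.csv(result$history, path, row.names = FALSE)
  invisible(path)
}
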