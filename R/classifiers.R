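# The two classification back-ends. Both expose the same train/predict
# contract (n x D feature matrix or list of T_i x D sequences, plus a factor
# of class labels), so the pipeline and HPO layers are classifier-agnostic.

#' Gaussian-kernel SVM configuration
#'
#' @param box_constraint positive soft-margin misclassification penalty.
#' @param kernel_scale positive Gaussian kernel width `s` in
#'   `k(x, x') = exp(-||x - x'||^2 / (2 s^2))`. The default `sqrt(D / 2)`
#'   (resolved at fit time) matches a unit-information kernel on standardized
#'   features.
#' @return an object of class `svm_config`.
#' @export
svm_config <- function(box_constraint = 1, kernel_scale = NULL) {
  assert_scalar_num(box_constraint, "box_constraint", lo = .Machine$double.eps)
  if (!is.null(kernel_scale))
    assert_scalar_num(kernel_scale, "kernel_scale", lo = .Machine$double.eps)
  structure(list(box_constraint = box_constraint, kernel_scale = kernel_scale),
            class = "svm_config")
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  sdev[!is.finite(sdev) | sdev < 1e-12] <- 1
  list(mu = mu, sd = sdev)
}

standardize_apply <- function(x, st) {
  sweep(sweep(x, 2L, st$mu, `-`), 2L, st$sd, `/`)
}

#' Train a Gaussian-kernel SVM
#'
#' Soft-margin SVM with kernel `exp(-||x - x'||^2 / (2 * kernel_scale^2))`.
#' Features are standardized inside the model using training-set statistics
#' only; the same statistics are applied at prediction time.
#'
#' @param x n x D feature matrix (rows are episodes).
#' @param labels factor (or coercible) of two class labels.
#' @param cfg an [svm_config()].
#' @return a `crydx_model` of kind `"svm"`.
#' @export
svm_train <- function(x, labels, cfg = svm_config()) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2)
    stop("svm_train requires exactly two classes in `labels`", call. = FALSE)
  if (nrow(x) != length(y)) stop("feature/label length mismatch", call. = FALSE)
  ks <- cfg$kernel_scale %||% sqrt(ncol(x) / 2)
  st <- standardize_fit(x)
  fit <- e1071::svm(standardize_apply(x, st), y, type = "C-classification",
                    kernel = "radial", cost = cfg$box_constraint,
                    gamma = 1 / (2 * ks^2), scale = FALSE)
  structure(list(kind = "svm", fit = fit, standardize = st,
                 config = list(box_constraint = cfg$box_constraint,
                               kernel_scale = ks),
                 levels = levels(y), dim = ncol(x)),
            class = "crydx_model")
}

#' Predict with a trained SVM
#'
#' @param model a `crydx_model` from [svm_train()].
#' @param x n x D matrix with the training dimensionality (n may be 0).
#' @return factor of predicted labels; deterministic and invariant to row
#'   order.
#' @export
svm_predict <- function(model, x) {
  stopifnot(inherits(model, "crydx_model"), model$kind == "svm")
  x <- as.matrix(x)
  if (nrow(x) == 0) return(factor(character(0), levels = model$levels))
  if (ncol(x) != model$dim)
    stop(sprintf("expected %d feature columns, got %d", model$dim, ncol(x)),
         call. = FALSE)
  predict(model$fit, standardize_apply(x, model$standardize))
}

#' LSTM configuration
#'
#' The tunable hyperparameters and their admissible ranges: initial learning
#' rate in `[0.001, 1]` (searched on a log scale), hidden units in `[2, 39]`,
#' maximum epochs in `[100, 500]`, and depth (number of stacked recurrent
#' layers) in `[1, 3]`. The recurrent activation is tanh. With
#' `strict = TRUE` (default) values outside these ranges are rejected;
#' `strict = FALSE` keeps only basic sanity checks, which permits scaled-down
#' epoch budgets in small simulation studies.
#'
#' @param hidden_units integer number of hidden units per layer.
#' @param initial_learning_rate Adam learning rate.
#' @param max_epochs integer training epochs.
#' @param depth integer number of stacked LSTM layers.
#' @param seed integer seed controlling weight init, shuffling, and the
#'   holdout split.
#' @param batch_size minibatch size.
#' @param holdout_fraction fraction of training sequences held out for
#'   validation scoring (0 disables validation).
#' @param val_every score the holdout every this many optimizer iterations.
#' @param strict enforce the admissible hyperparameter ranges.
#' @return an object of class `lstm_config`.
#' @export
lstm_config <- function(hidden_units = 10, initial_learning_rate = 0.01,
                        max_epochs = 150, depth = 1, seed = 1,
                        batch_size = 128, holdout_fraction = 0.2,
                        val_every = 10, strict = TRUE) {
  if (strict) {
    rng_err <- function(name, val, lo, hi)
      stop(sprintf("`%s` = %s outside the admissible range [%s, %s]",
                   name, format(val), format(lo), format(hi)), call. = FALSE)
    if (initial_learning_rate < 0.001 || initial_learning_rate > 1)
      rng_err("initial_learning_rate", initial_learning_rate, 0.001, 1)
    if (hidden_units < 2 || hidden_units > 39)
      rng_err("hidden_units", hidden_units, 2, 39)
    if (max_epochs < 100 || max_epochs > 500)
      rng_err("max_epochs", max_epochs, 100, 500)
    if (depth < 1 || depth > 3) rng_err("depth", depth, 1, 3)
  } else {
    assert_scalar_num(initial_learning_rate, "initial_learning_rate",
                      lo = 1e-8)
    assert_scalar_num(hidden_units, "hidden_units", lo = 1)
    assert_scalar_num(max_epochs, "max_epochs", lo = 1)
    assert_scalar_num(depth, "depth", lo = 1, hi = 10)
  }
  assert_scalar_num(holdout_fraction, "holdout_fraction", lo = 0, hi = 0.9)
  assert_scalar_num(batch_size, "batch_size", lo = 1)
  structure(list(hidden_units = as.integer(hidden_units),
                 initial_learning_rate = initial_learning_rate,
                 max_epochs = as.integer(max_epochs),
                 depth = as.integer(depth), seed = as.integer(seed),
                 batch_size = as.integer(batch_size),
                 holdout_fraction = holdout_fraction,
                 val_every = as.integer(val_every), strict = strict),
            class = "lstm_config")
}

init_lstm_weights <- function(depth, hidden, dims_in) {
  w <- list()
  din <- dims_in
  for (l in seq_len(depth)) {
    w[[paste0("W", l)]] <- matrix(runif(4 * hidden * din, -0.08, 0.08),
                                  4 * hidden, din)
    w[[paste0("U", l)]] <- matrix(runif(4 * hidden * hidden, -0.08, 0.08),
                                  4 * hidden, hidden)
    b <- rep(0, 4 * hidden)
    b[(hidden + 1):(2 * hidden)] <- 1   # forget-gate bias
    w[[paste0("b", l)]] <- b
    din <- hidden
  }
  w[["Wout"]] <- matrix(runif(2 * hidden, -0.08, 0.08), 2, hidden)
  w[["bout"]] <- rep(0, 2)
  w
}

sequences_to_cube <- function(seqs) {
  lens <- vapply(seqs, nrow, integer(1))
  D <- ncol(seqs[[1]])
  Tmax <- max(lens)
  X <- array(0, dim = c(D, Tmax, length(seqs)))
  for (j in seq_along(seqs)) X[, seq_len(lens[j]), j] <- t(seqs[[j]])
  list(cube = X, len = lens)
}

#' Train an LSTM sequence classifier
#'
#' `depth` stacked tanh LSTM layers of `hidden_units` each; the hidden state
#' at the final valid timestep feeds a dense layer with 2-way softmax, under
#' cross-entropy loss and Adam updates. A stratified `holdout_fraction` of
#' the training sequences is set aside for validation and scored every
#' `val_every` optimizer iterations. Frame features are standardized with
#' statistics computed over the supplied training frames and bundled into the
#' model. Training is reproducible: the same `(sequences, labels, cfg)`
#' yields an identical model.
#'
#' @param sequences list of T_i x D numeric matrices (one per episode).
#' @param labels factor of two class labels aligned with `sequences`.
#' @param cfg an [lstm_config()].
#' @return a `crydx_model` of kind `"lstm"` carrying the fitted weights, the
#'   validation history (`validation`: data.frame of iteration/accuracy) and
#'   the per-iteration training loss curve.
#' @export
lstm_train <- function(sequences, labels, cfg = lstm_config()) {
  if (!length(sequences)) stop("no training sequences", call. = FALSE)
  if (!inherits(cfg, "lstm_config")) stop("`cfg` must be an lstm_config", call. = FALSE)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2)
    stop("lstm_train requires exactly two classes in `labels`", call. = FALSE)
  if (length(sequences) != length(y))
    stop("sequence/label length mismatch", call. = FALSE)
  D <- ncol(sequences[[1]])

  all_frames <- do.call(rbind, sequences)
  st <- standardize_fit(all_frames)
  seqs <- lapply(sequences, standardize_apply, st = st)

  n <- length(seqs)
  withr::with_seed(cfg$seed, {
    if (cfg$holdout_fraction > 0 && n >= 5) {
      val_idx <- unlist(lapply(levels(y), function(lv) {
        members <- which(y == lv)
        k <- max(1L, round(cfg$holdout_fraction * length(members)))
        members[sample.int(length(members), k)]
      }))
    } else val_idx <- integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)

    weights <- init_lstm_weights(cfg$depth, cfg$hidden_units, D)
    perms <- vapply(seq_len(cfg$max_epochs),
                    function(e) sample(seq_along(tr_idx)) - 1L,
                    integer(length(tr_idx)))
  })

  tr <- sequences_to_cube(seqs[tr_idx])
  y_num <- as.integer(y) - 1L
  if (length(val_idx)) {
    va <- sequences_to_cube(seqs[val_idx])
    val_cube <- va$cube; val_len <- va$len; val_y <- y_num[val_idx]
  } else {
    val_cube <- array(0, dim = c(D, 1, 0)); val_len <- integer(0)
    val_y <- integer(0)
  }

  res <- .lstm_train_cpp(weights, tr$cube, tr$len, y_num[tr_idx],
                         val_cube, val_len, val_y, cfg$depth,
                         cfg$initial_learning_rate, cfg$max_epochs,
                         min(cfg$batch_size, length(tr_idx)),
                         matrix(as.integer(perms), ncol = cfg$max_epochs),
                         cfg$val_every)

  structure(list(kind = "lstm", weights = res$weights, standardize = st,
                 config = cfg, levels = levels(y), dim = D,
                 validation = data.frame(iteration = res$val_iter,
                                         accuracy = res$val_acc),
                 loss = res$loss),
            class = "crydx_model")
}

#' Predict with a trained LSTM
#'
#' Deterministic: repeated calls and batch-vs-single predictions agree. The
#' decision threshold on the softmax output is 0.5; an exact tie is resolved
#' toward the pathologic class when present, favouring sensitivity.
#'
#' @param model a `crydx_model` from [lstm_train()].
#' @param sequences list of T_i x D matrices.
#' @param type `"class"` (default) or `"prob"` (n x 2 matrix of class
#'   probabilities in level order).
#' @return factor of predicted labels, or a probability matrix.
#' @export
lstm_predict <- function(model, sequences, type = c("class", "prob")) {
  stopifnot(inherits(model, "crydx_model"), model$kind == "lstm")
  type <- match.arg(type)
  if (!length(sequences)) return(factor(character(0), levels = model$levels))
  if (ncol(sequences[[1]]) != model$dim)
    stop(sprintf("expected %d feature columns, got %d", model$dim,
                 ncol(sequences[[1]])), call. = FALSE)
  seqs <- lapply(sequences, standardize_apply, st = model$standardize)
  sc <- sequences_to_cube(seqs)
  probs <- .lstm_probs_cpp(model$weights, sc$cube, sc$len, model$config$depth)
  colnames(probs) <- model$levels
  if (type == "prob") return(probs)
  pos <- if ("pathologic" %in% model$levels)
    which(model$levels == "pathologic") else 2L
  other <- setdiff(1:2, pos)
  pick <- ifelse(probs[, pos] >= probs[, other], pos, other)
  factor(model$levels[pick], levels = model$levels)
}

#' @export
print.crydx_model <- function(x, ...) {
  if (x$kind == "svm") {
    cat(sprintf("<crydx_model> svm: C=%.4g, kernel_scale=%.4g, D=%d, %d SVs\n",
                x$config$box_constraint, x$config$kernel_scale, x$dim,
                x$fit$tot.nSV))
  } else {
    cat(sprintf("<crydx_model> lstm: depth=%d, hidden=%d, lr=%.4g, epochs=%d, D=%d\n",
                x$config$depth, x$config$hidden_units,
                x$config$initial_learning_rate, x$config$max_epochs, x$dim))
  }
  invisible(x)
}

#' Serialize a trained model to a JSON archive
#'
#' Self-describing: metadata plus numeric weight blobs. SVM models store the
#' libsvm support-vector representation; LSTM models store the full weight
#' list.
#'
#' @param model a `crydx_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  meta <- list(kind = model$kind, levels = model$levels, dim = model$dim,
               config = if (model$kind == "lstm") unclass(model$config)
                        else model$config,
               standardize = model$standardize)
  if (model$kind == "lstm") {
    meta$weights <- model$weights
  } else {
    meta$support_vectors <- model$fit$SV
    meta$coefs <- model$fit$coefs
    meta$rho <- model$fit$rho
  }
  jsonlite::write_json(meta, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
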