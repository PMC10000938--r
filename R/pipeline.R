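# End-to-end orchestration: corpus -> features -> (fusion) -> HPO -> final
# fit -> one evaluation on the untouched test set. Reproduces the experiment
# grid feature_set x classifier x HPO method on synthetic or user corpora.

#' Experiment configuration
#'
#' @param feature_set `"mfcc"`, `"gfcc"`, `"concat"`, or `"cca_fusion"`.
#' @param classifier `"svm"` or `"lstm"`.
#' @param hpo `"none"`, `"random"`, `"grid"`, or `"bayes"`.
#' @param hpo_budget evaluation budget for the search (grid resolution is
#'   derived as `floor(budget^(1/n_params))` points per dimension).
#' @param n_per_class synthetic corpus size per class (ignored when `corpus`
#'   is supplied).
#' @param episode `"EXP"` or `"INSV"`.
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param cca_d retained canonical pairs for the fused set (default 30, so
#'   two 39-dim views fuse to 60).
#' @param train_fraction holdout training fraction.
#' @param kfold folds for the SVM cross-validated objective.
#' @param lstm_epochs two-element range searched for `max_epochs` (the
#'   admissible range is `[100, 500]`; smaller ranges are allowed for
#'   scaled-down studies and imply non-strict LSTM configs).
#' @param lstm_stride temporal decimation of the LSTM frame sequences: every
#'   `lstm_stride`-th frame is kept. Adjacent 10 ms frames with 30% overlap
#'   are highly redundant, so moderate striding (default 4) preserves the
#'   spectral-envelope dynamics the classifier uses while shortening the
#'   recurrence. Set 1 to keep every frame.
#' @param lstm_batch_size,lstm_val_every LSTM trainer settings.
#' @param healthy_spec,pathologic_spec optional [cry_spec()] overrides for
#'   the synthetic corpus.
#' @param corpus optional pre-generated corpus (list of [cry_signal()]);
#'   overrides the synthetic generation parameters.
#' @param output_dir optional directory for JSON/CSV artifacts.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(feature_set = c("cca_fusion", "mfcc", "gfcc",
                                              "concat"),
                              classifier = c("svm", "lstm"),
                              hpo = c("bayes", "none", "random", "grid"),
                              hpo_budget = 30, n_per_class = 200,
                              episode = c("EXP", "INSV"), seed = 1,
                              cca_d = 30, train_fraction = 0.7, kfold = 5,
                              lstm_epochs = c(100, 500), lstm_stride = 4,
                              lstm_batch_size = 128, lstm_val_every = 10,
                              healthy_spec = NULL, pathologic_spec = NULL,
                              corpus = NULL, output_dir = NULL) {
  cfg <- list(feature_set = match.arg(feature_set),
              classifier = match.arg(classifier),
              hpo = match.arg(hpo),
              hpo_budget = as.integer(hpo_budget),
              n_per_class = as.integer(n_per_class),
              episode = match.arg(episode), seed = as.integer(seed),
              cca_d = as.integer(cca_d), train_fraction = train_fraction,
              kfold = as.integer(kfold),
              lstm_epochs = as.integer(lstm_epochs),
              lstm_stride = as.integer(lstm_stride),
              lstm_batch_size = as.integer(lstm_batch_size),
              lstm_val_every = as.integer(lstm_val_every),
              healthy_spec = healthy_spec,
              pathologic_spec = pathologic_spec,
              corpus = corpus, output_dir = output_dir)
  if (cfg$hpo_budget < 1) stop("`hpo_budget` must be >= 1", call. = FALSE)
  if (length(cfg$lstm_epochs) != 2 || cfg$lstm_epochs[1] > cfg$lstm_epochs[2])
    stop("`lstm_epochs` must be an increasing range", call. = FALSE)
  structure(cfg, class = "experiment_config")
}

#' Precompute the feature views of a corpus
#'
#' Extracts the MFCC and GFCC per-episode vectors (and, optionally, the
#' per-frame sequences for the LSTM path) once, so several experiment arms
#' can share them.
#'
#' @param corpus list of [cry_signal()] objects.
#' @param cep_cfg,frame_cfg analysis configurations.
#' @param sequences also extract frame sequences.
#' @return a list of class `crydx_features` with `mfcc`, `gfcc`
#'   ([extract_feature_set()] results), `labels`, and `subjects`.
#' @export
prepare_features <- function(corpus, cep_cfg = cepstral_config(),
                             frame_cfg = frame_config(), sequences = FALSE) {
  mf <- extract_feature_set(corpus, "mfcc", cep_cfg, frame_cfg,
                            sequences = sequences)
  gf <- extract_feature_set(corpus, "gfcc", cep_cfg, frame_cfg,
                            sequences = sequences)
  structure(list(mfcc = mf, gfcc = gf, labels = mf$labels,
                 subjects = mf$subjects),
            class = "crydx_features")
}

# Assemble the working representation of one feature_set arm.
# Returns per-episode matrices (n x D) and, if sequences are present,
# the matching frame-sequence lists; the CCA transform is fitted on the
# training episodes only and applied frame-wise for the sequence path.
build_feature_view <- function(feats, feature_set, train_idx, cca_d) {
  M <- feats$mfcc$features   # n x 39, rows = episodes
  G <- feats$gfcc$features
  seqs_m <- feats$mfcc$sequences
  seqs_g <- feats$gfcc$sequences
  transform <- NULL
  if (feature_set == "mfcc") {
    X <- M; S <- seqs_m
  } else if (feature_set == "gfcc") {
    X <- G; S <- seqs_g
  } else if (feature_set == "concat") {
    X <- cbind(G, M)
    S <- if (!is.null(seqs_m))
      Map(function(a, b) cbind(a, b), seqs_g, seqs_m)
  } else { # cca_fusion: views as p x n with training columns only for the fit
    transform <- cca_fit(t(G[train_idx, , drop = FALSE]),
                         t(M[train_idx, , drop = FALSE]), d = cca_d)
    X <- t(cca_fuse(transform, t(G), t(M)))
    S <- if (!is.null(seqs_m))
      Map(function(a, b) t(cca_fuse(transform, t(a), t(b))), seqs_g, seqs_m)
  }
  list(X = X, sequences = S, transform = transform, width = ncol(X))
}

default_svm_space <- function() {
  search_space(
    param_continuous("box_constraint", 1e-3, 1e3, scale = "log"),
    param_continuous("kernel_scale", 1e-3, 1e3, scale = "log"))
}

lstm_space <- function(epoch_range) {
  search_space(
    param_continuous("initial_learning_rate", 0.001, 1, scale = "log"),
    param_integer("hidden_units", 2, 39),
    param_integer("max_epochs", epoch_range[1], epoch_range[2]),
    param_integer("depth", 1, 3))
}

strict_epochs <- function(epoch_range) {
  epoch_range[1] >= 100 && epoch_range[2] <= 500
}

#' Run one experiment arm
#'
#' Pipeline order: corpus (generate or reuse) -> feature extraction ->
#' 70/30 stratified split -> CCA fit on the training episodes when fusing ->
#' hyperparameter search scored by 5-fold cross-validation (SVM) or a 20%
#' validation holdout (LSTM) on the training set -> refit of the best
#' configuration on the full training set -> a single evaluation on the
#' untouched test set. The test rows are never visible to any earlier stage.
#'
#' @param cfg an [experiment_config()].
#' @param features optional [prepare_features()] result for `cfg$corpus`,
#'   shared across arms.
#' @return an object of class `experiment_report`: the `metrics`
#'   ([compute_metrics()] report), `feature_width`, `best_config`,
#'   `hpo` history, split sizes, provenance (`seed`, config echo) and
#'   per-stage `timing` in seconds.
#' @export
run_experiment <- function(cfg, features = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  t0 <- Sys.time(); timing <- list()
  tick <- function(name) {
    timing[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    t0 <<- Sys.time()
  }

  need_seq <- cfg$classifier == "lstm"
  if (is.null(features)) {
    corpus <- cfg$corpus %||% generate_corpus(
      cfg$n_per_class, cfg$episode, seed = derive_seed(cfg$seed, 1),
      healthy_spec = cfg$healthy_spec, pathologic_spec = cfg$pathologic_spec)
  }
  tick("corpus")

  feats <- features %||% prepare_features(corpus, sequences = need_seq)
  if (need_seq && is.null(feats$mfcc$sequences))
    stop("LSTM arm needs frame sequences; call prepare_features(sequences = TRUE)",
         call. = FALSE)
  labels <- feats$labels
  tick("features")

  split <- split_holdout(labels,
                         split_spec(cfg$train_fraction,
                                    seed = derive_seed(cfg$seed, 2)))
  view <- build_feature_view(feats, cfg$feature_set, split$train, cfg$cca_d)
  if (need_seq && cfg$lstm_stride > 1L)
    view$sequences <- lapply(view$sequences, function(m)
      m[seq(1L, nrow(m), by = cfg$lstm_stride), , drop = FALSE])
  X_tr <- view$X[split$train, , drop = FALSE]
  y_tr <- droplevels(labels[split$train])
  tick("fusion")

  strict <- strict_epochs(cfg$lstm_epochs)
  make_lstm_cfg <- function(par) {
    lstm_config(hidden_units = par$hidden_units,
                initial_learning_rate = par$initial_learning_rate,
                max_epochs = par$max_epochs, depth = par$depth,
                seed = derive_seed(cfg$seed, 4),
                batch_size = cfg$lstm_batch_size,
                val_every = cfg$lstm_val_every, strict = strict)
  }

  if (cfg$classifier == "svm") {
    folds <- kfold_indices(y_tr, cfg$kfold, seed = derive_seed(cfg$seed, 3))
    objective <- function(par) {
      accs <- vapply(folds, function(fold) {
        fit <- svm_train(X_tr[-fold, , drop = FALSE], y_tr[-fold],
                         svm_config(par$box_constraint, par$kernel_scale))
        mean(svm_predict(fit, X_tr[fold, , drop = FALSE]) == y_tr[fold])
      }, numeric(1))
      mean(accs)
    }
    space <- default_svm_space()
  } else {
    S_tr <- view$sequences[split$train]
    objective <- function(par) {
      fit <- lstm_train(S_tr, y_tr, make_lstm_cfg(par))
      utils::tail(fit$validation$accuracy, 1)
    }
    space <- lstm_space(cfg$lstm_epochs)
  }

  hpo_res <- switch(cfg$hpo,
    none = NULL,
    grid = grid_search(space, objective,
                       points_per_dim = max(2L,
                         floor(cfg$hpo_budget^(1 / length(space))))),
    random = random_search(space, objective, cfg$hpo_budget,
                           seed = derive_seed(cfg$seed, 5)),
    bayes = bayesian_search(space, objective, cfg$hpo_budget,
                            seed = derive_seed(cfg$seed, 5)))
  tick("hpo")

  if (cfg$classifier == "svm") {
    final_cfg <- if (is.null(hpo_res)) svm_config()
                 else svm_config(hpo_res$best_config$box_constraint,
                                 hpo_res$best_config$kernel_scale)
    model <- svm_train(X_tr, y_tr, final_cfg)
    pred <- svm_predict(model, view$X[split$test, , drop = FALSE])
  } else {
    final_cfg <- if (is.null(hpo_res)) {
      lstm_config(seed = derive_seed(cfg$seed, 4),
                  max_epochs = cfg$lstm_epochs[2],
                  batch_size = cfg$lstm_batch_size,
                  val_every = cfg$lstm_val_every, strict = strict,
                  holdout_fraction = 0)
    } else {
      c0 <- make_lstm_cfg(hpo_res$best_config)
      c0$holdout_fraction <- 0  # refit on the full training set
      c0
    }
    model <- lstm_train(view$sequences[split$train], y_tr, final_cfg)
    pred <- lstm_predict(model, view$sequences[split$test])
  }
  cm <- contingency(labels[split$test], pred)
  metrics <- compute_metrics(cm)
  tick("final_fit_eval")

  report <- structure(list(
    metrics = metrics,
    feature_width = view$width,
    feature_set = cfg$feature_set, classifier = cfg$classifier,
    hpo_method = cfg$hpo, hpo = hpo_res,
    best_config = if (is.null(hpo_res)) NULL else hpo_res$best_config,
    n_train = length(split$train), n_test = length(split$test),
    seed = cfg$seed,
    cca_correlations = if (!is.null(view$transform))
      view$transform$correlations,
    timing = timing), class = "experiment_report")

  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s + %s + %s (width %d, train %d / test %d)\n",
              x$feature_set, x$classifier, x$hpo_method, x$feature_width,
              x$n_train, x$n_test))
  print(x$metrics)
  invisible(x)
}

report_as_list <- function(report, include_timing = TRUE) {
  m <- report$metrics
  out <- list(feature_set = report$feature_set,
              classifier = report$classifier,
              hpo_method = report$hpo_method,
              feature_width = report$feature_width,
              n_train = report$n_train, n_test = report$n_test,
              seed = report$seed,
              metrics = list(accuracy = m$accuracy, recall = m$recall,
                             specificity = m$specificity,
                             precision = m$precision, npv = m$npv,
                             f_score = m$f_score, mcc = m$mcc,
                             passes_mcc_gate = m$passes_mcc_gate),
              counts = m$counts,
              best_config = report$best_config)
  if (include_timing) out$timing <- report$timing
  out
}

#' Write an experiment report and its trial log to disk
#'
#' `report.json` (metrics + provenance), `trials.csv` (HPO history) and
#' `timing.json` are placed under `dir`.
#'
#' @param report an `experiment_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_as_list(report, include_timing = FALSE),
                       file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(report$timing, file.path(dir, "timing.json"),
                       digits = NA, auto_unbox = TRUE)
  if (!is.null(report$hpo))
    write_hpo_csv(report$hpo, file.path(dir, "trials.csv"))
  invisible(dir)
}

#' Run a list of experiment arms and tabulate the results
#'
#' Partial failures are recorded per row (column `error`) and the run
#' continues.
#'
#' @param cfgs list of [experiment_config()] objects.
#' @param features optional shared [prepare_features()] result.
#' @return data.frame with one row per config: arm descriptors, the six
#'   metrics, MCC, and an `error` column (NA on success).
#' @export
run_grid_experiments <- function(cfgs, features = NULL) {
  if (!length(cfgs))
    return(data.frame(feature_set = character(0), classifier = character(0),
                      hpo = character(0), hpo_budget = integer(0),
                      accuracy = numeric(0), recall = numeric(0),
                      specificity = numeric(0), precision = numeric(0),
                      npv = numeric(0), f_score = numeric(0),
                      mcc = numeric(0), error = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(cfgs, function(cfg) {
    res <- tryCatch(run_experiment(cfg, features = features),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(feature_set = cfg$feature_set, classifier = cfg$classifier,
                 hpo = cfg$hpo, hpo_budget = cfg$hpo_budget,
                 accuracy = NA_real_, recall = NA_real_,
                 specificity = NA_real_, precision = NA_real_,
                 npv = NA_real_, f_score = NA_real_, mcc = NA_real_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      m <- res$metrics
      data.frame(feature_set = cfg$feature_set, classifier = cfg$classifier,
                 hpo = cfg$hpo, hpo_budget = cfg$hpo_budget,
                 accuracy = m$accuracy, recall = m$recall,
                 specificity = m$specificity, precision = m$precision,
                 npv = m$npv, f_score = m$f_score, mcc = m$mcc,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Configurations for an HPO-budget sweep
#'
#' @param base an [experiment_config()].
#' @param budgets vector of budgets (default 30..100 by 10).
#' @return list of configs differing only in `hpo_budget`.
#' @export
sweep_budgets <- function(base, budgets = seq(30, 100, by = 10)) {
  lapply(budgets, function(b) { base$hpo_budget <- as.integer(b); base })
}
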