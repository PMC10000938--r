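# Data splitting, cross-validation folds, the contingency matrix, and the
# derived diagnostic metrics (pathologic = positive class).

#' Holdout split specification
#'
#' @param train_fraction fraction of samples assigned to training (0, 1).
#' @param stratified preserve class proportions (largest-remainder
#'   apportionment of the total `round(train_fraction * n)` across classes).
#' @param group_by_subject keep all episodes of one subject on the same side
#'   of the split (needs `subjects` at split time).
#' @param seed integer seed.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.7, stratified = TRUE,
                       group_by_subject = FALSE, seed = 1) {
  assert_scalar_num(train_fraction, "train_fraction",
                    lo = 1e-9, hi = 1 - 1e-9)
  structure(list(train_fraction = train_fraction, stratified = stratified,
                 group_by_subject = group_by_subject,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split samples into train and test sets
#'
#' The training size is `round(train_fraction * n)` overall. Under
#' stratification the total is apportioned across classes by largest
#' remainder, so balanced two-class corpora of 6010 and 7240 samples split
#' 4207/1803 and 5068/2172 at the default 70/30. Deterministic per seed.
#'
#' @param labels factor (or coercible) of class labels, one per sample.
#' @param spec a [split_spec()].
#' @param subjects optional subject ids (required when
#'   `spec$group_by_subject`).
#' @return list with integer index vectors `train` and `test`.
#' @export
split_holdout <- function(labels, spec = split_spec(), subjects = NULL) {
  y <- as.factor(labels)
  n <- length(y)
  if (!n) stop("empty dataset", call. = FALSE)
  n_train_total <- round(spec$train_fraction * n)

  if (spec$group_by_subject) {
    if (is.null(subjects)) stop("`subjects` required for subject-wise splitting",
                                call. = FALSE)
    train <- withr::with_seed(spec$seed, {
      idx <- integer(0)
      for (lv in levels(y)) {
        members <- which(y == lv)
        subj <- unique(subjects[members])
        subj <- subj[sample.int(length(subj))]
        target <- spec$train_fraction * length(members)
        got <- integer(0)
        for (s in subj) {
          if (length(got) >= target) break
          got <- c(got, members[subjects[members] == s])
        }
        idx <- c(idx, got)
      }
      sort(idx)
    })
  } else if (spec$stratified) {
    counts <- table(y)
    exact <- spec$train_fraction * as.numeric(counts)
    base <- floor(exact)
    rem <- n_train_total - sum(base)
    if (rem > 0) {
      order_frac <- order(exact - base, decreasing = TRUE)
      base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
    }
    train <- withr::with_seed(spec$seed, {
      unlist(lapply(seq_along(levels(y)), function(j) {
        members <- which(y == levels(y)[j])
        members[sample.int(length(members), base[j])]
      }))
    })
    train <- sort(train)
  } else {
    train <- withr::with_seed(spec$seed,
                              sort(sample.int(n, n_train_total)))
  }
  test <- setdiff(seq_len(n), train)
  if (spec$stratified &&
      (length(unique(y[train])) < nlevels(droplevels(y)) ||
       length(unique(y[test])) < nlevels(droplevels(y))))
    stop("a class is absent from one side of the stratified split", call. = FALSE)
  list(train = train, test = test)
}

#' Stratified k-fold partition
#'
#' Folds partition the indices, sizes differ by at most one, and class
#' proportions are preserved as closely as the counts allow.
#'
#' @param labels factor of class labels.
#' @param k number of folds (>= 2, <= n).
#' @param seed integer seed.
#' @return list of k disjoint integer index vectors.
#' @export
kfold_indices <- function(labels, k = 5, seed = 1) {
  y <- as.factor(labels)
  n <- length(y)
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (k > n) stop("`k` exceeds the number of samples", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    folds <- rep(list(integer(0)), k)
    fold_sizes <- integer(k)
    for (lv in levels(y)) {
      members <- which(y == lv)
      members <- members[sample.int(length(members))]
      for (m in members) {
        j <- which.min(fold_sizes)  # smallest fold first: sizes differ <= 1
        folds[[j]] <- c(folds[[j]], m)
        fold_sizes[j] <- fold_sizes[j] + 1L
      }
    }
    lapply(folds, sort)
  })
}

#' Contingency matrix of a binary prediction
#'
#' Counts with the pathologic class as positive: TP (pathologic predicted
#' pathologic), FP (healthy predicted pathologic), FN, TN.
#'
#' @param truth,predicted equal-length vectors of class labels.
#' @param positive the positive-class label.
#' @return an object of class `contingency_matrix`.
#' @export
contingency <- function(truth, predicted, positive = "pathologic") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  if (!length(truth)) stop("empty label vectors", call. = FALSE)
  lv <- unique(c(truth, predicted))
  if (length(lv) > 2)
    stop("more than two distinct labels: ", paste(lv, collapse = ", "),
         call. = FALSE)
  if (!positive %in% lv && length(lv) == 2)
    stop(sprintf("positive label '%s' not present in the data", positive),
         call. = FALSE)
  is_pos_t <- truth == positive
  is_pos_p <- predicted == positive
  structure(list(TP = sum(is_pos_t & is_pos_p),
                 FP = sum(!is_pos_t & is_pos_p),
                 FN = sum(is_pos_t & !is_pos_p),
                 TN = sum(!is_pos_t & !is_pos_p),
                 positive = positive),
            class = "contingency_matrix")
}

#' @export
print.contingency_matrix <- function(x, ...) {
  cat(sprintf("<contingency_matrix> TP=%d FP=%d FN=%d TN=%d (positive=%s)\n",
              x$TP, x$FP, x$FN, x$TN, x$positive))
  invisible(x)
}

#' Diagnostic metrics from a contingency matrix
#'
#' Accuracy, recall (sensitivity), specificity, precision (PPV), negative
#' predictive value, and F-score are reported as percentages; the Matthews
#' correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))` lies in [-1, 1].
#' A ratio with a zero denominator is reported as 0 and listed in the
#' `undefined` field rather than raised, so batch experiment tables stay
#' total. `passes_mcc_gate` records whether MCC reaches the acceptance value
#' (default +0.50).
#'
#' @param cm a [contingency()] result, or a list with TP/FP/FN/TN counts.
#' @param mcc_gate MCC acceptance threshold.
#' @return an object of class `evaluation_report`.
#' @export
compute_metrics <- function(cm, mcc_gate = 0.5) {
  TP <- cm$TP; FP <- cm$FP; FN <- cm$FN; TN <- cm$TN
  total <- TP + FP + FN + TN
  if (!isTRUE(total > 0)) stop("empty contingency matrix", call. = FALSE)
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  precision <- ratio(TP, TP + FP, "precision")
  recall <- ratio(TP, TP + FN, "recall")
  specificity <- ratio(TN, TN + FP, "specificity")
  npv <- ratio(TN, TN + FN, "npv")
  f_score <- ratio(2 * precision * recall, precision + recall, "f_score")
  mcc_den <- sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TP + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) { undefined <- c(undefined, "mcc"); 0 }
         else (TP * TN - FP * FN) / mcc_den
  structure(list(accuracy = 100 * (TP + TN) / total,
                 recall = 100 * recall,
                 specificity = 100 * specificity,
                 precision = 100 * precision,
                 npv = 100 * npv,
                 f_score = 100 * f_score,
                 mcc = mcc,
                 passes_mcc_gate = mcc >= mcc_gate,
                 mcc_gate = mcc_gate,
                 undefined = undefined,
                 counts = list(TP = TP, FP = FP, FN = FN, TN = TN)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "  Accuracy  Recall  Specificity  Precision  NPV     F-Score  MCC\n  %-9.2f %-7.2f %-12.2f %-10.2f %-7.2f %-8.2f %.3f %s\n",
    x$accuracy, x$recall, x$specificity, x$precision, x$npv, x$f_score,
    x$mcc, if (x$passes_mcc_gate) sprintf("(>= %.2f gate)", x$mcc_gate)
           else sprintf("(below %.2f gate)", x$mcc_gate)))
  if (length(x$undefined))
    cat("  undefined (zero denominator):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
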