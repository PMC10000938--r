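test_that("the 70/30 split reproduces the balanced-corpus arithmetic", {
  labs_exp <- factor(rep(c("healthy", "pathologic"), each = 3005))
  sp <- split_holdout(labs_exp, split_spec(seed = 1))
  expect_length(sp$train, 4207)
  expect_length(sp$test, 1803)

  labs_insv <- factor(rep(c("healthy", "pathologic"), each = 3620))
  sp2 <- split_holdout(labs_insv, split_spec(seed = 1))
  expect_length(sp2$train, 5068)
  expect_length(sp2$test, 2172)

  sp3 <- split_holdout(factor(rep(c("a", "b"), 5)), split_spec(seed = 2))
  expect_length(sp3$train, 7)
  expect_length(sp3$test, 3)
})

test_that("stratified splits balance classes and are seeded", {
  labs <- factor(rep(c("healthy", "pathologic"), each = 50))
  a <- split_holdout(labs, split_spec(seed = 3))
  b <- split_holdout(labs, split_spec(seed = 3))
  expect_identical(a, b)
  expect_false(identical(a, split_holdout(labs, split_spec(seed = 4))))
  per_class <- table(labs[a$train])
  expect_lte(max(per_class) - min(per_class), 1)
  expect_length(intersect(a$train, a$test), 0)
  expect_setequal(c(a$train, a$test), seq_along(labs))
})

test_that("subject-wise splitting keeps subjects on one side", {
  labs <- factor(rep(c("healthy", "pathologic"), each = 20))
  subj <- rep(sprintf("s%02d", 1:8), each = 5)
  sp <- split_holdout(labs, split_spec(group_by_subject = TRUE, seed = 5),
                      subjects = subj)
  train_subj <- unique(subj[sp$train])
  test_subj <- unique(subj[sp$test])
  expect_length(intersect(train_subj, test_subj), 0)
  expect_error(split_holdout(labs, split_spec(group_by_subject = TRUE)),
               "subjects")
})

test_that("k-fold partitions are disjoint, exhaustive, and balanced", {
  labs <- factor(rep(c("healthy", "pathologic"), each = 50))
  folds <- kfold_indices(labs, 5, seed = 1)
  expect_length(folds, 5)
  expect_equal(vapply(folds, length, integer(1)), rep(20L, 5))
  expect_setequal(unlist(folds), 1:100)
  expect_equal(sum(duplicated(unlist(folds))), 0)

  labs101 <- factor(rep("x", 101))
  sizes <- sort(vapply(kfold_indices(labs101, 5, seed = 2), length,
                       integer(1)), decreasing = TRUE)
  expect_equal(sizes, c(21L, 20L, 20L, 20L, 20L))
  expect_error(kfold_indices(labs, 1), "k")
  expect_error(kfold_indices(factor(rep("x", 3)), 5), "exceeds")
})

test_that("contingency counts use pathologic as the positive class", {
  perfect <- contingency(rep(c("pathologic", "healthy"), each = 10),
                         rep(c("pathologic", "healthy"), each = 10))
  expect_equal(unlist(perfect[c("TP", "FP", "FN", "TN")]),
               c(TP = 10, FP = 0, FN = 0, TN = 10))

  all_h <- contingency(rep(c("pathologic", "healthy"), 5),
                       rep("healthy", 10))
  expect_equal(all_h$TP, 0); expect_equal(all_h$FP, 0)
  expect_equal(all_h$FN, 5); expect_equal(all_h$TN, 5)

  mixed <- contingency(c("pathologic", "pathologic", "healthy", "healthy"),
                       c("pathologic", "healthy", "pathologic", "healthy"))
  expect_equal(unlist(mixed[c("TP", "FP", "FN", "TN")]),
               c(TP = 1, FP = 1, FN = 1, TN = 1))

  expect_error(contingency(c("a", "b"), c("a",  "b", "b")), "equal length")
  expect_error(contingency(c("a", "b", "c"), c("a", "b", "c")), "two")
})

test_that("metric formulas match hand-computed values", {
  perfect <- compute_metrics(list(TP = 7, FP = 0, FN = 0, TN = 7))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f_score, 100)
  expect_equal(perfect$mcc, 1)
  expect_true(perfect$passes_mcc_gate)

  inverted <- compute_metrics(list(TP = 0, FP = 9, FN = 9, TN = 0))
  expect_equal(inverted$mcc, -1)
  expect_false(inverted$passes_mcc_gate)

  r <- compute_metrics(list(TP = 40, FP = 5, FN = 10, TN = 45))
  expect_equal(r$accuracy, 85)
  expect_equal(r$precision, 100 * 40 / 45, tolerance = 1e-10)  # 88.89
  expect_equal(r$recall, 80)
  expect_equal(r$specificity, 90)
  expect_equal(r$npv, 100 * 45 / 55, tolerance = 1e-10)
  expect_equal(r$f_score, 100 * 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8),
               tolerance = 1e-10)                              # 84.21
  expect_equal(r$mcc, 1750 / sqrt(50 * 50 * 45 * 55), tolerance = 1e-10)
  expect_equal(r$mcc, 0.7035, tolerance = 1e-4)
  expect_error(compute_metrics(list(TP = 0, FP = 0, FN = 0, TN = 0)), "empty")
})

test_that("metrics agree with direct evaluation for every small matrix", {
  # independent re-implementation of the ratio definitions
  direct <- function(TP, FP, FN, TN) {
    div <- function(a, b) if (b == 0) 0 else a / b
    mden <- sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TP + FP) * sqrt(TN + FN)
    p <- div(TP, TP + FP); rec <- div(TP, TP + FN)
    c(accuracy = 100 * (TP + TN) / (TP + FP + FN + TN),
      recall = 100 * rec, specificity = 100 * div(TN, TN + FP),
      precision = 100 * p, npv = 100 * div(TN, TN + FN),
      f_score = 100 * div(2 * p * rec, p + rec),
      mcc = if (mden == 0) 0 else (TP * TN - FP * FN) / mden)
  }
  for (total in 1:12) {
    for (TP in 0:total) for (FP in 0:(total - TP)) {
      for (FN in 0:(total - TP - FP)) {
        TN <- total - TP - FP - FN
        got <- compute_metrics(list(TP = TP, FP = FP, FN = FN, TN = TN))
        want <- direct(TP, FP, FN, TN)
        expect_equal(c(accuracy = got$accuracy, recall = got$recall,
                       specificity = got$specificity,
                       precision = got$precision, npv = got$npv,
                       f_score = got$f_score, mcc = got$mcc),
                     want, tolerance = 1e-12)
      }
    }
  }
})

test_that("MCC is symmetric under class swap and flags undefined ratios", {
  withr::with_seed(1, cases <- matrix(sample(0:20, 40, TRUE), ncol = 4))
  for (i in seq_len(nrow(cases))) {
    cm <- list(TP = cases[i, 1], FP = cases[i, 2],
               FN = cases[i, 3], TN = cases[i, 4])
    sw <- list(TP = cm$TN, FP = cm$FN, FN = cm$FP, TN = cm$TP)
    if (sum(unlist(cm[1:4])) == 0) next
    expect_equal(compute_metrics(cm)$mcc, compute_metrics(sw)$mcc,
                 tolerance = 1e-12)
  }
  und <- compute_metrics(list(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_true("precision" %in% und$undefined)
  expect_equal(und$precision, 0)
})

test_that("balanced classes make accuracy the mean of recall and specificity", {
  withr::with_seed(2, {
    for (i in 1:20) {
      n <- sample(5:50, 1)
      TP <- sample(0:n, 1); FN <- n - TP
      TN <- sample(0:n, 1); FP <- n - TN
      r <- compute_metrics(list(TP = TP, FP = FP, FN = FN, TN = TN))
      expect_equal(r$accuracy, (r$recall + r$specificity) / 2,
                   tolerance = 1e-10)
    }
  })
})
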