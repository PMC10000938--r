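test_that("the SVM separates Gaussian blobs perfectly", {
  withr::with_seed(1, {
    x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 5), 50, 2))
  })
  y <- factor(rep(c("healthy", "pathologic"), each = 50))
  m <- svm_train(x, y, svm_config(box_constraint = 10))
  expect_equal(mean(svm_predict(m, x) == y), 1)
})

test_that("the Gaussian kernel handles XOR-patterned data", {
  withr::with_seed(2, {
    centers <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
    x <- do.call(rbind, lapply(1:4, function(k)
      matrix(rnorm(50, 0, 0.1), 25, 2) + rep(centers[k, ], each = 25)))
  })
  y <- factor(rep(c("A", "A", "B", "B"), each = 25))
  m <- svm_train(x, y, svm_config(box_constraint = 10, kernel_scale = 0.3))
  expect_gt(mean(svm_predict(m, x) == y), 0.95)
})

test_that("duplicating every training point leaves the decision unchanged", {
  withr::with_seed(3, {
    x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 2.5), 30, 2))
    probe <- matrix(runif(100, -2, 5), 50, 2)
  })
  y <- factor(rep(c("healthy", "pathologic"), each = 30))
  m1 <- svm_train(x, y, svm_config(box_constraint = 1, kernel_scale = 1))
  m2 <- svm_train(rbind(x, x), factor(c(as.character(y), as.character(y))),
                  svm_config(box_constraint = 0.5, kernel_scale = 1))
  # halving the per-point penalty compensates the doubled data
  expect_equal(svm_predict(m1, probe), svm_predict(m2, probe))
})

test_that("SVM predictions are deterministic and order-invariant", {
  withr::with_seed(4, {
    x <- rbind(matrix(rnorm(80, 0), 40, 2), matrix(rnorm(80, 1.6), 40, 2))
    probe <- matrix(rnorm(60, 0.8), 30, 2)
  })
  y <- factor(rep(c("healthy", "pathologic"), each = 40))
  m <- svm_train(x, y)
  p1 <- svm_predict(m, probe)
  expect_identical(p1, svm_predict(m, probe))
  perm <- sample(30)
  expect_identical(as.character(p1)[perm],
                   as.character(svm_predict(m, probe[perm, ])))
  expect_length(svm_predict(m, matrix(0, 0, 2)), 0)
  expect_error(svm_predict(m, matrix(0, 3, 5)), "feature columns")
  expect_error(svm_train(x, factor(rep("healthy", 80))), "two classes")
})

test_that("the LSTM learns mean-separated sequence classes", {
  d <- blob_sequences(30, sep = 1.5, seed = 10)
  cfg <- lstm_config(hidden_units = 8, initial_learning_rate = 0.02,
                     max_epochs = 40, depth = 1, seed = 3, strict = FALSE)
  m <- lstm_train(d$sequences, d$labels, cfg)
  expect_gt(tail(m$validation$accuracy, 1), 0.95)
  expect_equal(mean(lstm_predict(m, d$sequences) == d$labels), 1,
               tolerance = 0.05)
})

test_that("shuffled labels give chance-level holdout accuracy", {
  d <- blob_sequences(100, t_len = 10, sep = 1.5, seed = 11)
  y_shuf <- withr::with_seed(12, sample(d$labels))
  cfg <- lstm_config(hidden_units = 6, initial_learning_rate = 0.02,
                     max_epochs = 12, depth = 1, seed = 5, strict = FALSE)
  m <- lstm_train(d$sequences, y_shuf, cfg)
  acc <- tail(m$validation$accuracy, 1)
  expect_gte(acc, 0.4); expect_lte(acc, 0.6)
})

test_that("LSTM training and prediction are deterministic", {
  d <- blob_sequences(15, seed = 13)
  cfg <- lstm_config(hidden_units = 4, initial_learning_rate = 0.05,
                     max_epochs = 15, depth = 1, seed = 7, strict = FALSE)
  m1 <- lstm_train(d$sequences, d$labels, cfg)
  m2 <- lstm_train(d$sequences, d$labels, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(tail(m1$validation$accuracy, 1),
                   tail(m2$validation$accuracy, 1))
  p <- lstm_predict(m1, d$sequences)
  expect_identical(p, lstm_predict(m1, d$sequences))
})

test_that("batch and one-by-one LSTM predictions agree", {
  d <- blob_sequences(10, seed = 14)
  cfg <- lstm_config(hidden_units = 4, initial_learning_rate = 0.05,
                     max_epochs = 10, depth = 2, seed = 2, strict = FALSE)
  m <- lstm_train(d$sequences, d$labels, cfg)
  batch <- lstm_predict(m, d$sequences)
  single <- vapply(d$sequences, function(s)
    as.character(lstm_predict(m, list(s))), character(1))
  expect_equal(as.character(batch), single)
  expect_length(lstm_predict(m, list(d$sequences[[1]])), 1)
  probs <- lstm_predict(m, d$sequences, type = "prob")
  expect_equal(rowSums(probs), rep(1, 20), tolerance = 1e-9)
})

test_that("the admissible hyperparameter ranges are enforced when strict", {
  expect_error(lstm_config(initial_learning_rate = 2), "\\[0.001, 1\\]")
  expect_error(lstm_config(hidden_units = 1), "\\[2, 39\\]")
  expect_error(lstm_config(max_epochs = 50), "\\[100, 500\\]")
  expect_error(lstm_config(depth = 4), "\\[1, 3\\]")
  expect_s3_class(lstm_config(max_epochs = 50, strict = FALSE), "lstm_config")
  d <- blob_sequences(4, seed = 15)
  expect_error(lstm_train(d$sequences,
                          factor(rep("healthy", 8)),
                          lstm_config(strict = FALSE, max_epochs = 5)),
               "two classes")
})

test_that("variable-length sequences are handled through masking", {
  withr::with_seed(16, {
    seqs <- c(lapply(1:12, function(i) matrix(rnorm(sample(5:25, 1) * 3), ncol = 3)),
              lapply(1:12, function(i) matrix(rnorm(sample(5:25, 1) * 3, 2), ncol = 3)))
  })
  labels <- factor(rep(c("healthy", "pathologic"), each = 12))
  cfg <- lstm_config(hidden_units = 6, initial_learning_rate = 0.05,
                     max_epochs = 30, depth = 1, seed = 9, strict = FALSE)
  m <- lstm_train(seqs, labels, cfg)
  expect_gt(mean(lstm_predict(m, seqs) == labels), 0.9)
  # padding must not change a prediction: compare against per-sequence calls
  longest <- seqs[[which.max(vapply(seqs, nrow, integer(1)))]]
  shortest <- seqs[[which.min(vapply(seqs, nrow, integer(1)))]]
  mixed <- lstm_predict(m, list(longest, shortest))
  expect_equal(as.character(mixed),
               c(as.character(lstm_predict(m, list(longest))),
                 as.character(lstm_predict(m, list(shortest)))))
})
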