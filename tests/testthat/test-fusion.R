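test_that("concatenation stacks rows with aligned columns", {
  withr::with_seed(1, { X <- matrix(rnorm(39 * 10), 39); Y <- matrix(rnorm(39 * 10), 39) })
  Z <- concat_features(X, Y)
  expect_equal(nrow(Z), 78)
  expect_equal(Z[, 4], c(X[, 4], Y[, 4]))
  empty <- concat_features(matrix(0, 39, 0), matrix(0, 39, 0))
  expect_equal(dim(empty), c(78, 0))
  expect_error(concat_features(X, Y[, 1:5]), "equal n")
})

test_that("identical views have unit canonical correlations", {
  withr::with_seed(2, X <- matrix(rnorm(5 * 200), 5))
  tr <- cca_fit(X, X, d = 5, ridge = 0)
  expect_equal(tr$correlations, rep(1, 5), tolerance = 1e-8)
})

test_that("the 1-dimensional case reduces to |Pearson correlation|", {
  withr::with_seed(3, {
    x <- matrix(rnorm(300), 1)
    y <- 0.4 * x + matrix(rnorm(300, sd = 0.8), 1)
  })
  tr <- cca_fit(x, y, d = 1, ridge = 0)
  expect_equal(tr$correlations, abs(cor(drop(x), drop(y))), tolerance = 1e-10)
})

test_that("independent views have near-zero canonical correlations", {
  withr::with_seed(4, {
    X <- matrix(rnorm(4 * 10000), 4)
    Y <- matrix(rnorm(4 * 10000), 4)
  })
  tr <- cca_fit(X, Y, d = 4, ridge = 0)
  expect_lt(max(tr$correlations), 0.1)
})

test_that("correlations match a brute-force generalized eigensolution", {
  # oracle: assemble the covariance blocks literally and take the
  # eigenvalues of Sxx^-1 Sxy Syy^-1 Syx (squared canonical correlations)
  brute_cca <- function(X, Y) {
    n <- ncol(X)
    xc <- X - rowMeans(X); yc <- Y - rowMeans(Y)
    Sxx <- tcrossprod(xc) / (n - 1); Syy <- tcrossprod(yc) / (n - 1)
    Sxy <- tcrossprod(xc, yc) / (n - 1)
    M <- solve(Sxx, Sxy %*% solve(Syy, t(Sxy)))
    sort(sqrt(pmax(Re(eigen(M, only.values = TRUE)$values), 0)),
         decreasing = TRUE)
  }
  worst <- 0
  for (i in 1:50) {
    withr::with_seed(1000 + i, {
      X <- matrix(rnorm(6 * 300), 6)
      Y <- matrix(rnorm(6 * 300), 6)
      Y[1:2, ] <- Y[1:2, ] + 0.5 * X[1:2, ]
    })
    tr <- cca_fit(X, Y, d = 6, ridge = 0)
    worst <- max(worst, max(abs(tr$correlations - brute_cca(X, Y))))
  }
  expect_lt(worst, 1e-7)
})

test_that("canonical correlations are invariant to invertible view maps", {
  withr::with_seed(5, {
    X <- matrix(rnorm(6 * 400), 6)
    Y <- matrix(rnorm(6 * 400), 6) + 0.3 * X
    A <- matrix(rnorm(36), 6) + diag(6)
  })
  base <- cca_fit(X, Y, d = 6, ridge = 0)$correlations
  mapped <- cca_fit(A %*% X, Y, d = 6, ridge = 0)$correlations
  expect_equal(base, mapped, tolerance = 1e-6)
})

test_that("projections are ordered, uncorrelated within view, unit variance", {
  withr::with_seed(6, {
    X <- matrix(rnorm(8 * 500), 8)
    Y <- matrix(rnorm(8 * 500), 8) + 0.4 * X
  })
  tr <- cca_fit(X, Y, d = 6, ridge = 0)
  expect_true(all(diff(tr$correlations) <= 1e-10))
  Z <- cca_fuse(tr, X, Y)
  Xs <- Z[1:6, ]; Ys <- Z[7:12, ]
  expect_equal(cov(t(Xs)), diag(6), tolerance = 1e-8)
  expect_equal(cov(t(Ys)), diag(6), tolerance = 1e-8)
  # successive projection pairs correlate exactly at the fitted values
  for (k in 1:6)
    expect_equal(cor(Xs[k, ], Ys[k, ]), tr$correlations[k], tolerance = 1e-8)
})

test_that("fusion widths follow the retained-pair count", {
  withr::with_seed(7, {
    X <- matrix(rnorm(39 * 200), 39)
    Y <- matrix(rnorm(39 * 200), 39)
  })
  tr30 <- cca_fit(X, Y, d = 30)
  expect_equal(nrow(cca_fuse(tr30, X, Y)), 60)
  tr39 <- cca_fit(X, Y, d = 39)
  expect_equal(nrow(cca_fuse(tr39, X, Y)), 78)
})

test_that("a frozen transform is reproducible and validates dimensions", {
  withr::with_seed(8, {
    X <- matrix(rnorm(5 * 100), 5)
    Y <- matrix(rnorm(5 * 100), 5)
  })
  tr <- cca_fit(X, Y, d = 3)
  expect_identical(cca_fuse(tr, X, Y), cca_fuse(tr, X, Y))
  expect_error(cca_fuse(tr, X[1:4, ], Y), "dimensions")
  expect_error(cca_fit(X, Y[, 1:50]), "same number of columns")
  expect_error(cca_fit(X[, 1, drop = FALSE], Y[, 1, drop = FALSE]),
               "at least 2")
  # rank-deficient without ridge: duplicated feature row
  Xdup <- rbind(X, X[1, ])
  expect_error(cca_fit(Xdup, rbind(Y, Y[1, ]), d = 2, ridge = 0), "ridge")
  expect_silent(tr2 <- cca_fit(Xdup, rbind(Y, Y[1, ]), d = 2, ridge = 1e-6))
})

test_that("a transform survives a JSON round trip", {
  withr::with_seed(9, {
    X <- matrix(rnorm(4 * 80), 4)
    Y <- matrix(rnorm(4 * 80), 4)
  })
  tr <- cca_fit(X, Y, d = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_cca_json(tr, path)
  back <- read_cca_json(path)
  expect_equal(back$Wx, tr$Wx, tolerance = 1e-12)
  expect_equal(back$correlations, tr$correlations, tolerance = 1e-12)
  expect_equal(cca_fuse(back, X, Y), cca_fuse(tr, X, Y), tolerance = 1e-12)
})
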