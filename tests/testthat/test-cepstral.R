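test_that("the mel scale evaluates correctly", {
  expect_equal(mel_scale(0), 0)
  expect_equal(mel_scale(700), 1125 * log(2))      # ~779.87
  expect_equal(mel_scale(22050), 1125 * log(32.5)) # ~3916.4
  expect_equal(mel_to_hz(mel_scale(1234.5)), 1234.5)
  expect_error(mel_scale(-1), "non-negative")
})

test_that("the mel filterbank has mel-equispaced unimodal triangles", {
  bank <- build_mel_filterbank(cepstral_config(), rate = 44100)
  expect_equal(nrow(bank$weights), 13)
  expect_true(all(bank$weights >= 0))
  expect_true(all(rowSums(bank$weights) > 0))
  # unimodal: weights rise then fall along each row
  for (b in seq_len(13)) {
    w <- bank$weights[b, ]
    peak <- which.max(w)
    expect_true(all(diff(w[1:peak]) >= -1e-12))
    expect_true(all(diff(w[peak:length(w)]) <= 1e-12))
  }
  mels <- mel_scale(bank$center_freqs)
  expect_lt(max(abs(diff(mels) - diff(mels)[1])), 1e-9)
})

test_that("the gammatone filterbank is ERB-spaced with widening bands", {
  cfg <- cepstral_config(fft_size = 8192)  # fine grid to resolve -3 dB widths
  bank <- build_gammatone_filterbank(cfg, rate = 44100)
  expect_equal(nrow(bank$weights), 64)
  expect_true(all(diff(bank$center_freqs) > 0))
  expect_equal(apply(bank$weights, 1, max), rep(1, 64))
  width_hz <- function(b) {
    above <- which(bank$weights[b, ] >= 1 / sqrt(2))
    (max(above) - min(above)) * 44100 / cfg$fft_size
  }
  # low bands are narrower than the FFT grid and the top band is truncated
  # at Nyquist, so measure interior bands where the -3 dB width resolves
  widths <- vapply(seq(16, 56, by = 8), width_hz, numeric(1))
  expect_true(all(diff(widths) > 0))
  expect_error(build_gammatone_filterbank(cepstral_config(), rate = 90),
               "50 Hz")
})

test_that("the orthonormal DCT-II round-trips and matches the closed form", {
  withr::with_seed(11, x <- rnorm(64))
  expect_lt(max(abs(idct_ii(dct_ii(x)) - x)), 1e-9)

  # impulse log-energy vector: coefficient m is sqrt(2/N) cos(pi m (1/2)/N)
  N <- 64
  imp <- c(1, rep(0, N - 1))
  got <- dct_ii(imp)[-1]
  m <- seq_len(N - 1)
  expect_equal(got, sqrt(2 / N) * cos(pi * m * 0.5 / N), tolerance = 1e-12)

  # brute-force summation oracle for the same coefficients
  brute <- vapply(m, function(mm)
    sqrt(2 / N) * sum(imp * cos(pi * mm * ((1:N) - 0.5) / N)), numeric(1))
  expect_equal(got, brute, tolerance = 1e-12)
})

test_that("cepstra match a naive triple-loop implementation", {
  cfg <- cepstral_config(fft_size = 64, n_coeffs = 5, n_mel_filters = 8,
                         n_gammatone_filters = 8)
  withr::with_seed(3, x <- rnorm(200))
  fm <- frame_and_window(x, frame_config(frame_ms = 8), rate = 8000)
  fm$frames <- fm$frames[1:3, , drop = FALSE]
  for (maker in list(build_mel_filterbank, build_gammatone_filterbank)) {
    bank <- maker(cfg, 8000)
    got <- cepstra_from_frames(fm, bank, cfg)
    K <- cfg$fft_size %/% 2 + 1
    naive <- matrix(0, 3, cfg$n_coeffs)
    for (t in 1:3) {
      frame <- c(fm$frames[t, ], rep(0, cfg$fft_size - fm$frame_length))
      mag <- Mod(fft(frame))[1:K]
      B <- nrow(bank$weights)
      energies <- numeric(B)
      for (b in 1:B) energies[b] <- sum(bank$weights[b, ] * mag)
      lg <- log(pmax(energies, cfg$log_floor))
      for (m in 1:cfg$n_coeffs) {
        acc <- 0
        for (n in 1:B) acc <- acc + lg[n] * cos(pi * m * (n - 0.5) / B)
        naive[t, m] <- sqrt(2 / B) * acc
      }
    }
    expect_lt(max(abs(got - naive)), 1e-9)
  }
})

test_that("uniform band energies give zero retained cepstra", {
  cfg <- cepstral_config(fft_size = 512, n_coeffs = 13, n_mel_filters = 13)
  flat <- structure(list(kind = "mel",
                         weights = matrix(1 / 257, 13, 257),
                         center_freqs = seq_len(13)),
                    class = "filter_bank")
  withr::with_seed(4, x <- rnorm(2000))
  fm <- frame_and_window(x, frame_config(), rate = 44100)
  got <- cepstra_from_frames(fm, flat, cfg)
  expect_lt(max(abs(got)), 1e-9)
})

test_that("silent frames stay finite through the log floor", {
  cfg <- cepstral_config()
  fm <- frame_and_window(rep(0, 2000), frame_config(), rate = 44100)
  bank <- build_mel_filterbank(cfg, 44100)
  got <- cepstra_from_frames(fm, bank, cfg)
  expect_true(all(is.finite(got)))
})

test_that("amplitude scaling leaves retained coefficients unchanged", {
  cfg <- cepstral_config(log_floor = 1e-300)
  bank <- build_mel_filterbank(cfg, 44100)
  withr::with_seed(6, x <- rnorm(3000))
  a <- cepstra_from_frames(frame_and_window(x, rate = 44100), bank, cfg)
  b <- cepstra_from_frames(frame_and_window(123.4 * x, rate = 44100), bank, cfg)
  expect_lt(max(abs(a - b)), 1e-9)
})

test_that("delta implements the local regression derivative", {
  const <- matrix(5, 10, 3)
  expect_equal(delta_coefficients(const, 2), matrix(0, 10, 3))

  ramp <- matrix(1:20, 20, 1)
  d <- delta_coefficients(ramp, 2)
  expect_equal(drop(d[3:18, ]), rep(1, 16))  # interior frames

  quad <- matrix((1:20)^2, 20, 1)
  dd <- delta_coefficients(delta_coefficients(quad, 2), 2)
  expect_equal(drop(dd[5:16, ]), rep(2, 12))

  expect_error(delta_coefficients(matrix(0, 0, 3), 2), "empty")
})

test_that("per-episode vectors stack 13 static + 13 delta + 13 delta-delta", {
  s <- tiny_corpus()[[1]]
  for (kind in c("mfcc", "gfcc")) {
    fv <- extract_features(s, kind)
    expect_length(fv$values, 39)
    expect_true(all(is.finite(fv$values)))
    expect_equal(fv$class_label, s$class_label)
  }
})

test_that("a stationary tone has vanishing delta blocks", {
  # tone period chosen to divide the hop (309 samples) so frames repeat
  f <- 10 * 44100 / 309
  x <- 0.5 * sin(2 * pi * f * (0:44099) / 44100)
  s <- cry_signal(x, 44100, "EXP", "healthy")
  seq39 <- extract_frame_features(s, "mfcc", preemph = FALSE)
  interior <- seq39[5:(nrow(seq39) - 4), ]
  expect_lt(max(abs(interior[, 14:39])), 1e-6)
})

test_that("too-short episodes and undersized FFTs are rejected", {
  s <- cry_signal(rnorm(600) / 10, 44100, "EXP", "healthy")
  expect_error(extract_features(s, "mfcc"), "too short")
  expect_error(cepstral_config(n_coeffs = 20, n_mel_filters = 13), "n_coeffs")
  fm <- frame_and_window(rnorm(2000), frame_config(), rate = 44100)
  cfg_small <- cepstral_config(fft_size = 256)
  bank <- build_mel_filterbank(cfg_small, 44100)
  expect_error(cepstra_from_frames(fm, bank, cfg_small), "fft_size")
})

test_that("corpus-level extraction tabulates features with labels", {
  corp <- tiny_corpus()
  fs <- extract_feature_set(corp, "mfcc")
  expect_equal(dim(fs$features), c(12, 39))
  expect_equal(as.vector(table(fs$labels)), c(6, 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fs, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 12)
  expect_true(file.exists(paste0(path, ".json")))
})
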