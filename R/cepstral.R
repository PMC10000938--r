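# MFCC and GFCC extraction: filterbank construction, log-energy cepstra via
# an orthonormal DCT-II, delta / delta-delta stacking, per-episode averaging.

#' Cepstral analysis configuration
#'
#' @param n_coeffs number of retained cepstral coefficients per frame
#'   (the 0th/DC cepstral term is excluded; coefficients `m = 1..n_coeffs`
#'   are kept).
#' @param n_mel_filters number of triangular mel filters. The default of 13
#'   mirrors the diagnostic pipeline this package reproduces; 20-40 is the
#'   broader speech-processing convention.
#' @param n_gammatone_filters number of gammatone (ERB-spaced) bands.
#' @param fft_size FFT length (>= frame length; frames are zero-padded).
#' @param delta_T half-width of the delta regression context, in frames.
#' @param log_floor positive floor applied to band energies before the log,
#'   so silent frames stay finite.
#' @return an object of class `cepstral_config`.
#' @export
cepstral_config <- function(n_coeffs = 13, n_mel_filters = 13,
                            n_gammatone_filters = 64, fft_size = 512,
                            delta_T = 2, log_floor = 1e-10) {
  assert_scalar_num(n_coeffs, "n_coeffs", lo = 1)
  assert_scalar_num(n_mel_filters, "n_mel_filters", lo = 1)
  assert_scalar_num(n_gammatone_filters, "n_gammatone_filters", lo = 1)
  assert_scalar_num(fft_size, "fft_size", lo = 8)
  assert_scalar_num(delta_T, "delta_T", lo = 1)
  assert_scalar_num(log_floor, "log_floor", lo = 0)
  if (n_coeffs > n_mel_filters || n_coeffs > n_gammatone_filters)
    stop("`n_coeffs` must not exceed the number of filters", call. = FALSE)
  structure(list(n_coeffs = as.integer(n_coeffs),
                 n_mel_filters = as.integer(n_mel_filters),
                 n_gammatone_filters = as.integer(n_gammatone_filters),
                 fft_size = as.integer(fft_size),
                 delta_T = as.integer(delta_T),
                 log_floor = log_floor),
            class = "cepstral_config")
}

#' Mel scale
#'
#' `M(f) = 1125 * ln(1 + f / 700)`, mapping frequency in Hz to perceived
#' pitch in mels.
#'
#' @param f frequency in Hz (vectorized, >= 0).
#' @return mel values.
#' @export
mel_scale <- function(f) {
  if (any(!is.finite(f)) || any(f < 0))
    stop("frequencies must be finite and non-negative", call. = FALSE)
  1125 * log(1 + f / 700)
}

#' Inverse mel scale
#' @param m mel values (>= 0).
#' @return frequency in Hz.
#' @export
mel_to_hz <- function(m) 700 * (exp(m / 1125) - 1)

#' Equivalent rectangular bandwidth at a centre frequency
#' @param f centre frequency in Hz.
#' @return ERB in Hz: `24.7 * (4.37 * f / 1000 + 1)`.
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

erb_rate <- function(f) 21.4 * log10(1 + 0.00437 * f)
erb_rate_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437

fft_bin_freqs <- function(fft_size, rate) {
  (0:(fft_size %/% 2)) * rate / fft_size
}

#' Build a triangular mel-spaced filterbank
#'
#' Filter centres are equally spaced on the mel axis between 0 Hz and the
#' Nyquist frequency; adjacent triangles overlap and each filter peaks (with
#' unit weight) at its centre frequency.
#'
#' @param cfg a [cepstral_config()].
#' @param rate sampling rate in Hz.
#' @return an object of class `filter_bank` with `kind`, `weights`
#'   (B x K matrix over the K = fft_size/2 + 1 magnitude bins) and
#'   `center_freqs`.
#' @export
build_mel_filterbank <- function(cfg = cepstral_config(), rate = 44100) {
  assert_scalar_num(rate, "rate", lo = 1000)
  B <- cfg$n_mel_filters
  freqs <- fft_bin_freqs(cfg$fft_size, rate)
  pts_hz <- mel_to_hz(seq(0, mel_scale(rate / 2), length.out = B + 2))
  if (min(diff(pts_hz)) < rate / cfg$fft_size)
    stop("fft_size too small to separate mel filter centres", call. = FALSE)
  W <- matrix(0, B, length(freqs))
  for (b in seq_len(B)) {
    lo <- pts_hz[b]; c0 <- pts_hz[b + 1]; hi <- pts_hz[b + 2]
    rise <- (freqs - lo) / (c0 - lo)
    fall <- (hi - freqs) / (hi - c0)
    W[b, ] <- pmax(0, pmin(rise, fall))
  }
  if (any(rowSums(W) == 0))
    stop("a mel filter has no FFT-bin support; increase fft_size", call. = FALSE)
  structure(list(kind = "mel", weights = W, center_freqs = pts_hz[2:(B + 1)]),
            class = "filter_bank")
}

#' Build a gammatone (ERB-spaced) filterbank
#'
#' Frequency-domain magnitude responses of 4th-order gammatone filters,
#' `(1 + ((f - fc) / b)^2)^(-2)` with `b = 1.019 * ERB(fc)`, with centre
#' frequencies equally spaced on the ERB-rate scale between 50 Hz and the
#' Nyquist frequency. Each band is normalized to unit peak magnitude.
#'
#' @param cfg a [cepstral_config()].
#' @param rate sampling rate in Hz.
#' @return a `filter_bank` with `n_gammatone_filters` bands.
#' @export
build_gammatone_filterbank <- function(cfg = cepstral_config(), rate = 44100) {
  assert_scalar_num(rate, "rate", lo = 1)
  if (rate / 2 <= 50)
    stop("sampling rate too low for the 50 Hz lower band edge", call. = FALSE)
  N <- cfg$n_gammatone_filters
  freqs <- fft_bin_freqs(cfg$fft_size, rate)
  centers <- erb_rate_inv(seq(erb_rate(50), erb_rate(rate / 2),
                              length.out = N))
  W <- matrix(0, N, length(freqs))
  for (i in seq_len(N)) {
    b <- 1.019 * erb_bandwidth(centers[i])
    resp <- (1 + ((freqs - centers[i]) / b)^2)^(-2)
    W[i, ] <- resp / max(resp)
  }
  structure(list(kind = "gammatone", weights = W, center_freqs = centers),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %s: %d bands over %d bins (%.0f-%.0f Hz)\n",
              x$kind, nrow(x$weights), ncol(x$weights),
              min(x$center_freqs), max(x$center_freqs)))
  invisible(x)
}

#' Orthonormal DCT-II of a vector
#'
#' Basis rows `s_m * cos(pi * m * (n + 1/2) / N)` for `m = 0..N-1`, with
#' `s_0 = sqrt(1/N)` and `s_m = sqrt(2/N)` otherwise. [idct_ii()] is its
#' exact inverse.
#'
#' @param x numeric vector.
#' @return coefficient vector of the same length.
#' @export
dct_ii <- function(x) drop(dct_matrix(length(x)) %*% x)

#' Inverse orthonormal DCT-II
#' @param y DCT-II coefficient vector.
#' @return reconstructed vector.
#' @export
idct_ii <- function(y) drop(t(dct_matrix(length(y))) %*% y)

dct_matrix <- function(N) {
  m <- 0:(N - 1)
  M <- sqrt(2 / N) * cos(pi * outer(m, (m + 0.5)) / N)
  M[1, ] <- sqrt(1 / N)
  M
}

# Retained-coefficient DCT rows m = 1..n_coeffs over B bands (DC excluded).
# With n_coeffs == B the last row is identically zero -- the price of a bank
# with exactly as many filters as requested coefficients.
cepstral_basis <- function(n_coeffs, B) {
  sqrt(2 / B) * cos(pi * outer(seq_len(n_coeffs), (seq_len(B) - 0.5)) / B)
}

#' Per-frame cepstral coefficients from windowed frames
#'
#' Each frame is zero-padded to `fft_size`, magnitude-transformed, mapped to
#' band energies through the filterbank, floored at `log_floor`, logged, and
#' decorrelated with an orthonormal DCT-II; coefficients `m = 1..n_coeffs`
#' (DC excluded) are retained. The identical code path serves mel and
#' gammatone banks.
#'
#' @param fm a `frame_matrix` from [frame_and_window()].
#' @param bank a `filter_bank` built for the same `fft_size` and rate.
#' @param cfg a [cepstral_config()].
#' @return T x `n_coeffs` matrix of static cepstra.
#' @export
cepstra_from_frames <- function(fm, bank, cfg = cepstral_config()) {
  if (!inherits(fm, "frame_matrix")) stop("`fm` must be a frame_matrix", call. = FALSE)
  L <- fm$frame_length
  if (cfg$fft_size < L)
    stop("fft_size must be at least the frame length", call. = FALSE)
  K <- cfg$fft_size %/% 2 + 1
  if (ncol(bank$weights) != K)
    stop("filter bank does not match fft_size", call. = FALSE)
  padded <- t(cbind(fm$frames,
                    matrix(0, nrow(fm$frames), cfg$fft_size - L)))
  spec <- Mod(stats::mvfft(padded))[seq_len(K), , drop = FALSE]
  E <- bank$weights %*% spec                 # B x T band energies
  E <- pmax(E, cfg$log_floor)
  Lg <- log(E)
  basis <- cepstral_basis(cfg$n_coeffs, nrow(bank$weights))
  t(basis %*% Lg)                            # T x n_coeffs
}

#' Delta (local regression derivative) of a coefficient sequence
#'
#' `delta_c(n) = sum_{i=-T..T} i * c(n + i) / (2 * sum_{i=1..T} i^2)` with
#' edge frames replicated. Applying it twice yields delta-delta coefficients.
#'
#' @param x T x M matrix of per-frame coefficients (a vector is treated as a
#'   single-column sequence).
#' @param T_ctx regression half-width in frames (>= 1).
#' @return matrix of the same shape.
#' @export
delta_coefficients <- function(x, T_ctx = 2) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (!nrow(x)) stop("empty coefficient sequence", call. = FALSE)
  assert_scalar_num(T_ctx, "T_ctx", lo = 1)
  T_ctx <- as.integer(T_ctx)
  n <- nrow(x)
  denom <- 2 * sum(seq_len(T_ctx)^2)
  out <- matrix(0, n, ncol(x))
  for (i in seq(-T_ctx, T_ctx)) {
    if (i == 0) next
    idx <- pmin(pmax(seq_len(n) + i, 1L), n)
    out <- out + i * x[idx, , drop = FALSE]
  }
  out / denom
}

#' Extract a per-episode cepstral feature vector
#'
#' Runs pre-emphasis (optional), framing/windowing, static cepstra, and
#' delta / delta-delta stacking, then averages over frames to one vector of
#' width `3 * n_coeffs` (39 by default: 13 static, 13 delta, 13 delta-delta).
#'
#' @param signal a [cry_signal()].
#' @param feature_kind `"mfcc"` or `"gfcc"`.
#' @param cfg a [cepstral_config()].
#' @param frame_cfg a [frame_config()].
#' @param preemph apply pre-emphasis before framing (used identically for
#'   both feature kinds by default).
#' @param bank optional pre-built `filter_bank` (rebuilt from `cfg` if NULL).
#' @return an object of class `feature_vector` with `values` (length
#'   `3 * n_coeffs`), `feature_kind`, `class_label`, `episode`, `subject_id`.
#' @export
extract_features <- function(signal, feature_kind = c("mfcc", "gfcc"),
                             cfg = cepstral_config(),
                             frame_cfg = frame_config(),
                             preemph = TRUE, bank = NULL) {
  feature_kind <- match.arg(feature_kind)
  seq39 <- extract_frame_features(signal, feature_kind, cfg, frame_cfg,
                                  preemph, bank)
  structure(list(values = colMeans(seq39), feature_kind = feature_kind,
                 class_label = signal$class_label, episode = signal$episode,
                 subject_id = signal$subject_id),
            class = "feature_vector")
}

#' Extract the per-frame stacked feature sequence of one episode
#'
#' The sequence form of [extract_features()]: a T x `3 * n_coeffs` matrix
#' `[static | delta | delta-delta]`, the natural input for a sequence
#' classifier.
#'
#' @inheritParams extract_features
#' @return T x `3 * n_coeffs` numeric matrix.
#' @export
extract_frame_features <- function(signal, feature_kind = c("mfcc", "gfcc"),
                                   cfg = cepstral_config(),
                                   frame_cfg = frame_config(),
                                   preemph = TRUE, bank = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (!inherits(signal, "cry_signal"))
    stop("`signal` must be a cry_signal", call. = FALSE)
  x <- signal$samples
  if (preemph) x <- preemphasize(x, frame_cfg$preemphasis_alpha)
  fm <- frame_and_window(x, frame_cfg, rate = signal$rate)
  if (nrow(fm$frames) < 2 * cfg$delta_T + 1)
    stop("episode too short for the delta context", call. = FALSE)
  if (is.null(bank)) {
    bank <- if (feature_kind == "mfcc") build_mel_filterbank(cfg, signal$rate)
            else build_gammatone_filterbank(cfg, signal$rate)
  }
  static <- cepstra_from_frames(fm, bank, cfg)
  d1 <- delta_coefficients(static, cfg$delta_T)
  d2 <- delta_coefficients(d1, cfg$delta_T)
  cbind(static, d1, d2)
}

#' Extract features for a whole corpus
#'
#' @param corpus list of [cry_signal()] objects.
#' @param feature_kind `"mfcc"` or `"gfcc"`.
#' @param cfg,frame_cfg analysis configurations.
#' @param preemph apply pre-emphasis.
#' @param sequences also return the per-frame sequences (for the LSTM path).
#' @return a list with `features` (n x `3 * n_coeffs` matrix, one row per
#'   episode), `labels` (factor), `subjects`, `episodes`, and optionally
#'   `sequences` (list of T_i x D matrices).
#' @export
extract_feature_set <- function(corpus, feature_kind = c("mfcc", "gfcc"),
                                cfg = cepstral_config(),
                                frame_cfg = frame_config(),
                                preemph = TRUE, sequences = FALSE) {
  feature_kind <- match.arg(feature_kind)
  if (!length(corpus)) stop("empty corpus", call. = FALSE)
  rate <- corpus[[1]]$rate
  bank <- if (feature_kind == "mfcc") build_mel_filterbank(cfg, rate)
          else build_gammatone_filterbank(cfg, rate)
  seqs <- lapply(corpus, extract_frame_features, feature_kind = feature_kind,
                 cfg = cfg, frame_cfg = frame_cfg, preemph = preemph,
                 bank = bank)
  feats <- do.call(rbind, lapply(seqs, colMeans))
  colnames(feats) <- sprintf("%s_%02d", feature_kind, seq_len(ncol(feats)))
  out <- list(features = feats, labels = corpus_labels(corpus),
              subjects = vapply(corpus, function(s) s$subject_id, character(1)),
              episodes = vapply(corpus, function(s) s$episode, character(1)))
  if (sequences) out$sequences <- seqs
  out
}

#' Write a feature table to CSV with a JSON config sidecar
#'
#' One row per episode (`subject_id`, `episode`, `class_label`, `f1..fD`);
#' the cepstral configuration is recorded next to it as `<path>.json`.
#'
#' @param fs result of [extract_feature_set()].
#' @param path CSV output path.
#' @param cfg the [cepstral_config()] used (stored for provenance).
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fs, path, cfg = cepstral_config()) {
  df <- data.frame(subject_id = fs$subjects, episode = fs$episodes,
                   class_label = as.character(fs$labels),
                   fs$features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(unclass(cfg), paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
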