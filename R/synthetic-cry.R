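# Seeded source-filter generator of cry-like audio. Stands in for a clinical
# corpus: healthy newborn cries are voiced at F0 400-600 Hz (mean ~450 Hz)
# and last about 1-1.5 s; pathologic cries are modelled as lower-pitched and
# hoarse (raised jitter/shimmer, occasional subharmonics).

#' Specification of a synthetic cry class
#'
#' Bundles the acoustic parameters of one cry population. Defaults depend on
#' `class_label` and `episode`: healthy expiratory cries are voiced in
#' 400-600 Hz and last 1-1.5 s; the pathologic default lowers the F0 band to
#' 250-400 Hz and raises jitter (3%) and shimmer (10%) with occasional
#' subharmonic injection, operationalizing "low-pitched" and "hoarse".
#' Inspiratory (INSV) episodes are shorter (0.2-0.6 s) and breathier (lower
#' SNR).
#'
#' @param class_label `"healthy"` or `"pathologic"`.
#' @param episode `"EXP"` (expiratory) or `"INSV"` (inspiratory).
#' @param f0_range fundamental-frequency interval in Hz (low, high).
#' @param jitter_pct cycle-to-cycle F0 perturbation, percent (>= 0).
#' @param shimmer_pct cycle-to-cycle amplitude perturbation, percent (>= 0).
#' @param duration_range episode duration interval in seconds, within (0.1, 5].
#' @param snr_db signal-to-background-noise ratio in dB.
#' @param formants list of `c(center_hz, bandwidth_hz)` resonances of the
#'   vocal-tract filter. The three defaults (1.1, 3.3, 5.5 kHz, 200 Hz wide)
#'   are generic infant-tract stand-ins, not physiological claims.
#' @param subharmonic_prob probability that a cry carries an F0/2 subharmonic
#'   (alternate glottal cycles attenuated).
#' @return an object of class `cry_spec`.
#' @export
cry_spec <- function(class_label = c("healthy", "pathologic"),
                     episode = c("EXP", "INSV"),
                     f0_range = NULL,
                     jitter_pct = NULL,
                     shimmer_pct = NULL,
                     duration_range = NULL,
                     snr_db = NULL,
                     formants = list(c(1100, 200), c(3300, 200), c(5500, 200)),
                     subharmonic_prob = NULL) {
  class_label <- match.arg(class_label)
  episode <- match.arg(episode)
  healthy <- class_label == "healthy"
  f0_range <- f0_range %||% if (healthy) c(400, 600) else c(250, 400)
  jitter_pct <- jitter_pct %||% if (healthy) 1 else 3
  shimmer_pct <- shimmer_pct %||% if (healthy) 3 else 10
  duration_range <- duration_range %||%
    if (episode == "EXP") c(1, 1.5) else c(0.2, 0.6)
  snr_db <- snr_db %||% if (episode == "EXP") 20 else 10
  subharmonic_prob <- subharmonic_prob %||% if (healthy) 0 else 0.3

  if (!is.numeric(f0_range) || length(f0_range) != 2 || any(!is.finite(f0_range)) ||
      f0_range[1] <= 0 || f0_range[1] >= f0_range[2])
    stop("`f0_range` must be a positive interval with low < high", call. = FALSE)
  if (!is.numeric(duration_range) || length(duration_range) != 2 ||
      any(!is.finite(duration_range)) ||
      duration_range[1] <= 0.1 || duration_range[2] > 5 ||
      duration_range[1] > duration_range[2])
    stop("`duration_range` must lie within (0.1, 5] seconds", call. = FALSE)
  assert_scalar_num(jitter_pct, "jitter_pct", lo = 0)
  assert_scalar_num(shimmer_pct, "shimmer_pct", lo = 0)
  assert_scalar_num(snr_db, "snr_db")
  assert_scalar_num(subharmonic_prob, "subharmonic_prob", lo = 0, hi = 1)
  if (!is.list(formants) || !length(formants) ||
      !all(vapply(formants, function(f)
        is.numeric(f) && length(f) == 2 && all(is.finite(f)) && all(f > 0),
        logical(1))))
    stop("`formants` must be a list of c(center_hz, bandwidth_hz) pairs",
         call. = FALSE)

  structure(list(class_label = class_label, episode = episode,
                 f0_range = f0_range, jitter_pct = jitter_pct,
                 shimmer_pct = shimmer_pct, duration_range = duration_range,
                 snr_db = snr_db, formants = formants,
                 subharmonic_prob = subharmonic_prob),
            class = "cry_spec")
}

#' Construct a cry-signal object
#'
#' @param samples numeric amplitudes in `[-1, 1]`.
#' @param rate sampling rate in Hz.
#' @param episode `"EXP"` or `"INSV"`.
#' @param class_label `"healthy"` or `"pathologic"`.
#' @param subject_id opaque subject identifier.
#' @return an object of class `cry_signal`.
#' @export
cry_signal <- function(samples, rate, episode, class_label,
                       subject_id = NA_character_) {
  stopifnot(is.numeric(samples), rate > 0)
  if (length(samples) && max(abs(samples)) > 1 + 1e-12)
    stop("cry samples must lie in [-1, 1]", call. = FALSE)
  structure(list(samples = as.numeric(samples), rate = rate,
                 episode = episode, class_label = class_label,
                 subject_id = subject_id),
            class = "cry_signal")
}

#' @export
print.cry_signal <- function(x, ...) {
  cat(sprintf("<cry_signal> %s %s  %.3f s @ %d Hz  subject=%s\n",
              x$class_label, x$episode, length(x$samples) / x$rate,
              as.integer(x$rate), x$subject_id))
  invisible(x)
}

#' Synthesize one cry episode
#'
#' Source-filter synthesis: a glottal pulse train at an F0 drawn from the
#' spec's band, with per-cycle jitter and shimmer (and optional alternate-
#' cycle attenuation producing an F0/2 subharmonic), is passed through a
#' cascade of second-order formant resonators, amplitude-enveloped, and mixed
#' with Gaussian background noise at the requested SNR. The result is peak-
#' normalized to 0.9 and quantized to the 16-bit grid, so emitted audio
#' round-trips through [write_wav()]/[read_wav()] bit-exactly.
#'
#' Deterministic: the same `(spec, seed)` pair always yields bit-identical
#' samples.
#'
#' @param spec a [cry_spec()].
#' @param seed integer seed.
#' @param rate sampling rate in Hz (default 44100).
#' @param subject_id optional subject identifier carried on the signal.
#' @return a [cry_signal()].
#' @export
generate_cry <- function(spec, seed, rate = 44100, subject_id = NA_character_) {
  if (!inherits(spec, "cry_spec")) stop("`spec` must be a cry_spec", call. = FALSE)
  assert_scalar_num(seed, "seed")
  assert_scalar_num(rate, "rate", lo = 1000)
  withr::with_seed(as.integer(seed), {
    dur <- runif(1, spec$duration_range[1], spec$duration_range[2])
    n <- round(dur * rate)
    f0 <- runif(1, spec$f0_range[1], spec$f0_range[2])
    sub_on <- runif(1) < spec$subharmonic_prob

    # glottal pulse train with per-cycle jitter/shimmer
    pos <- integer(0); amp <- numeric(0)
    cur <- 1L; cyc <- 0L
    while (cur <= n) {
      a <- max(0.2, 1 + spec$shimmer_pct / 100 * rnorm(1))
      if (sub_on && cyc %% 2L == 1L) a <- a * 0.55
      pos <- c(pos, cur); amp <- c(amp, a)
      f_cyc <- f0 * (1 + spec$jitter_pct / 100 *
                       max(-3, min(3, rnorm(1))))
      cur <- cur + max(4L, as.integer(round(rate / f_cyc)))
      cyc <- cyc + 1L
    }
    x <- numeric(n)
    x[pos] <- amp

    # vocal-tract filter: cascade of 2nd-order resonators
    for (fm in spec$formants) {
      r <- exp(-pi * fm[2] / rate)
      th <- 2 * pi * fm[1] / rate
      x <- as.numeric(stats::filter(x, c(2 * r * cos(th), -r * r),
                                    method = "recursive"))
    }

    # amplitude envelope: soft rise and fall over the episode
    tt <- seq(0, 1, length.out = n)
    x <- x * sin(pi * tt)^0.35

    # background noise at the requested SNR
    p_sig <- mean(x^2)
    sigma <- sqrt(p_sig / 10^(spec$snr_db / 10))
    x <- x + rnorm(n, 0, sigma)

    x <- 0.9 * x / max(abs(x))
    x <- round(x * 32767) / 32767
    cry_signal(x, rate, spec$episode, spec$class_label, subject_id)
  })
}

#' Estimate fundamental frequency by autocorrelation
#'
#' Uses the central portion of the episode (where the envelope is strong) and
#' returns the frequency of the dominant autocorrelation peak in
#' `[fmin, fmax]`.
#'
#' @param signal a [cry_signal()] or numeric vector.
#' @param rate sampling rate (taken from the signal if omitted).
#' @param fmin,fmax F0 search band in Hz.
#' @return estimated F0 in Hz.
#' @export
estimate_f0 <- function(signal, rate = NULL, fmin = 150, fmax = 1000) {
  if (inherits(signal, "cry_signal")) {
    rate <- signal$rate
    x <- signal$samples
  } else {
    x <- as.numeric(signal)
    if (is.null(rate)) stop("`rate` required for a bare sample vector", call. = FALSE)
  }
  n <- length(x)
  lo <- max(1L, floor(n * 0.2)); hi <- ceiling(n * 0.8)
  x <- x[lo:hi]
  x <- x - mean(x)
  lag_max <- as.integer(round(rate / fmin))
  lag_min <- as.integer(round(rate / fmax))
  if (length(x) <= lag_max + 1)
    stop("signal too short for F0 estimation", call. = FALSE)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  lags <- lag_min:lag_max
  best <- lags[which.max(ac[lags + 1L])]
  rate / best
}

#' Generate a balanced synthetic corpus
#'
#' Emits exactly `n_per_class` signals per class (healthy first, then
#' pathologic), with subjects assigned round-robin within each class and
#' per-signal seeds derived from the master seed by a counter scheme, so the
#' corpus is a pure function of its arguments.
#'
#' @param n_per_class number of episodes per class (>= 1).
#' @param episode `"EXP"` or `"INSV"`.
#' @param seed master integer seed.
#' @param subjects_per_class number of distinct subject ids per class
#'   (<= `n_per_class`).
#' @param healthy_spec,pathologic_spec optional [cry_spec()] overrides for the
#'   two classes (episode defaults are used otherwise).
#' @param rate sampling rate in Hz.
#' @return a list of [cry_signal()] objects of length `2 * n_per_class`.
#' @export
generate_corpus <- function(n_per_class, episode = c("EXP", "INSV"), seed = 1,
                            subjects_per_class = min(n_per_class, 10),
                            healthy_spec = NULL, pathologic_spec = NULL,
                            rate = 44100) {
  episode <- match.arg(episode)
  if (!is.numeric(n_per_class) || n_per_class < 1)
    stop("`n_per_class` must be >= 1", call. = FALSE)
  if (subjects_per_class > n_per_class)
    stop("`subjects_per_class` must be <= `n_per_class`", call. = FALSE)
  specs <- list(
    healthy = healthy_spec %||% cry_spec("healthy", episode),
    pathologic = pathologic_spec %||% cry_spec("pathologic", episode)
  )
  out <- vector("list", 2L * n_per_class)
  k <- 0L
  for (cls in c("healthy", "pathologic")) {
    prefix <- if (cls == "healthy") "H" else "P"
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      sid <- sprintf("%s%03d", prefix, ((i - 1L) %% subjects_per_class) + 1L)
      out[[k]] <- generate_cry(specs[[cls]], derive_seed(seed, k), rate = rate,
                               subject_id = sid)
    }
  }
  out
}

#' Corpus labels as a factor
#'
#' @param corpus list of [cry_signal()] objects.
#' @return factor with levels `healthy`, `pathologic`.
#' @export
corpus_labels <- function(corpus) {
  factor(vapply(corpus, function(s) s$class_label, character(1)),
         levels = c("healthy", "pathologic"))
}

#' Write a corpus to disk as WAV + labels + manifest
#'
#' One WAV and one WaveSurfer-style label file (`start end label`, seconds)
#' per episode, plus a `manifest.csv` with columns `path`, `label_path`,
#' `subject_id`, `episode`, `class_label`.
#'
#' @param corpus list of [cry_signal()] objects.
#' @param dir output directory (created if absent).
#' @return path of the manifest, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(corpus), function(i) {
    s <- corpus[[i]]
    stem <- sprintf("cry_%04d", i)
    wav <- file.path(dir, paste0(stem, ".wav"))
    lab <- file.path(dir, paste0(stem, ".lab"))
    write_wav(s$samples, s$rate, wav)
    writeLines(sprintf("%.6f %.6f %s", 0, length(s$samples) / s$rate,
                       s$episode), lab)
    data.frame(path = wav, label_path = lab, subject_id = s$subject_id,
               episode = s$episode, class_label = s$class_label,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a corpus back from a manifest
#'
#' @param manifest_path path to a `manifest.csv` written by [write_corpus()].
#' @return list of [cry_signal()] objects.
#' @export
read_corpus <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  out <- list()
  for (i in seq_len(nrow(man))) {
    eps <- read_episodes(resolve(man$path[i]), resolve(man$label_path[i]),
                         class_label = man$class_label[i],
                         subject_id = man$subject_id[i])
    out <- c(out, eps)
  }
  out
}
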