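# Ingestion and short-time analysis front end: segment-label reading,
# pre-emphasis, framing, Hamming windowing.

#' Framing configuration
#'
#' @param frame_ms frame length in milliseconds.
#' @param overlap fractional overlap between consecutive frames, in `[0, 1)`.
#' @param window window type; only `"hamming"` is supported.
#' @param preemphasis_alpha pre-emphasis coefficient in `[0, 1)`.
#' @return an object of class `frame_config`.
#' @export
frame_config <- function(frame_ms = 10, overlap = 0.3, window = "hamming",
                         preemphasis_alpha = 0.97) {
  assert_scalar_num(frame_ms, "frame_ms", lo = 1e-6)
  assert_scalar_num(overlap, "overlap", lo = 0)
  if (overlap >= 1) stop("`overlap` must be in [0, 1)", call. = FALSE)
  window <- match.arg(window, "hamming")
  assert_scalar_num(preemphasis_alpha, "preemphasis_alpha", lo = 0)
  if (preemphasis_alpha >= 1)
    stop("`preemphasis_alpha` must be in [0, 1)", call. = FALSE)
  structure(list(frame_ms = frame_ms, overlap = overlap, window = window,
                 preemphasis_alpha = preemphasis_alpha),
            class = "frame_config")
}

#' First-order pre-emphasis
#'
#' `y[1] = x[1]; y[t] = x[t] - alpha * x[t-1]`. A linear operation with the
#' same length as its input.
#'
#' @param x numeric amplitude vector.
#' @param alpha coefficient in `[0, 1]` (the closed upper end admits the pure
#'   first-difference boundary case).
#' @return pre-emphasized vector.
#' @export
preemphasize <- function(x, alpha = 0.97) {
  stopifnot(is.numeric(x))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha > 1)
    stop("`alpha` must be in [0, 1]", call. = FALSE)
  if (!length(x)) return(numeric(0))
  c(x[1], x[-1] - alpha * x[-length(x)])
}

#' Split a signal into Hamming-windowed frames
#'
#' Frame length is `L = round(frame_ms * rate / 1000)` samples and the hop is
#' `round(L * (1 - overlap))`; a trailing partial frame is dropped. The
#' symmetric Hamming window `0.54 - 0.46 cos(2*pi*k / (L-1))` is applied to
#' every frame.
#'
#' @param signal a [cry_signal()] or numeric vector.
#' @param cfg a [frame_config()].
#' @param rate sampling rate, required when `signal` is a bare vector.
#' @return an object of class `frame_matrix` with elements `frames`
#'   (T x L matrix), `rate`, `hop`, and `frame_length`.
#' @export
frame_and_window <- function(signal, cfg = frame_config(), rate = NULL) {
  if (inherits(signal, "cry_signal")) {
    x <- signal$samples
    rate <- signal$rate
  } else {
    x <- as.numeric(signal)
    if (is.null(rate)) stop("`rate` required for a bare sample vector", call. = FALSE)
  }
  L <- as.integer(round(cfg$frame_ms * rate / 1000))
  hop <- as.integer(round(L * (1 - cfg$overlap)))
  n <- length(x)
  if (n < L) stop("episode too short: fewer samples than one frame", call. = FALSE)
  n_frames <- (n - L) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(starts, seq_len(L), `+`)
  frames <- matrix(x[idx], nrow = n_frames, ncol = L)
  w <- as.numeric(signal::hamming(L))
  frames <- sweep(frames, 2L, w, `*`)
  structure(list(frames = frames, rate = rate, hop = hop, frame_length = L),
            class = "frame_matrix")
}

#' @export
print.frame_matrix <- function(x, ...) {
  cat(sprintf("<frame_matrix> %d frames x %d samples, hop %d @ %d Hz\n",
              nrow(x$frames), x$frame_length, x$hop, as.integer(x$rate)))
  invisible(x)
}

parse_label_file <- function(label_path, duration) {
  lines <- readLines(label_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(data.frame(start = numeric(0), end = numeric(0),
                                        label = character(0)))
  segs <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) < 3)
      stop(sprintf("label line %d is not 'start end label': %s", i, lines[i]),
           call. = FALSE)
    start <- suppressWarnings(as.numeric(parts[1]))
    end <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(start) || is.na(end) || start < 0 || start >= end)
      stop(sprintf("label line %d has invalid times: %s", i, lines[i]),
           call. = FALSE)
    if (end > duration + 1e-6)
      stop(sprintf("label line %d ends after the audio (%.3f > %.3f s)",
                   i, end, duration), call. = FALSE)
    data.frame(start = start, end = end, label = parts[3], line = i)
  })
  segs <- do.call(rbind, segs)
  o <- order(segs$start)
  so <- segs[o, ]
  if (nrow(so) > 1 && any(so$start[-1] < so$end[-nrow(so)] - 1e-9)) {
    bad <- which(so$start[-1] < so$end[-nrow(so)] - 1e-9)[1] + 1L
    stop(sprintf("label line %d overlaps the previous segment", so$line[bad]),
         call. = FALSE)
  }
  segs
}

#' Read labelled cry episodes from a WAV file
#'
#' Slices the audio according to a WaveSurfer-style transcription file (one
#' `start end label` line per segment, times in seconds). Segments labelled
#' `EXP` or `INSV` become one [cry_signal()] each; any other label (silence,
#' noise, ...) is skipped. Overlapping or out-of-range segments raise an
#' error naming the offending line.
#'
#' @param wav_path path to a 16-bit PCM mono WAV file.
#' @param label_path path to the matching label file.
#' @param class_label,subject_id metadata attached to every returned episode.
#' @param allow_any_rate if `FALSE` (default), non-44.1 kHz audio is rejected.
#' @return list of [cry_signal()] objects (possibly empty).
#' @export
read_episodes <- function(wav_path, label_path,
                          class_label = NA_character_,
                          subject_id = NA_character_,
                          allow_any_rate = FALSE) {
  wav <- read_wav(wav_path)
  if (!allow_any_rate && wav$rate != 44100)
    stop(sprintf("expected 44100 Hz audio, got %d Hz (set allow_any_rate = TRUE to override)",
                 wav$rate), call. = FALSE)
  duration <- length(wav$samples) / wav$rate
  segs <- parse_label_file(label_path, duration)
  keep <- segs$label %in% c("EXP", "INSV")
  segs <- segs[keep, , drop = FALSE]
  lapply(seq_len(nrow(segs)), function(i) {
    a <- as.integer(round(segs$start[i] * wav$rate)) + 1L
    b <- as.integer(round(segs$end[i] * wav$rate))
    cry_signal(wav$samples[a:b], wav$rate, segs$label[i], class_label,
               subject_id)
  })
}
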