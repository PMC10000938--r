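# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a master seed and a counter
#'
#' Counter-based derivation keeps corpora and experiment stages reproducible
#' under reordering: signal i always receives the same seed regardless of how
#' many other signals were generated before it.
#'
#' @param master integer master seed.
#' @param counter non-negative integer counter.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, counter) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(counter), length(counter) == 1L, counter >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(master) %% m) * 69069 + (counter + 1) * 1013904223
  as.integer(s %% (m - 1) + 1)
}

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a finite number in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  invisible(x)
}
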