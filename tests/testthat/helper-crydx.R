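# Shared fixtures, built in code. Short-duration specs keep unit tests fast;
# the full study-scale conditions live in the acceptance tests.

short_spec <- function(class_label = "healthy", episode = "EXP", ...) {
  cry_spec(class_label, episode, duration_range = c(0.3, 0.45), ...)
}

# A small cached corpus of short episodes (6 per class).
tiny_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_corpus(6, "EXP", seed = 404,
                                healthy_spec = short_spec("healthy"),
                                pathologic_spec = short_spec("pathologic"))
    cache
  }
})

# Gaussian blob sequences for classifier tests: class means differ by `sep`.
blob_sequences <- function(n_per_class, t_len = 20, dims = 5, sep = 1.5,
                           seed = 1) {
  withr::with_seed(seed, {
    seqs <- c(lapply(seq_len(n_per_class),
                     function(i) matrix(rnorm(t_len * dims, 0), t_len, dims)),
              lapply(seq_len(n_per_class),
                     function(i) matrix(rnorm(t_len * dims, sep), t_len, dims)))
    list(sequences = seqs,
         labels = factor(rep(c("healthy", "pathologic"), each = n_per_class)))
  })
}
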