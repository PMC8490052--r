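# Small, fast study configurations reused across tests. Generation happens
# at test time; nothing is stored on disk.

small_config <- function(seed = 1L, ...) {
  args <- list(n_trials_per_class = 20, n_channels = 2, fs = 256,
               trial_duration = 2, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}

# Feature matrix with known ground truth: 3 informative columns (class mean
# shift) + 8 pure-noise columns, balanced labels.
informative_matrix <- function(n = 400, shift = 1, seed = 1L) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    labels <- rep(c("hand", "feet"), each = n / 2)
    x <- matrix(rnorm(n * 11), n, 11)
    for (j in 1:3) x[labels == "feet", j] <- x[labels == "feet", j] + shift
    feature_matrix(x, labels)
  })
}

# A deterministic preprocessed-scale trial (channels x samples) at 200 Hz.
tone_trial <- function(freqs = c(10, 20), n = 1000, fs = 200) {
  t <- seq_len(n) / fs
  do.call(rbind, lapply(freqs, function(f) sin(2 * pi * f * t)))
}
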