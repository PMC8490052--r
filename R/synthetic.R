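#' Configuration for the synthetic motor-imagery EEG generator
#'
#' Defines the study conditions the generator emulates: trial-structured
#' multichannel EEG (5 s at 512 Hz over central electrodes) consisting of
#' 1/f background noise plus band-limited theta/alpha/beta/gamma
#' oscillations, with a class-dependent modulation of alpha and beta
#' amplitude separating "hand" from "feet" trials — the
#' event-related-desynchronization/synchronization (ERD/ERS) contrast that
#' motor-imagery classifiers exploit.
#'
#' @param n_trials_per_class trials per class (default 80, i.e. 160 total,
#'   mirroring one recording session of 8 runs x 20 trials).
#' @param n_channels number of channels (default 3, labeled C3/Cz/C4).
#' @param fs sampling rate in Hz (default 512).
#' @param trial_duration trial length in seconds (default 5).
#' @param band_amplitudes named numeric vector of baseline oscillation
#'   amplitudes in microvolts for `theta`, `alpha`, `beta`, `gamma`.
#' @param class_effect named numeric vector of multiplicative amplitude
#'   factors applied to class "feet" relative to class "hand". The default
#'   (alpha x1.4, beta x0.7) mimics alpha synchronization together with beta
#'   desynchronization; band power scales by the square of the factor.
#' @param noise_exponent spectral slope of the 1/f^a background (default 1).
#' @param noise_scale RMS of the background noise in microvolts (default 3).
#' @param amplitude_jitter standard deviation (log scale) of the per-trial,
#'   per-band lognormal amplitude fluctuation shared across channels
#'   (default 0.15). Band power in real recordings varies substantially from
#'   trial to trial; the jitter is symmetric on the log scale, so the
#'   between-class mean-power ratio stays at `class_effect^2`.
#' @param lateralization optional extra amplitude factor applied to alpha on
#'   the first channel (C3) for "hand" and the last (C4) for "feet";
#'   default 1 (off).
#' @param seed integer seed; identical configs generate bit-identical data.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_trials_per_class = 80,
                             n_channels = 3,
                             fs = 512,
                             trial_duration = 5,
                             band_amplitudes = c(theta = 4, alpha = 8,
                                                 beta = 6, gamma = 2),
                             class_effect = c(alpha = 1.4, beta = 0.7),
                             noise_exponent = 1,
                             noise_scale = 3,
                             amplitude_jitter = 0.15,
                             lateralization = 1,
                             seed = 1L) {
  stopifnot(n_trials_per_class >= 1, fs > 0, trial_duration > 0,
            n_channels >= 1, noise_scale >= 0, amplitude_jitter >= 0,
            lateralization > 0)
  bands <- names(.mipower_bands)
  amp <- setNames(rep(0, length(bands)), bands)
  amp[names(band_amplitudes)] <- band_amplitudes
  if (any(amp < 0)) stop("band amplitudes must be >= 0")
  eff <- setNames(rep(1, length(bands)), bands)
  eff[names(class_effect)] <- class_effect
  if (any(eff <= 0)) stop("class_effect factors must be > 0")
  structure(
    list(n_trials_per_class = as.integer(n_trials_per_class),
         n_channels = as.integer(n_channels), fs = fs,
         trial_duration = trial_duration, band_amplitudes = amp,
         class_effect = eff, noise_exponent = noise_exponent,
         noise_scale = noise_scale, amplitude_jitter = amplitude_jitter,
         lateralization = lateralization,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a narrow-band oscillation
#'
#' Produces a single-channel rhythm as a random-phase sinusoid (carrier
#' frequency drawn inside the band) under a slowly drifting amplitude
#' envelope, so its spectral energy is confined to the named band and its
#' RMS is proportional to `amplitude`. Consumes the current RNG stream; seed
#' with [set.seed()] for reproducibility.
#'
#' @param band one of `"theta"` (4-7.5 Hz), `"alpha"` (8-12 Hz), `"beta"`
#'   (13-25 Hz), `"gamma"` (26-45 Hz).
#' @param amplitude peak amplitude in microvolts (RMS is about
#'   `amplitude / sqrt(2)`).
#' @param fs sampling rate in Hz.
#' @param duration length in seconds.
#' @return Numeric waveform of `round(fs * duration)` samples.
#' @export
band_oscillation <- function(band, amplitude, fs, duration) {
  if (!band %in% names(.mipower_bands))
    stop("unknown band '", band, "'; valid bands: ",
         paste(names(.mipower_bands), collapse = ", "))
  if (amplitude < 0) stop("amplitude must be >= 0")
  n <- round(fs * duration)
  t <- seq_len(n) / fs
  lim <- .mipower_bands[[band]]
  # keep the carrier off the band edges so sideband leakage stays in-band
  margin <- 0.1 * diff(lim)
  f0 <- runif(1, lim[1] + margin, lim[2] - margin)
  phase <- runif(1, 0, 2 * pi)
  # slow (<0.4 Hz) multiplicative drift: three random-phase cosines
  fd <- runif(3, 0.05, 0.4)
  pd <- runif(3, 0, 2 * pi)
  env <- 1 + 0.25 * rowMeans(cos(outer(t, 2 * pi * fd) +
                                 matrix(pd, n, 3, byrow = TRUE)))
  amplitude * env * sin(2 * pi * f0 * t + phase)
}

# 1/f^a background noise with unit RMS, via spectral shaping of white
# Gaussian noise (DC removed).
pink_noise <- function(n, exponent) {
  white <- rnorm(n)
  spec <- fft(white)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1)))
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(fft(spec * shape, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Generate a single synthetic EEG trial
#'
#' Sums the four band oscillations (amplitudes scaled by the class effect
#' when `label = "feet"`) with 1/f background noise, independently phased
#' per channel. Consumes the current RNG stream.
#'
#' @param config a [synthetic_config()].
#' @param label `"hand"` or `"feet"`.
#' @return Numeric matrix, channels x samples, in microvolts.
#' @export
generate_trial <- function(config, label = c("hand", "feet")) {
  label <- match.arg(label)
  n <- round(config$fs * config$trial_duration)
  out <- matrix(0, config$n_channels, n)
  # per-trial rhythm-strength fluctuation, shared across channels
  jit <- exp(rnorm(length(.mipower_bands), 0, config$amplitude_jitter))
  names(jit) <- names(.mipower_bands)
  for (ch in seq_len(config$n_channels)) {
    x <- numeric(n)
    for (band in names(.mipower_bands)) {
      a <- config$band_amplitudes[[band]] * jit[[band]]
      if (label == "feet") a <- a * config$class_effect[[band]]
      if (band == "alpha" && config$lateralization != 1) {
        lat_ch <- if (label == "hand") 1L else config$n_channels
        if (ch == lat_ch) a <- a * config$lateralization
      }
      if (a > 0)
        x <- x + band_oscillation(band, a, config$fs, config$trial_duration)
    }
    if (config$noise_scale > 0)
      x <- x + config$noise_scale * pink_noise(n, config$noise_exponent)
    out[ch, ] <- x
  }
  out
}

#' Generate a balanced, labeled synthetic trial set
#'
#' Produces `2 * n_trials_per_class` trials in shuffled order. The full
#' output is a pure function of the configuration (including its seed); the
#' caller's RNG state is left untouched.
#'
#' @param config a [synthetic_config()].
#' @param subject_id identifier stored on the result.
#' @return A [trialset()].
#' @export
generate_trialset <- function(config, subject_id = "S01") {
  stopifnot(inherits(config, "synthetic_config"))
  with_private_seed(config$seed, {
    n_per <- config$n_trials_per_class
    labels <- rep(c("hand", "feet"), each = n_per)
    ord <- sample(length(labels))
    labels <- labels[ord]
    n <- round(config$fs * config$trial_duration)
    data <- array(0, dim = c(length(labels), config$n_channels, n))
    for (i in seq_along(labels))
      data[i, , ] <- generate_trial(config, labels[i])
    ch_names <- if (config$n_channels == 3) c("C3", "Cz", "C4")
                else paste0("ch", seq_len(config$n_channels))
    trialset(data, labels, config$fs, ch_names, subject_id)
  })
}
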