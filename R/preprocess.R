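#' Band-pass filter specification
#'
#' Preprocessing uses a 5th-order Butterworth band-pass with a 0.5 Hz lower
#' and 100 Hz upper cutoff, the standard broad-band EEG cleanup that removes
#' drift and out-of-band noise while leaving every rhythm of interest
#' untouched.
#'
#' @param order filter order (default 5).
#' @param low_cut lower cutoff in Hz (default 0.5).
#' @param high_cut upper cutoff in Hz (default 100).
#' @param fs sampling rate in Hz.
#' @return A validated list of class `filter_spec`.
#' @export
filter_spec <- function(order = 5, low_cut = 0.5, high_cut = 100, fs) {
  if (order < 1) stop("order must be >= 1")
  if (!(0 < low_cut && low_cut < high_cut && high_cut < fs / 2))
    stop("cutoffs must satisfy 0 < low_cut < high_cut < fs/2 (got ",
         low_cut, ", ", high_cut, " at fs=", fs, ")")
  structure(list(order = order, low_cut = low_cut, high_cut = high_cut,
                 fs = fs), class = "filter_spec")
}

#' Design the Butterworth band-pass filter
#'
#' @param spec a [filter_spec()].
#' @return A `signal::Arma` coefficient object (elements `b`, `a`) realizing
#'   a maximally flat band-pass response.
#' @export
design_bandpass <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  signal::butter(spec$order,
                 c(spec$low_cut, spec$high_cut) / (spec$fs / 2),
                 type = "pass")
}

#' Apply zero-phase band-pass filtering to every channel of every trial
#'
#' Filters forward and backward (`signal::filtfilt`) so band timing is
#' preserved; the effective attenuation order doubles. Shape is unchanged.
#'
#' @param trials a [trialset()].
#' @param spec a [filter_spec()] whose `fs` matches the trial set.
#' @return The filtered [trialset()].
#' @export
apply_filter <- function(trials, spec) {
  stopifnot(inherits(trials, "trialset"), inherits(spec, "filter_spec"))
  if (!isTRUE(all.equal(spec$fs, trials$fs)))
    stop("filter fs (", spec$fs, ") does not match trial fs (", trials$fs, ")")
  bf <- design_bandpass(spec)
  d <- dim(trials$data)
  out <- trials
  for (i in seq_len(d[1L]))
    for (ch in seq_len(d[2L]))
      out$data[i, ch, ] <- signal::filtfilt(bf, trials$data[i, ch, ])
  out
}

#' Resample a trial set to the pipeline's effective rate
#'
#' The dyadic sub-band table used downstream (gamma 25-50, beta 12.5-25,
#' alpha 6.25-12.5, theta 3.125-6.25 Hz) is the 5-level decomposition of a
#' 200 Hz signal, so recordings at higher rates are brought down to 200 Hz
#' after band-pass filtering (the 100 Hz cutoff doubles as the anti-alias
#' filter). Polyphase resampling via `signal::resample`.
#'
#' @param trials a [trialset()].
#' @param target_fs target rate in Hz (default 200); must not exceed the
#'   current rate.
#' @return A [trialset()] at `target_fs`.
#' @export
resample_to_effective <- function(trials, target_fs = 200) {
  stopifnot(inherits(trials, "trialset"))
  if (target_fs > trials$fs)
    stop("upsampling not supported: target_fs (", target_fs,
         ") > fs (", trials$fs, ")")
  if (isTRUE(all.equal(target_fs, trials$fs))) return(trials)
  frac <- .ratio_approx(target_fs / trials$fs)
  d <- dim(trials$data)
  n_out <- length(signal::resample(numeric(d[3L]), frac[1L], frac[2L]))
  data <- array(0, dim = c(d[1L], d[2L], n_out))
  for (i in seq_len(d[1L]))
    for (ch in seq_len(d[2L]))
      data[i, ch, ] <- signal::resample(trials$data[i, ch, ],
                                        frac[1L], frac[2L])
  trialset(data, trials$labels, target_fs, trials$channel_names,
           trials$subject_id)
}

# small-denominator rational approximation of a resampling ratio
.ratio_approx <- function(x, max_den = 1000L) {
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p >= 1 && abs(p / q - x) < 1e-9) return(c(p, q))
  }
  stop("cannot express resampling ratio ", x, " as a small fraction")
}

#' Preprocess a trial set (filter then resample)
#'
#' Convenience wrapper fixing the pipeline order: Butterworth band-pass at
#' the native rate, then resampling to the effective rate.
#'
#' @param trials a [trialset()].
#' @param order,low_cut,high_cut Butterworth parameters, see [filter_spec()].
#' @param target_fs effective rate (default 200 Hz).
#' @return The preprocessed [trialset()].
#' @export
preprocess_trialset <- function(trials, order = 5, low_cut = 0.5,
                                high_cut = 100, target_fs = 200) {
  spec <- filter_spec(order, low_cut, high_cut, trials$fs)
  resample_to_effective(apply_filter(trials, spec), target_fs)
}
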