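#' Welch power spectral density estimate
#'
#' Averaged modified periodogram over overlapping Hamming-windowed
#' segments, one-sided density scaling (units: power per Hz). Defaults
#' mirror the common MATLAB `pwelch` behaviour: the signal is split into 8
#' segments with 50% overlap (`nperseg = floor(n / 4.5)`) and the FFT
#' length is the next power of two, at least 256. No detrending is applied.
#'
#' @param signal numeric waveform.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples; default `floor(n / 4.5)`.
#' @param overlap fractional overlap between segments (default 0.5).
#' @param nfft FFT length; default `max(256, 2^ceiling(log2(nperseg)))`.
#' @return An object of class `psd_estimate`: list with `frequencies`
#'   (Hz grid spanning 0..fs/2), `density` (nonnegative), `fs` and
#'   `welch_params` (segment length, overlap fraction, window name, nfft).
#' @export
welch_psd <- function(signal, fs, nperseg = NULL, overlap = 0.5,
                      nfft = NULL) {
  n <- length(signal)
  if (n == 0L) stop("empty signal")
  if (fs <= 0) stop("fs must be positive")
  if (is.null(nperseg)) nperseg <- max(8L, floor(n / 4.5))
  nperseg <- as.integer(min(nperseg, n))
  if (nperseg < 2L) stop("signal too short for Welch estimation")
  if (is.null(nfft)) nfft <- max(256L, 2^ceiling(log2(nperseg)))
  nfft <- as.integer(nfft)
  if (nfft < nperseg) stop("nfft must be >= nperseg")
  step <- max(1L, nperseg - floor(nperseg * overlap))
  starts <- seq.int(1L, n - nperseg + 1L, by = step)
  # symmetric Hamming window (MATLAB convention)
  k <- seq_len(nperseg) - 1L
  w <- 0.54 - 0.46 * cos(2 * pi * k / (nperseg - 1L))
  U <- sum(w^2)
  n_freq <- nfft %/% 2L + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- signal[s:(s + nperseg - 1L)] * w
    X <- fft(c(seg, numeric(nfft - nperseg)))
    acc <- acc + Mod(X[seq_len(n_freq)])^2
  }
  pxx <- acc / (length(starts) * fs * U)
  # one-sided: double everything except DC and (for even nfft) Nyquist
  dbl <- rep(2, n_freq); dbl[1L] <- 1
  if (nfft %% 2L == 0L) dbl[n_freq] <- 1
  pxx <- pxx * dbl
  structure(
    list(frequencies = (seq_len(n_freq) - 1L) * fs / nfft,
         density = pxx, fs = fs,
         welch_params = list(nperseg = nperseg, overlap = overlap,
                             window = "hamming", nfft = nfft)),
    class = "psd_estimate"
  )
}

.band_index <- function(psd, band) {
  if (band[1L] < 0 || band[2L] > psd$fs / 2)
    stop("band must lie within [0, fs/2]")
  which(psd$frequencies >= band[1L] & psd$frequencies < band[2L])
}

#' Average spectral power in a band
#'
#' Mean of the PSD values at grid frequencies `low <= f < high`.
#'
#' @param psd a [welch_psd()] estimate.
#' @param band numeric `c(low, high)` in Hz.
#' @return Nonnegative scalar (power per Hz).
#' @export
average_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd_estimate"))
  idx <- .band_index(psd, band)
  if (length(idx) == 0L)
    stop("band [", band[1L], ", ", band[2L], ") contains no frequency bins")
  mean(psd$density[idx])
}

#' Variance of the spectral power distribution in a band
#'
#' Sample variance (n - 1 denominator) of the PSD values across the in-band
#' frequency bins — the "varied power" feature quantifying how peaked the
#' band's spectrum is.
#'
#' @inheritParams average_power
#' @return Nonnegative scalar.
#' @export
variance_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd_estimate"))
  idx <- .band_index(psd, band)
  if (length(idx) < 2L)
    stop("variance_power needs at least 2 in-band frequency bins, got ",
         length(idx))
  var(psd$density[idx])
}
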