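# Daubechies-4 ("db4", 8-tap) analysis/synthesis filter bank.
# Standard orthogonal tabulation; hi filters are the quadrature mirrors.
.db4_dec_lo <- c(-0.010597401785069032,  0.0328830116668852,
                  0.030841381835560764, -0.18703481171909309,
                 -0.027983769416859854,  0.6308807679298589,
                  0.7148465705529157,    0.2303778133088965)
.db4_dec_hi <- c(-0.2303778133088965,    0.7148465705529157,
                 -0.6308807679298589,   -0.027983769416859854,
                  0.18703481171909309,   0.030841381835560764,
                 -0.0328830116668852,   -0.010597401785069032)
.db4_rec_lo <- rev(.db4_dec_lo)
.db4_rec_hi <- rev(.db4_dec_hi)

# One analysis step of the periodized DWT (x must have even length).
.dwt_step <- function(x) {
  N <- length(x)
  half <- N %/% 2L
  cA <- numeric(half); cD <- numeric(half)
  base <- seq.int(0L, N - 2L, by = 2L)
  for (m in 0:7) {
    idx <- ((base + 4L - m) %% N) + 1L
    cA <- cA + .db4_dec_lo[m + 1L] * x[idx]
    cD <- cD + .db4_dec_hi[m + 1L] * x[idx]
  }
  list(cA = cA, cD = cD)
}

# One synthesis step; exact inverse of .dwt_step.
.idwt_step <- function(cA, cD) {
  N <- 2L * length(cA)
  up_a <- numeric(N); up_d <- numeric(N)
  up_a[seq.int(1L, N, by = 2L)] <- cA
  up_d[seq.int(1L, N, by = 2L)] <- cD
  x <- numeric(N)
  n0 <- seq.int(0L, N - 1L)
  for (m in 0:7) {
    idx <- ((n0 - m + 3L) %% N) + 1L
    x <- x + .db4_rec_lo[m + 1L] * up_a[idx] + .db4_rec_hi[m + 1L] * up_d[idx]
  }
  x
}

#' Five-level db4 wavelet decomposition of a single-channel signal
#'
#' Dyadic discrete wavelet transform with the 8-tap Daubechies-4 filter
#' bank, yielding `levels` detail coefficient sets (D1 = finest octave,
#' fs/4 to fs/2) and one approximation set (A_levels). At the pipeline's
#' 200 Hz effective rate and 5 levels the detail bands line up with the
#' EEG rhythms: D2 gamma, D3 beta, D4 alpha, D5 theta; D1 (50-100 Hz) is
#' broadband noise and A5 (0-3.125 Hz) delta, both discarded downstream.
#'
#' Signals whose length is not a multiple of `2^levels` are
#' reflection-padded at the end before the periodized transform; the
#' padded length is stored so reconstructions are truncated back. The
#' transform is exactly invertible (perfect reconstruction).
#'
#' @param signal numeric waveform.
#' @param fs sampling rate in Hz.
#' @param wavelet wavelet name; only `"db4"` is implemented.
#' @param levels decomposition depth (default 5).
#' @return An object of class `dwt_decomposition`: list with `details`
#'   (list `d1`..`d5` of coefficient vectors), `approx` (A5 coefficients),
#'   `levels`, `fs`, `n` (original length), `n_padded`.
#' @export
dwt_decompose <- function(signal, fs, wavelet = "db4", levels = 5) {
  if (wavelet != "db4") stop("only the db4 wavelet is implemented")
  if (fs <= 0) stop("fs must be positive")
  n <- length(signal)
  min_n <- 2^levels
  if (n < min_n)
    stop("signal too short for ", levels, "-level decomposition: need at ",
         "least ", min_n, " samples, got ", n)
  block <- 2^levels
  n_pad <- ceiling(n / block) * block
  if (n_pad > n) {
    pad <- rev(signal)[seq_len(n_pad - n)]  # reflect the tail
    signal <- c(signal, pad)
  }
  details <- vector("list", levels)
  names(details) <- paste0("d", seq_len(levels))
  a <- signal
  for (lev in seq_len(levels)) {
    st <- .dwt_step(a)
    details[[lev]] <- st$cD
    a <- st$cA
  }
  structure(list(details = details, approx = a, levels = levels, fs = fs,
                 n = n, n_padded = n_pad),
            class = "dwt_decomposition")
}

#' Nominal frequency edges of a dyadic decomposition level
#'
#' Detail level `j` covers the octave `(fs / 2^(j+1), fs / 2^j)`; the
#' approximation covers `(0, fs / 2^(levels+1))`. At fs = 200 Hz and 5
#' levels this reproduces the rhythm table: D2 = 25-50 (gamma),
#' D3 = 12.5-25 (beta), D4 = 6.25-12.5 (alpha), D5 = 3.125-6.25 (theta).
#'
#' @param level integer detail level 1..`levels`, or `"a"` for the
#'   approximation band.
#' @param fs sampling rate in Hz.
#' @param levels decomposition depth (default 5), used for `"a"`.
#' @return Numeric `c(low, high)` in Hz.
#' @export
band_edges <- function(level, fs, levels = 5) {
  if (fs <= 0) stop("fs must be positive")
  if (identical(level, "a")) return(c(0, fs / 2^(levels + 1)))
  if (!is.numeric(level) || length(level) != 1L || level < 1 ||
      level > levels || level != round(level))
    stop("level must be an integer in 1..", levels, " or \"a\"")
  c(fs / 2^(level + 1), fs / 2^level)
}

# Map rhythm names to detail levels of the 5-level / 200 Hz decomposition.
.band_level <- c(gamma = 2L, beta = 3L, alpha = 4L, theta = 5L)

# Inverse transform with an arbitrary subset of components kept.
.dwt_reconstruct <- function(decomp, keep) {
  lv <- decomp$levels
  a <- if ("a" %in% keep) decomp$approx else numeric(length(decomp$approx))
  for (lev in rev(seq_len(lv))) {
    d <- if (paste0("d", lev) %in% keep) decomp$details[[lev]]
         else numeric(length(decomp$details[[lev]]))
    a <- .idwt_step(a, d)
  }
  a[seq_len(decomp$n)]
}

#' Reconstruct one rhythm's time-domain signal from a decomposition
#'
#' Inverse transform with every coefficient set zeroed except the detail
#' level carrying the requested band (gamma: D2, beta: D3, alpha: D4,
#' theta: D5). The output has the original signal length.
#'
#' @param decomp a [dwt_decompose()] result.
#' @param band one of `"gamma"`, `"beta"`, `"alpha"`, `"theta"`, or a
#'   component name `"d1"`..`"d5"` / `"a"` for direct access.
#' @return Numeric waveform, same length as the decomposed signal.
#' @export
reconstruct_band <- function(decomp, band) {
  stopifnot(inherits(decomp, "dwt_decomposition"))
  comp <- if (band %in% names(.band_level)) paste0("d", .band_level[[band]])
          else if (band %in% c(paste0("d", seq_len(decomp$levels)), "a")) band
          else stop("unknown band '", band, "'; valid: ",
                    paste(names(.band_level), collapse = ", "),
                    " (or d1..d", decomp$levels, ", a)")
  .dwt_reconstruct(decomp, comp)
}
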