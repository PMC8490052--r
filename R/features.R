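#' Canonical feature names of the 11-dimensional band-power vector
#'
#' Order: four average band powers (alpha, beta, gamma, theta), three
#' relative powers of alpha to beta/gamma/theta, four within-band PSD
#' variances (alpha, beta, gamma, theta).
#'
#' @return Character vector of length 11.
#' @export
feature_names <- function() .mipower_feature_names

#' Extract the 11-dimensional band-power feature vector from one trial
#'
#' Per channel the trial is decomposed with the 5-level db4 DWT, the
#' theta/alpha/beta/gamma detail levels are reconstructed in the time
#' domain, and each reconstruction's Welch PSD gives an average power and a
#' spectral-variance ("varied") power over the band's nominal dyadic edges.
#' The eight average/variance quantities are averaged across channels, and
#' the three relative powers (alpha over beta, gamma, theta) are then
#' formed from the channel-averaged band powers.
#'
#' A ratio denominator is guarded by `max(., eps)` with `eps = 1e-12`
#' (squared microvolts per Hz): degenerate inputs with zero band power warn
#' instead of producing NaN.
#'
#' @param trial numeric matrix, channels x samples, already preprocessed at
#'   the effective rate.
#' @param fs sampling rate in Hz (200 for the standard pipeline).
#' @param eps zero-denominator guard for the relative features.
#' @return Named numeric vector of length 11 in canonical order.
#' @export
extract_features <- function(trial, fs, eps = 1e-12) {
  if (is.null(dim(trial))) trial <- matrix(trial, nrow = 1L)
  n_ch <- nrow(trial)
  bands <- names(.band_level)  # gamma, beta, alpha, theta
  avg <- matrix(0, n_ch, length(bands), dimnames = list(NULL, bands))
  vr <- avg
  for (ch in seq_len(n_ch)) {
    dec <- dwt_decompose(trial[ch, ], fs)
    for (b in bands) {
      rec <- reconstruct_band(dec, b)
      psd <- welch_psd(rec, fs)
      edges <- band_edges(.band_level[[b]], fs)
      avg[ch, b] <- average_power(psd, edges)
      vr[ch, b] <- variance_power(psd, edges)
    }
  }
  avg_m <- colMeans(avg)
  vr_m <- colMeans(vr)
  if (any(avg_m[c("beta", "gamma", "theta")] < eps))
    warning("zero band power in relative-feature denominator; ",
            "applying epsilon guard")
  denom <- function(x) max(x, eps)
  out <- c(avg_m[["alpha"]], avg_m[["beta"]], avg_m[["gamma"]],
           avg_m[["theta"]],
           avg_m[["alpha"]] / denom(avg_m[["beta"]]),
           avg_m[["alpha"]] / denom(avg_m[["gamma"]]),
           avg_m[["alpha"]] / denom(avg_m[["theta"]]),
           vr_m[["alpha"]], vr_m[["beta"]], vr_m[["gamma"]],
           vr_m[["theta"]])
  setNames(out, .mipower_feature_names)
}

#' Extract the trials-by-features matrix from a trial set
#'
#' Applies [extract_features()] to every trial; row i corresponds to trial
#' i and labels are carried through.
#'
#' @param trials a preprocessed [trialset()] at the effective rate.
#' @param eps ratio guard passed to [extract_features()].
#' @return An object of class `feature_matrix`: list with `features`
#'   (numeric matrix, trials x 11, canonical column names) and `labels`.
#' @export
extract_matrix <- function(trials, eps = 1e-12) {
  stopifnot(inherits(trials, "trialset"))
  n <- n_trials(trials)
  out <- matrix(0, n, length(.mipower_feature_names),
                dimnames = list(NULL, .mipower_feature_names))
  for (i in seq_len(n)) {
    out[i, ] <- tryCatch(
      extract_features(trials$data[i, , , drop = TRUE], trials$fs, eps),
      error = function(e) stop("trial ", i, ": ", conditionMessage(e)))
  }
  feature_matrix(out, trials$labels)
}

#' Construct a feature matrix object
#'
#' @param features numeric matrix, trials x 11, canonical column names
#'   (set if absent).
#' @param labels per-trial class labels aligned to rows.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(features, labels) {
  features <- as.matrix(features)
  if (ncol(features) == length(.mipower_feature_names) &&
      is.null(colnames(features)))
    colnames(features) <- .mipower_feature_names
  if (nrow(features) != length(labels))
    stop("labels length must equal the number of rows")
  if (anyNA(features)) stop("feature matrix contains missing values")
  structure(list(features = features, labels = as.character(labels)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features\n",
              nrow(x$features), ncol(x$features)))
  print(head(as.data.frame(x), 4))
  invisible(x)
}

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  data.frame(label = x$labels, x$features, check.names = FALSE)
}

#' Write a feature matrix to CSV
#'
#' Fixed header: `trial_id`, `label`, then the 11 canonical feature names.
#'
#' @param fm a [feature_matrix()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(trial_id = seq_len(nrow(fm$features)),
                   label = fm$labels, fm$features, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV file.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE)
  need <- c("trial_id", "label", .mipower_feature_names)
  if (!all(need %in% names(df)))
    stop("feature CSV is missing required columns")
  feature_matrix(as.matrix(df[, .mipower_feature_names]), df$label)
}
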