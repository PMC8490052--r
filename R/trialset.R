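#' Construct a trial set
#'
#' A `trialset` is the pipeline's raw-input container: a collection of
#' equally sized multichannel EEG trials with per-trial class labels and a
#' common sampling rate.
#'
#' @param data numeric array of dimension trials x channels x samples, in
#'   microvolts.
#' @param labels character or factor vector of per-trial classes, one of
#'   `"hand"` or `"feet"`, length equal to the number of trials.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector naming the channels (default
#'   C3/Cz/C4-style names).
#' @param subject_id free-text identifier carried through reports.
#'
#' @return An object of class `trialset` with elements `data`, `labels`,
#'   `fs`, `channel_names`, `subject_id`.
#' @export
trialset <- function(data, labels, fs, channel_names = NULL, subject_id = "S01") {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array: trials x channels x samples")
  n_trials <- dim(data)[1L]
  labels <- as.character(labels)
  if (length(labels) != n_trials)
    stop("length(labels) must equal the number of trials (", n_trials, ")")
  if (!all(labels %in% c("hand", "feet")))
    stop("labels must be 'hand' or 'feet'")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[2L]))
  if (length(channel_names) != dim(data)[2L])
    stop("channel_names length must equal the channel dimension")
  structure(
    list(data = data, labels = labels, fs = fs,
         channel_names = as.character(channel_names),
         subject_id = subject_id),
    class = "trialset"
  )
}

#' @export
print.trialset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trialset> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat("  labels:  ", paste(sprintf("%s=%d", names(table(x$labels)),
                                   table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trialset <- function(x) dim(x$data)

n_trials <- function(ts) dim(ts$data)[1L]

#' Write a trial set to a directory of CSV files
#'
#' Serializes one CSV per trial (`trial_0001.csv`, ... ; columns = channels,
#' header row = channel names) plus a `trialset.json` holding the sampling
#' rate, labels and subject id. The layout round-trips through
#' [read_trialset()].
#'
#' @param ts a [trialset()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(ts, path) {
  stopifnot(inherits(ts, "trialset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ts$data)
  for (i in seq_len(d[1L])) {
    m <- t(ts$data[i, , , drop = TRUE])
    if (d[2L] == 1L) m <- matrix(ts$data[i, 1L, ], ncol = 1L)
    colnames(m) <- ts$channel_names
    write.csv(m, file.path(path, sprintf("trial_%04d.csv", i)),
              row.names = FALSE)
  }
  meta <- list(fs = ts$fs, labels = ts$labels,
               channel_names = ts$channel_names, subject_id = ts$subject_id,
               n_trials = d[1L], n_samples = d[3L])
  jsonlite::write_json(meta, file.path(path, "trialset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial set from disk
#'
#' Reads the CSV-directory layout written by [write_trialset()]: one CSV per
#' trial plus a `trialset.json` with sampling rate and labels.
#'
#' @param path directory containing `trial_*.csv` files and `trialset.json`.
#' @param format input format; only `"csv-dir"` is supported.
#' @return A [trialset()].
#' @export
read_trialset <- function(path, format = c("csv-dir")) {
  format <- match.arg(format)
  if (!dir.exists(path)) stop("no such directory: ", path)
  meta_file <- file.path(path, "trialset.json")
  if (!file.exists(meta_file)) stop("missing metadata file: ", meta_file)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  files <- sort(list.files(path, pattern = "^trial_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no trial CSV files in ", path)
  mats <- lapply(files, function(f) as.matrix(read.csv(f, check.names = FALSE)))
  ncols <- vapply(mats, ncol, 1L)
  if (length(unique(ncols)) != 1L)
    stop("inconsistent channel counts across trial files in ", path)
  nrows <- vapply(mats, nrow, 1L)
  if (length(unique(nrows)) != 1L)
    stop("inconsistent sample counts across trial files in ", path)
  data <- array(0, dim = c(length(mats), ncols[1L], nrows[1L]))
  for (i in seq_along(mats)) data[i, , ] <- t(mats[[i]])
  trialset(data, labels = meta$labels, fs = meta$fs,
           channel_names = colnames(mats[[1L]]),
           subject_id = meta$subject_id %||% "S01")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
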