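# Equal-frequency discretization. Features with at most n_bins distinct
# values are already discrete and keep one bin per value; otherwise tied
# quantile breaks are collapsed, so degenerate features land in fewer
# (possibly 1) bins.
.ef_bins <- function(x, n_bins) {
  if (length(unique(x)) <= n_bins) return(factor(x))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE, type = 7))
  if (length(br) < 2L) return(factor(rep(1L, length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Mutual information between a feature and the class label
#'
#' The feature is discretized into `n_bins` equal-frequency bins, the joint
#' distribution with the class label is tabulated, and
#' `sum p(a,b) * log(p(a,b) / (p(a) p(b)))` is returned in nats.
#' Zero-probability cells contribute 0. A feature identical to a balanced
#' binary label scores `ln 2`; an independent feature scores near 0.
#'
#' @param feature per-trial numeric column.
#' @param labels per-trial class column, same length.
#' @param n_bins number of discretization bins (default 4).
#' @return Nonnegative mutual-information score in nats.
#' @export
mutual_information_score <- function(feature, labels, n_bins = 4) {
  if (length(feature) != length(labels) || length(feature) < 2L)
    stop("feature and labels must have equal length >= 2")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  bins <- .ef_bins(feature, n_bins)
  if (nlevels(droplevels(bins)) < 2L) {
    warning("constant feature: mutual information is 0")
    return(0)
  }
  joint <- table(bins, labels) / length(feature)
  pa <- rowSums(joint); pb <- colSums(joint)
  terms <- joint * log(joint / outer(pa, pb))
  sum(terms[joint > 0])
}

#' Chi-square dependence score between a feature and the class label
#'
#' Bins the feature (equal-frequency, `n_bins`), builds the observed
#' contingency table against the class, forms expected counts from the
#' marginals, and returns the statistic `sum((O - E)^2 / E)` with its
#' p-value from the chi-square distribution on
#' `(bins - 1) * (classes - 1)` degrees of freedom. Bins whose expected
#' count falls below 1 are merged with their neighbor (with a warning).
#'
#' @inheritParams mutual_information_score
#' @param alpha significance level recorded in the result (default 0.05).
#' @return List with `statistic`, `p_value`, `df`, `alpha`.
#' @export
chi_square_score <- function(feature, labels, n_bins = 4, alpha = 0.05) {
  if (length(feature) != length(labels) || length(feature) < 2L)
    stop("feature and labels must have equal length >= 2")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  bins <- .ef_bins(feature, n_bins)
  obs <- as.matrix(table(bins, labels))
  obs <- obs[rowSums(obs) > 0, , drop = FALSE]
  expected <- function(o) outer(rowSums(o), colSums(o)) / sum(o)
  # merge adjacent bins while any expected cell is below 1
  while (nrow(obs) > 1L && any(expected(obs) < 1)) {
    warning("expected count < 1; merging adjacent bins")
    i <- which(apply(expected(obs) < 1, 1, any))[1L]
    j <- if (i == nrow(obs)) i - 1L else i + 1L
    obs[j, ] <- obs[j, ] + obs[i, ]
    obs <- obs[-i, , drop = FALSE]
  }
  if (nrow(obs) < 2L) {
    warning("constant feature: chi-square statistic is 0")
    return(list(statistic = 0, p_value = 1, df = 0, alpha = alpha))
  }
  E <- expected(obs)
  stat <- sum((obs - E)^2 / E)
  df <- (nrow(obs) - 1L) * (ncol(obs) - 1L)
  list(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE),
       df = df, alpha = alpha)
}

#' Pearson correlation coefficient between two feature columns
#'
#' @param a,b numeric columns of equal length >= 2; neither constant.
#' @return r in `[-1, 1]`.
#' @export
correlation_coefficient <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("inputs must have equal length >= 2")
  if (sd(a) == 0 || sd(b) == 0)
    stop("correlation undefined for a constant input")
  cor(a, b)
}

#' Pairwise feature correlation map
#'
#' Full Pearson correlation matrix of the feature columns, plus the list of
#' pairs whose |r| meets the redundancy threshold (rendered as a heat map in
#' exploratory use). Constant columns get zero correlations with a warning.
#'
#' @param fm a [feature_matrix()] (or plain numeric matrix).
#' @param threshold absolute-correlation cutoff for flagging a pair as
#'   redundant (default 0.85).
#' @return An object of class `correlation_map`: list with `r` (symmetric
#'   matrix, unit diagonal), `pairs` (data frame `i`, `j`, `r` with
#'   `|r| >= threshold`, i < j), `threshold`.
#' @export
correlation_map <- function(fm, threshold = 0.85) {
  x <- if (inherits(fm, "feature_matrix")) fm$features else as.matrix(fm)
  if (ncol(x) < 2L) stop("need at least 2 features")
  const <- apply(x, 2, sd) == 0
  r <- suppressWarnings(cor(x))
  if (any(const)) {
    warning("constant feature column(s): ",
            paste(which(const), collapse = ", "),
            "; correlations set to 0")
    r[const, ] <- 0; r[, const] <- 0
  }
  diag(r) <- 1
  ut <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  pairs <- data.frame(i = ut[, 1], j = ut[, 2],
                      r = r[ut])
  pairs <- pairs[order(-abs(pairs$r)), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(r = r, pairs = pairs, threshold = threshold),
            class = "correlation_map")
}

#' Drop redundant features by greedy correlation elimination
#'
#' While any remaining pair exceeds the map's threshold, the
#' worst-offending pair is examined and the member with the higher mean
#' absolute correlation to all other remaining features is discarded (ties
#' broken toward the higher column index). Survivors are returned in
#' canonical order.
#'
#' @param map a [correlation_map()].
#' @return Integer vector of surviving feature indices.
#' @export
discard_correlated <- function(map) {
  stopifnot(inherits(map, "correlation_map"))
  r <- abs(map$r)
  keep <- seq_len(ncol(r))
  repeat {
    sub <- r[keep, keep, drop = FALSE]
    diag(sub) <- 0
    if (all(sub < map$threshold)) break
    w <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    cand <- keep[c(w[1L], w[2L])]
    mean_abs <- vapply(cand, function(f)
      mean(r[f, setdiff(keep, f)]), numeric(1))
    drop_f <- if (abs(diff(mean_abs)) < 1e-12) max(cand)
              else cand[which.max(mean_abs)]
    keep <- setdiff(keep, drop_f)
    if (length(keep) < 2L) break
  }
  keep
}

#' Rank features over repeated subsampling iterations and select a subset
#'
#' Implements the 10-iteration ranking protocol: each iteration scores all
#' features on a seeded random subsample of 80% of the trials and records
#' the resulting ranks (1 = best). The final selection is the `k` features
#' appearing most often in the per-iteration top-k sets (ties broken toward
#' the higher mean score). Defaults follow the method's usage: mutual
#' information keeps 6 of 11 features, chi-square 5 of 11.
#'
#' @param fm a [feature_matrix()].
#' @param method `"mutual_information"`, `"chi_square"` or
#'   `"correlation"`. For `"correlation"` the ranking score is a feature's
#'   mean absolute correlation with the others (lower = better, i.e. least
#'   redundant ranks first) and the selected set is the survivor set of
#'   [discard_correlated()] computed on the full data.
#' @param k selection size; defaults to 6 for mutual information and 5 for
#'   chi-square; ignored for correlation (survivor set).
#' @param n_iterations number of subsampling iterations (default 10).
#' @param n_bins discretization bins for MI / chi-square (default 4).
#' @param subsample fraction of trials drawn (without replacement) per
#'   iteration (default 0.8).
#' @param threshold redundancy threshold for the correlation method.
#' @param seed integer seed making the iterations reproducible.
#' @return An object of class `ranking_result`: list with `method`,
#'   `per_iteration_scores` and `per_iteration_ranks` (iterations x
#'   features), `selected` (ordered integer indices), `selection_rule`,
#'   `n_iterations`, `seed`.
#' @export
rank_features <- function(fm,
                          method = c("mutual_information", "chi_square",
                                     "correlation"),
                          k = NULL, n_iterations = 10, n_bins = 4,
                          subsample = 0.8, threshold = 0.85, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  method <- match.arg(method)
  p <- ncol(fm$features)
  if (is.null(k))
    k <- switch(method, mutual_information = 6L, chi_square = 5L,
                correlation = NA_integer_)
  if (method != "correlation") {
    if (k <= 0) stop("k must be positive")
    if (k > p) stop("k cannot exceed the number of features (", p, ")")
  }
  n <- nrow(fm$features)
  scores <- matrix(NA_real_, n_iterations, p,
                   dimnames = list(NULL, colnames(fm$features)))
  for (it in seq_len(n_iterations)) {
    idx <- with_private_seed(seed + it,
                             sample(n, size = max(2L, round(subsample * n))))
    xs <- fm$features[idx, , drop = FALSE]
    ys <- fm$labels[idx]
    scores[it, ] <- switch(method,
      mutual_information = apply(xs, 2, function(col)
        suppressWarnings(mutual_information_score(col, ys, n_bins))),
      chi_square = apply(xs, 2, function(col)
        suppressWarnings(chi_square_score(col, ys, n_bins))$statistic),
      correlation = {
        cm <- suppressWarnings(correlation_map(xs, threshold))
        r <- abs(cm$r); diag(r) <- NA
        -rowMeans(r, na.rm = TRUE)  # least redundant scores highest
      })
  }
  ranks <- t(apply(-scores, 1, rank, ties.method = "first"))
  if (method == "correlation") {
    selected <- discard_correlated(correlation_map(fm, threshold))
    rule <- sprintf("survivors of greedy |r| >= %g elimination", threshold)
  } else {
    topk <- ranks <= k
    counts <- colSums(topk)
    mean_score <- colMeans(scores)
    ord <- order(-counts, -mean_score)
    selected <- sort(ord[seq_len(k)])
    rule <- sprintf(
      "top %d by count of top-%d appearances over %d iterations", k, k,
      n_iterations)
  }
  structure(list(method = method, per_iteration_scores = scores,
                 per_iteration_ranks = ranks, selected = selected,
                 selection_rule = rule, n_iterations = n_iterations,
                 seed = seed),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> %s, %d iterations\n", x$method,
              x$n_iterations))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  cat("  rule:    ", x$selection_rule, "\n")
  invisible(x)
}
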