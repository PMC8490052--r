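#' Cross-validated accuracy of a feature subset
#'
#' Restricts the feature matrix to the given columns and runs the
#' stratified k-fold evaluation.
#'
#' @param fm a [feature_matrix()].
#' @param subset nonempty integer vector of feature column indices.
#' @param spec a [classifier_spec()] (default weighted KNN, the benchmark's
#'   best performer and the classifier used for ablation).
#' @param n_folds,seed passed to [stratified_kfold_eval()].
#' @return Mean accuracy in percent.
#' @export
subset_accuracy <- function(fm, subset, spec = classifier_spec("weighted_knn"),
                            n_folds = 5, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(subset) == 0L) stop("feature subset must be nonempty")
  if (any(subset < 1 | subset > ncol(fm$features)))
    stop("subset indices out of range 1..", ncol(fm$features))
  sub_fm <- feature_matrix(fm$features[, subset, drop = FALSE], fm$labels)
  stratified_kfold_eval(sub_fm, spec, n_folds, seed)$mean_accuracy
}

#' Loss in accuracy of a feature subset relative to the full set
#'
#' Defined as `accuracy_all - accuracy_subset` in percentage points; a
#' negative value means the subset outperformed the full feature set.
#'
#' @param accuracy_all,accuracy_subset accuracies in percent.
#' @return Percentage points.
#' @export
loss_in_accuracy <- function(accuracy_all, accuracy_subset) {
  stopifnot(accuracy_all >= 0, accuracy_all <= 100,
            accuracy_subset >= 0, accuracy_subset <= 100)
  accuracy_all - accuracy_subset
}

#' Run the full analysis pipeline on one subject's trials
#'
#' Orchestrates generate/read, preprocess (band-pass + resample to the
#' effective rate), feature extraction, the three ranking methods, the
#' five-classifier benchmark, and the feature-ablation analysis with the
#' weighted KNN: accuracy with all 11 features, without the three relative
#' powers, with the mutual-information and chi-square selections, and with
#' the correlation survivors, each paired with its loss in accuracy.
#'
#' @param input a [synthetic_config()] (trials are generated), a
#'   [trialset()], or a path readable by [read_trialset()].
#' @param n_folds CV folds (default 5).
#' @param seed seed for fold assignment, ranking iterations and stochastic
#'   learners.
#' @param ablation_spec classifier used for the ablation columns (default
#'   weighted KNN).
#' @param out_dir optional directory; when given, features, rankings,
#'   reports and a run manifest are written there.
#' @return An object of class `pipeline_result`: list with `features`
#'   ([feature_matrix()]), `rankings` (3 `ranking_result`s), `benchmark`
#'   (5 `cv_report`s), `ablation` (one-row data frame in the ablation-table
#'   shape), `subject_id`, `seed`.
#' @export
run_pipeline <- function(input, n_folds = 5, seed = 1L,
                         ablation_spec = classifier_spec("weighted_knn"),
                         out_dir = NULL) {
  trials <-
    if (inherits(input, "synthetic_config")) generate_trialset(input)
    else if (inherits(input, "trialset")) input
    else if (is.character(input)) read_trialset(input)
    else stop("input must be a synthetic_config, trialset, or path")
  step <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))

  pp <- step("preprocess", preprocess_trialset(trials))
  fm <- step("extract", extract_matrix(pp))
  rankings <- step("rank", list(
    mutual_information = rank_features(fm, "mutual_information",
                                       seed = seed),
    chi_square = rank_features(fm, "chi_square", seed = seed),
    correlation = rank_features(fm, "correlation", seed = seed)))
  benchmark <- step("benchmark", benchmark_all(
    fm, default_classifiers(seed = seed), n_folds, seed))
  ablation <- step("ablation", {
    p <- ncol(fm$features)
    acc <- function(sub) subset_accuracy(fm, sub, ablation_spec, n_folds,
                                         seed)
    all_acc <- acc(seq_len(p))
    subsets <- list(
      without_relative = setdiff(seq_len(p), .mipower_relative_idx),
      mi_subset = rankings$mutual_information$selected,
      chi2_subset = rankings$chi_square$selected,
      corr_survivors = rankings$correlation$selected)
    accs <- vapply(subsets, acc, numeric(1))
    data.frame(subject = trials$subject_id,
               accuracy_all = all_acc,
               accuracy_without_relative = accs[["without_relative"]],
               accuracy_mi_subset = accs[["mi_subset"]],
               accuracy_chi2_subset = accs[["chi2_subset"]],
               accuracy_corr_survivors = accs[["corr_survivors"]],
               loss_without_relative =
                 loss_in_accuracy(all_acc, accs[["without_relative"]]),
               loss_mi = loss_in_accuracy(all_acc, accs[["mi_subset"]]),
               loss_chi2 = loss_in_accuracy(all_acc, accs[["chi2_subset"]]),
               loss_corr = loss_in_accuracy(all_acc,
                                            accs[["corr_survivors"]]))
  })
  res <- structure(
    list(features = fm, rankings = rankings, benchmark = benchmark,
         ablation = ablation, subject_id = trials$subject_id, seed = seed,
         n_folds = n_folds, classifier = ablation_spec$name),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir, input)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> subject %s, seed %d\n", x$subject_id,
              x$seed))
  accs <- vapply(x$benchmark, `[[`, numeric(1), "mean_accuracy")
  cat("  benchmark accuracy (%):\n")
  print(round(accs, 2))
  cat("  ablation (", x$classifier, "):\n", sep = "")
  print(x$ablation[, 2:6], row.names = FALSE)
  invisible(x)
}

# Serialize every pipeline artifact plus a machine-readable manifest.
write_pipeline_result <- function(res, out_dir, input = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_matrix(res$features, file.path(out_dir, "features.csv"))
  for (m in names(res$rankings)) {
    rk <- res$rankings[[m]]
    jsonlite::write_json(
      list(method = rk$method, selected = rk$selected,
           selection_rule = rk$selection_rule,
           n_iterations = rk$n_iterations, seed = rk$seed,
           per_iteration_ranks = rk$per_iteration_ranks),
      file.path(out_dir, paste0("ranking_", m, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  bench <- data.frame(
    subject = res$subject_id,
    t(vapply(res$benchmark, `[[`, numeric(1), "mean_accuracy")))
  write.csv(bench, file.path(out_dir, "classifier_report.csv"),
            row.names = FALSE)
  write.csv(res$ablation, file.path(out_dir, "ablation.csv"),
            row.names = FALSE)
  manifest <- list(
    package = "mipower",
    version = as.character(utils::packageVersion("mipower")),
    subject_id = res$subject_id, seed = res$seed, n_folds = res$n_folds,
    ablation_classifier = res$classifier,
    config = if (inherits(input, "synthetic_config")) unclass(input))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the pipeline for several synthetic subjects
#'
#' Emulates a multi-subject study: each subject is an independent synthetic
#' recording differing by seed. Returns benchmark and ablation tables with
#' one row per subject plus an average row — the layout used to compare
#' classifiers and to quantify the impact of the relative-power features.
#'
#' @param n_subjects number of synthetic subjects (default 3).
#' @param base_config a [synthetic_config()]; each subject reuses it with
#'   `seed = base_config$seed + subject - 1`.
#' @param n_folds,seed passed to [run_pipeline()].
#' @return List with `benchmark_table` (subjects x classifiers, percent),
#'   `ablation_table` (subjects x ablation columns), `results` (per-subject
#'   `pipeline_result`s).
#' @export
run_study <- function(n_subjects = 3, base_config = synthetic_config(),
                      n_folds = 5, seed = 1L) {
  results <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    cfg <- base_config
    cfg$seed <- base_config$seed + s - 1L
    ts <- generate_trialset(cfg, subject_id = sprintf("S%02d", s))
    results[[s]] <- run_pipeline(ts, n_folds = n_folds, seed = seed + s - 1L)
  }
  bench <- do.call(rbind, lapply(results, function(r)
    data.frame(subject = r$subject_id,
               t(vapply(r$benchmark, `[[`, numeric(1), "mean_accuracy")))))
  ablation <- do.call(rbind, lapply(results, `[[`, "ablation"))
  avg_row <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    out <- df[1, , drop = FALSE]
    out$subject <- "AVG"
    out[, num] <- as.list(colMeans(df[, num, drop = FALSE]))
    out
  }
  list(benchmark_table = rbind(bench, avg_row(bench)),
       ablation_table = rbind(ablation, avg_row(ablation)),
       results = results)
}
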