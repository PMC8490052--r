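test_that("loss_in_accuracy is the plain accuracy difference", {
  expect_equal(loss_in_accuracy(93.51, 93.51), 0)
  expect_equal(loss_in_accuracy(94.3, 93.8), 0.5)
  expect_equal(loss_in_accuracy(92.8, 93.7), -0.9)
  expect_error(loss_in_accuracy(101, 50))
})

test_that("subset_accuracy restricts columns and matches the full run", {
  fm <- informative_matrix(n = 100, seed = 12)
  spec <- classifier_spec("weighted_knn")
  full <- stratified_kfold_eval(fm, spec, seed = 4)$mean_accuracy
  expect_equal(subset_accuracy(fm, 1:11, spec, seed = 4), full)
  expect_error(subset_accuracy(fm, integer(0)), "nonempty")
  expect_error(subset_accuracy(fm, c(1, 12)), "out of range")
})

test_that("a single pure-noise feature scores at chance on null data", {
  set.seed(30)
  labels <- rep(c("hand", "feet"), each = 150)
  fm <- feature_matrix(matrix(rnorm(300 * 11), 300, 11), labels)
  acc <- subset_accuracy(fm, 4, classifier_spec("weighted_knn"), seed = 7)
  expect_true(acc >= 35 && acc <= 65)
})

test_that("run_pipeline produces the full report bundle deterministically", {
  cfg <- small_config(seed = 17)
  res <- run_pipeline(cfg, seed = 17)
  expect_s3_class(res, "pipeline_result")
  expect_length(res$benchmark, 5)
  expect_length(res$rankings, 3)
  expect_named(res$ablation,
               c("subject", "accuracy_all", "accuracy_without_relative",
                 "accuracy_mi_subset", "accuracy_chi2_subset",
                 "accuracy_corr_survivors", "loss_without_relative",
                 "loss_mi", "loss_chi2", "loss_corr"))
  # ablation identity holds exactly
  with(res$ablation, {
    expect_identical(loss_mi, accuracy_all - accuracy_mi_subset)
    expect_identical(loss_chi2, accuracy_all - accuracy_chi2_subset)
    expect_identical(loss_corr, accuracy_all - accuracy_corr_survivors)
    expect_identical(loss_without_relative,
                     accuracy_all - accuracy_without_relative)
  })
  res2 <- run_pipeline(cfg, seed = 17)
  expect_equal(res$ablation, res2$ablation)
  expect_equal(vapply(res$benchmark, `[[`, numeric(1), "mean_accuracy"),
               vapply(res2$benchmark, `[[`, numeric(1), "mean_accuracy"))
})

test_that("pipeline artifacts serialize with a manifest", {
  dir <- withr::local_tempdir()
  cfg <- small_config(seed = 23)
  res <- run_pipeline(cfg, seed = 23, out_dir = dir)
  expect_true(file.exists(file.path(dir, "features.csv")))
  expect_true(file.exists(file.path(dir, "ablation.csv")))
  expect_true(file.exists(file.path(dir, "classifier_report.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  for (m in c("mutual_information", "chi_square", "correlation"))
    expect_true(file.exists(file.path(dir,
                                      paste0("ranking_", m, ".json"))))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 23)
  expect_equal(manifest$config$seed, 23)
  # byte-identical manifests and reports on a re-run
  dir2 <- withr::local_tempdir()
  run_pipeline(cfg, seed = 23, out_dir = dir2)
  for (f in c("features.csv", "ablation.csv", "manifest.json"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})

test_that("run_study emits benchmark and ablation tables with an average row", {
  st <- run_study(n_subjects = 2, base_config = small_config(seed = 40),
                  seed = 40)
  expect_equal(nrow(st$benchmark_table), 3)
  expect_equal(st$benchmark_table$subject, c("S01", "S02", "AVG"))
  expect_named(st$benchmark_table,
               c("subject", "tree", "fine_knn", "weighted_knn",
                 "quadratic_svm", "random_forest"))
  expect_equal(st$benchmark_table$weighted_knn[3],
               mean(st$benchmark_table$weighted_knn[1:2]))
  # ablation table: 5 accuracy columns per subject (Table-2 shape)
  acc_cols <- grep("^accuracy_", names(st$ablation_table), value = TRUE)
  expect_length(acc_cols, 5)
  expect_equal(nrow(st$ablation_table), 3)
})

test_that("pipeline errors name the failing stage", {
  cfg <- small_config(seed = 2, n_trials_per_class = 3)
  # 3 trials per class cannot be split into 5 stratified folds
  expect_error(run_pipeline(cfg, n_folds = 5), "benchmark|fewer")
})
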