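test_that("compute_metrics reproduces hand-computed values", {
  confusion <- matrix(c(50, 0, 0, 50), 2, 2,
                      dimnames = list(c("feet", "hand"), c("feet", "hand")))
  m <- compute_metrics(confusion)
  expect_equal(m$accuracy, 100)
  expect_equal(unname(m$precision), c(1, 1))
  expect_equal(unname(m$recall), c(1, 1))
  expect_equal(unname(m$f1), c(1, 1))

  confusion2 <- matrix(c(40, 20, 10, 30), 2, 2,
                       dimnames = list(c("a", "b"), c("a", "b")))
  m2 <- compute_metrics(confusion2)
  expect_equal(m2$accuracy, 70)
  expect_equal(m2$precision[["a"]], 40 / 60)
  expect_equal(m2$recall[["a"]], 0.8)
  expect_equal(m2$f1[["a"]], 2 * (2 / 3) * 0.8 / (2 / 3 + 0.8))
  # swapping the classes permutes per-class rows, accuracy unchanged
  m2r <- compute_metrics(confusion2[2:1, 2:1])
  expect_equal(m2r$accuracy, m2$accuracy)
  expect_equal(m2r$precision[["a"]], m2$precision[["a"]])
  expect_equal(m2r$precision[["b"]], m2$precision[["b"]])
  # F1 is the harmonic mean of the reported precision and recall
  expect_equal(m2$f1,
               2 * m2$precision * m2$recall / (m2$precision + m2$recall))
  expect_warning(m3 <- compute_metrics(matrix(c(5, 5, 0, 0), 2)),
                 "zero denominator")
  expect_equal(unname(m3$precision[2]), 0)
})

test_that("far-separated classes are classified perfectly", {
  set.seed(10)
  n <- 100
  labels <- rep(c("hand", "feet"), each = n / 2)
  x <- matrix(rnorm(n * 11), n, 11)
  x[labels == "feet", ] <- x[labels == "feet", ] + 10
  fm <- feature_matrix(x, labels)
  rep <- stratified_kfold_eval(fm, classifier_spec("weighted_knn"),
                               seed = 1)
  expect_equal(rep$mean_accuracy, 100)
  expect_equal(rep$n_folds, 5)
  expect_equal(sum(rep$confusion), n)
})

test_that("shuffled labels give chance-level accuracy for every classifier", {
  set.seed(22)
  n <- 400
  labels <- sample(rep(c("hand", "feet"), each = n / 2))
  fm <- feature_matrix(matrix(rnorm(n * 11), n, 11), labels)
  reports <- benchmark_all(fm, default_classifiers(seed = 2), seed = 2)
  for (r in reports)
    expect_true(r$mean_accuracy >= 40 && r$mean_accuracy <= 60,
                label = sprintf("%s: %.1f%%", r$classifier,
                                r$mean_accuracy))
})

test_that("cross-validation is reproducible and fold-paired", {
  fm <- informative_matrix(n = 100, seed = 6)
  specs <- default_classifiers(seed = 3)
  r1 <- benchmark_all(fm, specs, seed = 3)
  r2 <- benchmark_all(fm, specs, seed = 3)
  expect_named(r1, c("tree", "fine_knn", "weighted_knn", "quadratic_svm",
                     "random_forest"))
  for (nm in names(r1)) {
    expect_identical(r1[[nm]]$fold_accuracy, r2[[nm]]$fold_accuracy)
    expect_identical(r1[[nm]]$confusion, r2[[nm]]$confusion)
  }
  # pooled accuracy equals the trial-weighted mean of fold accuracies
  for (r in r1) {
    fold_sizes <- as.vector(table(mipower:::make_folds(fm$labels, 5, 3)))
    expect_equal(r$mean_accuracy,
                 sum(r$fold_accuracy * fold_sizes) / sum(fold_sizes),
                 tolerance = 1e-10)
  }
})

test_that("stratification keeps class balance per fold and validates input", {
  labels <- rep(c("hand", "feet"), c(40, 40))
  folds <- mipower:::make_folds(labels, 5, 1)
  for (f in 1:5) {
    expect_equal(sum(labels[folds == f] == "hand"), 8)
    expect_equal(sum(labels[folds == f] == "feet"), 8)
  }
  expect_error(mipower:::make_folds(rep(c("hand", "feet"), c(3, 40)), 5, 1),
               "fewer members")
  fm_bad <- informative_matrix(20)
  fm_bad$features[1, 1] <- NA
  expect_error(suppressWarnings(
    stratified_kfold_eval(fm_bad, classifier_spec("tree"))), "missing")
})

test_that("classifier presets expose the expected hyperparameters", {
  sp <- default_classifiers()
  expect_equal(sp$fine_knn$hyperparameters$k, 1L)
  expect_equal(sp$weighted_knn$hyperparameters$k, 10L)
  expect_equal(sp$quadratic_svm$hyperparameters$degree, 2)
  expect_equal(sp$random_forest$hyperparameters$ntree, 30L)
  expect_true(sp$quadratic_svm$standardize)
  expect_false(sp$tree$standardize)
  expect_error(classifier_spec("boosted"))
  expect_error(classifier_spec("fine_knn", k = -1), "nonnegative")
})
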