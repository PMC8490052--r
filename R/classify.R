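#' Classifier specification
#'
#' Fixed presets for the five benchmark classifiers. Hyperparameters mirror
#' the common "preset" meanings of the names: a fine KNN uses a single
#' Euclidean neighbor; a weighted KNN uses 10 neighbors with
#' squared-inverse-distance weights; a quadratic SVM uses a degree-2
#' polynomial kernel at unit cost on standardized features; the random
#' forest grows 30 bootstrap trees; the decision tree grows unpruned to a
#' depth cap.
#'
#' @param name one of `"tree"`, `"fine_knn"`, `"weighted_knn"`,
#'   `"quadratic_svm"`, `"random_forest"`.
#' @param ... preset overrides: `k` (neighbors), `ntree`, `cost`, `degree`,
#'   `coef0`, `maxdepth`.
#' @param seed integer seed for stochastic learners (random forest).
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("tree", "fine_knn", "weighted_knn",
                                     "quadratic_svm", "random_forest"),
                            ..., seed = 1L) {
  name <- match.arg(name)
  hp <- switch(name,
    tree = list(maxdepth = 30, cp = 0),
    fine_knn = list(k = 1L),
    weighted_knn = list(k = 10L),
    quadratic_svm = list(degree = 2, cost = 1, coef0 = 1),
    random_forest = list(ntree = 30L))
  dots <- list(...)
  hp[names(dots)] <- dots
  if (any(vapply(hp, function(v) is.numeric(v) && v < 0, logical(1))))
    stop("hyperparameters must be nonnegative")
  structure(list(name = name, hyperparameters = hp,
                 standardize = name %in% c("fine_knn", "weighted_knn",
                                           "quadratic_svm"),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' The five default benchmark classifiers
#'
#' @param seed seed shared by the stochastic learners.
#' @return Named list of [classifier_spec()] objects in benchmark order.
#' @export
default_classifiers <- function(seed = 1L) {
  nm <- c("tree", "fine_knn", "weighted_knn", "quadratic_svm",
          "random_forest")
  setNames(lapply(nm, classifier_spec, seed = seed), nm)
}

# k-nearest-neighbor prediction, optionally squared-inverse-distance
# weighted (no installed package offers the weighted variant).
.knn_predict <- function(xtr, ytr, xte, k, weighted) {
  lev <- levels(ytr)
  tr_sq <- rowSums(xtr^2)
  pred <- character(nrow(xte))
  for (i in seq_len(nrow(xte))) {
    d2 <- pmax(tr_sq - 2 * drop(xtr %*% xte[i, ]) + sum(xte[i, ]^2), 0)
    ord <- order(d2)[seq_len(min(k, length(d2)))]
    if (!weighted) {
      votes <- table(ytr[ord])
      pred[i] <- names(votes)[which.max(votes)]
    } else {
      w <- 1 / pmax(d2[ord], 1e-12)
      score <- vapply(lev, function(cl) sum(w[ytr[ord] == cl]), numeric(1))
      pred[i] <- lev[which.max(score)]
    }
  }
  factor(pred, levels = lev)
}

# Fit on the training fold, predict the held-out fold.
.fit_predict <- function(spec, xtr, ytr, xte, fold_seed) {
  hp <- spec$hyperparameters
  if (spec$standardize) {
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, sd)
    sdv[sdv == 0] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
    xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
  }
  switch(spec$name,
    tree = {
      df <- data.frame(.y = ytr, xtr, check.names = TRUE)
      fit <- rpart::rpart(.y ~ ., df, method = "class",
                          control = rpart::rpart.control(
                            cp = hp$cp, maxdepth = hp$maxdepth,
                            xval = 0))
      nd <- data.frame(xte, check.names = TRUE)
      names(nd) <- names(df)[-1L]
      factor(as.character(predict(fit, nd, type = "class")),
             levels = levels(ytr))
    },
    fine_knn = .knn_predict(xtr, ytr, xte, hp$k, weighted = FALSE),
    weighted_knn = .knn_predict(xtr, ytr, xte, hp$k, weighted = TRUE),
    quadratic_svm = {
      fit <- e1071::svm(xtr, ytr, kernel = "polynomial",
                        degree = hp$degree, coef0 = hp$coef0,
                        cost = hp$cost, scale = FALSE)
      predict(fit, xte)
    },
    random_forest = with_private_seed(fold_seed, {
      fit <- randomForest::randomForest(xtr, ytr, ntree = hp$ntree)
      predict(fit, xte)
    }))
}

#' Classification metrics from a 2x2 confusion matrix
#'
#' @param confusion 2x2 nonnegative count matrix, rows = truth,
#'   columns = prediction, identical dimnames.
#' @return List with `accuracy` (percent), and per-class `precision`,
#'   `recall`, `f1` (named vectors in `[0, 1]`). Undefined ratios (zero
#'   denominator) are reported as 0 with a warning.
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0) || sum(confusion) == 0)
    stop("confusion matrix must be nonnegative with positive total")
  total <- sum(confusion)
  acc <- 100 * sum(diag(confusion)) / total
  safe_div <- function(num, den) {
    if (den == 0) {
      warning("undefined precision/recall (zero denominator); reporting 0")
      0
    } else num / den
  }
  classes <- rownames(confusion) %||% paste0("class", seq_len(nrow(confusion)))
  precision <- recall <- f1 <- setNames(numeric(nrow(confusion)), classes)
  for (i in seq_len(nrow(confusion))) {
    precision[i] <- safe_div(confusion[i, i], sum(confusion[, i]))
    recall[i] <- safe_div(confusion[i, i], sum(confusion[i, ]))
    f1[i] <- if (precision[i] + recall[i] == 0) 0
             else 2 * precision[i] * recall[i] / (precision[i] + recall[i])
  }
  list(accuracy = acc, precision = precision, recall = recall, f1 = f1)
}

# Seeded stratified fold assignment: within each class, shuffled indices
# are dealt round-robin into folds.
make_folds <- function(labels, n_folds, seed) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds)
      stop("class '", cl, "' has fewer members (", length(idx),
           ") than folds (", n_folds, ")")
    shuffled <- with_private_seed(seed + utf8ToInt(substr(cl, 1, 1)),
                                  sample(idx))
    fold[shuffled] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validated evaluation of one classifier
#'
#' Seeded stratified fold assignment; per fold the classifier is fitted on
#' the training portion (any standardization fitted on training data only)
#' and predicts the held-out fold. Metrics are pooled over folds.
#'
#' @param fm a [feature_matrix()].
#' @param spec a [classifier_spec()].
#' @param n_folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param folds optional externally supplied fold vector (used by
#'   [benchmark_all()] to pair classifiers on one partition).
#' @return An object of class `cv_report`: `classifier`, `fold_accuracy`
#'   (percent, per fold), `mean_accuracy` (percent, pooled), `confusion`,
#'   `precision`/`recall`/`f1` per class, `n_folds`, `seed`.
#' @export
stratified_kfold_eval <- function(fm, spec, n_folds = 5, seed = 1L,
                                  folds = NULL) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(spec, "classifier_spec"))
  x <- fm$features
  if (anyNA(x)) stop("feature matrix contains missing values")
  y <- factor(fm$labels)
  if (is.null(folds)) folds <- make_folds(y, n_folds, seed)
  pred <- factor(rep(levels(y)[1L], length(y)), levels = levels(y))
  fold_acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    te <- folds == f
    pf <- .fit_predict(spec, x[!te, , drop = FALSE], y[!te],
                       x[te, , drop = FALSE],
                       fold_seed = spec$seed * 1000L + f)
    pred[te] <- pf
    fold_acc[f] <- 100 * mean(pf == y[te])
  }
  confusion <- table(truth = y, prediction = pred)
  m <- compute_metrics(confusion)
  structure(list(classifier = spec$name, fold_accuracy = fold_acc,
                 mean_accuracy = m$accuracy, confusion = confusion,
                 precision = m$precision, recall = m$recall, f1 = m$f1,
                 n_folds = n_folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: %.2f%% accuracy (%d-fold CV)\n",
              x$classifier, x$mean_accuracy, x$n_folds))
  cat("  per-fold:", paste(sprintf("%.1f", x$fold_accuracy),
                           collapse = " "), "\n")
  invisible(x)
}

#' Benchmark several classifiers on one shared fold partition
#'
#' All classifiers are evaluated on the identical seeded stratified
#' partition, so their accuracies are paired comparisons.
#'
#' @param fm a [feature_matrix()].
#' @param specs list of [classifier_spec()]s (default all five presets).
#' @param n_folds folds (default 5).
#' @param seed fold-assignment seed.
#' @return Named list of `cv_report`s in spec order.
#' @export
benchmark_all <- function(fm, specs = default_classifiers(), n_folds = 5,
                          seed = 1L) {
  folds <- make_folds(fm$labels, n_folds, seed)
  reports <- lapply(specs, function(sp)
    stratified_kfold_eval(fm, sp, n_folds, seed, folds = folds))
  names(reports) <- vapply(specs, `[[`, "", "name")
  reports
}
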