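test_that("mutual information recovers exact dependence and independence", {
  labels <- rep(c("hand", "feet"), each = 50)
  feature <- as.integer(labels == "feet")
  # feature identical to a balanced binary label: MI = H(label) = ln 2
  expect_equal(mutual_information_score(feature, labels), log(2),
               tolerance = 1e-12)
  # exactly independent joint: p(a,b) = p(a)p(b) gives 0
  f2 <- rep(c(0, 1), times = 50)
  expect_equal(mutual_information_score(f2, labels), 0, tolerance = 1e-12)
  expect_warning(s <- mutual_information_score(rep(1, 100), labels),
                 "constant")
  expect_equal(s, 0)
  expect_error(mutual_information_score(1:5, labels), "equal length")
})

test_that("mutual information of independent draws vanishes with n", {
  set.seed(14)
  labels <- rep(c("hand", "feet"), each = 1000)
  scores <- replicate(5, mutual_information_score(rnorm(2000), labels))
  expect_true(all(scores <= 0.02))
})

test_that("chi-square statistic matches the hand-computed table", {
  # binary feature aligned with class: observed [[10,0],[0,10]],
  # expected [[5,5],[5,5]], statistic = 4 * 25/5 = 20
  labels <- rep(c("hand", "feet"), each = 10)
  feature <- as.integer(labels == "feet")
  res <- chi_square_score(feature, labels, n_bins = 2)
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)
  expect_equal(res$alpha, 0.05)
  # agreement with the textbook test statistic
  ref <- suppressWarnings(chisq.test(table(feature, labels),
                                     correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
})

test_that("chi-square is 0 with p-value 1 when observed equals expected", {
  labels <- rep(c("hand", "feet"), each = 10)
  feature <- rep(c(0, 1), times = 10)
  res <- chi_square_score(feature, labels, n_bins = 2)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("correlation coefficient handles exact linear relations", {
  a <- c(1, 2, 3)
  expect_equal(correlation_coefficient(a, 2 * a + 3), 1)
  expect_equal(correlation_coefficient(a, c(6, 4, 2)), -1)
  expect_equal(correlation_coefficient(a, c(1, 2, 4)),
               cor(a, c(1, 2, 4)))
  expect_gt(correlation_coefficient(a, c(1, 2, 4)), 0.98)
  expect_error(correlation_coefficient(a, c(1, 1, 1)), "constant")
})

test_that("correlation map flags duplicates and spares independents", {
  set.seed(6)
  x <- matrix(rnorm(5000), 1000, 5)
  x <- cbind(x, dup = x[, 1])
  cm <- correlation_map(x, threshold = 0.85)
  expect_equal(unname(diag(cm$r)), rep(1, 6))
  expect_true(all(abs(cm$r) <= 1 + 1e-12))
  expect_equal(cm$r, t(cm$r))
  expect_equal(nrow(cm$pairs), 1)
  expect_setequal(unlist(cm$pairs[1, c("i", "j")]), c(1, 6))
  expect_equal(cm$pairs$r[1], 1)
  # constant column warns and is zeroed
  expect_warning(cm2 <- correlation_map(cbind(x[, 1:2], k = 1)),
                 "constant")
  expect_true(all(cm2$r[3, -3] == 0))
})

test_that("greedy correlated-feature discard follows its rule", {
  set.seed(16)
  base <- matrix(rnorm(3000), 1000, 3)
  # no pair above threshold: everything survives
  cm <- correlation_map(base)
  expect_equal(discard_correlated(cm), 1:3)
  # one duplicated pair: the member more correlated overall is dropped
  extra <- base[, 1] + 0.3 * base[, 2]  # column 4 ~ column 1, plus pull to 2
  x <- cbind(base, extra)
  cm2 <- correlation_map(x, threshold = 0.9)
  surv <- discard_correlated(cm2)
  expect_length(surv, 3)
  expect_false(4 %in% surv)
  # three mutual duplicates collapse to a single survivor
  y <- cbind(base[, 1], base[, 1], base[, 1], base[, 2])
  surv3 <- discard_correlated(correlation_map(y))
  expect_length(surv3, 2)
  expect_true(4 %in% surv3)
  expect_length(intersect(surv3, 1:3), 1)
})

test_that("rank_features keeps its structural contracts", {
  fm <- informative_matrix(n = 200, seed = 2)
  for (m in c("mutual_information", "chi_square")) {
    rr <- rank_features(fm, m, seed = 5)
    expect_equal(rr$n_iterations, 10)
    k_expect <- if (m == "mutual_information") 6 else 5
    expect_length(rr$selected, k_expect)
    expect_true(all(rr$selected %in% 1:11))
    # each iteration's ranks are a permutation of 1..11
    for (it in 1:10)
      expect_setequal(rr$per_iteration_ranks[it, ], 1:11)
    # reproducible from the seed
    rr2 <- rank_features(fm, m, seed = 5)
    expect_identical(rr$per_iteration_scores, rr2$per_iteration_scores)
    expect_identical(rr$selected, rr2$selected)
  }
  expect_error(rank_features(fm, "chi_square", k = 0), "positive")
  expect_error(rank_features(fm, "chi_square", k = 12), "exceed")
})

test_that("a label-equal feature dominates every iteration", {
  fm <- informative_matrix(n = 200, shift = 0, seed = 3)
  fm$features[, 4] <- as.integer(fm$labels == "feet")
  rr <- rank_features(fm, "mutual_information", seed = 2)
  expect_true(all(rr$per_iteration_ranks[, 4] == 1))
  expect_true(4 %in% rr$selected)
})

test_that("informative features outrank noise for MI and chi-square", {
  fm <- informative_matrix(n = 400, seed = 8)
  rr_mi <- rank_features(fm, "mutual_information", seed = 1)
  rr_chi <- rank_features(fm, "chi_square", seed = 1)
  expect_true(all(1:3 %in% rr_mi$selected))
  expect_true(all(1:3 %in% rr_chi$selected))
})

test_that("scores are invariant to affine rescaling under equal-frequency binning", {
  set.seed(19)
  labels <- rep(c("hand", "feet"), each = 100)
  x <- rnorm(200) + 0.8 * (labels == "feet")
  y <- 5 * x - 7
  expect_equal(mutual_information_score(x, labels),
               mutual_information_score(y, labels), tolerance = 1e-12)
  expect_equal(chi_square_score(x, labels)$statistic,
               chi_square_score(y, labels)$statistic, tolerance = 1e-12)
  expect_equal(correlation_coefficient(x, rnorm(200) -> z),
               correlation_coefficient(y, z), tolerance = 1e-12)
})

test_that("correlation ranking selects the redundancy survivors", {
  fm <- informative_matrix(n = 300, seed = 4)
  fm$features[, 11] <- fm$features[, 1] + rnorm(300, sd = 0.01)
  rr <- rank_features(fm, "correlation", seed = 1)
  expect_false(all(c(1, 11) %in% rr$selected))
  expect_length(setdiff(1:11, rr$selected), 1)
})
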