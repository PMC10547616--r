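# Nonparametric statistics: Spearman, Wilcoxon, Jonckheere-Terpstra, ROC

test_that("spearman handles comonotone, antitone and tied data", {
  expect_equal(spearman_corr(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_corr(1:3, c(3, 2, 1))$rho, -1)
  r <- spearman_corr(1:5, c(2, 1, 4, 3, 5))
  rank_pearson <- stats::cor(rank(1:5), rank(c(2, 1, 4, 3, 5)))
  expect_equal(r$rho, rank_pearson, tolerance = 1e-12)
  # against base R as an independent implementation, with ties
  set.seed(51)
  for (i in 1:20) {
    x <- sample(1:6, 15, replace = TRUE)
    y <- x + sample(1:4, 15, replace = TRUE)
    ours <- spearman_corr(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(52)
  x <- rlnorm(40); y <- rnorm(40)
  base <- spearman_corr(x, y)
  for (f in list(log, sqrt, function(v) v^3, function(v) 5 * v + 2)) {
    expect_equal(spearman_corr(f(x), y)$rho, base$rho, tolerance = 1e-12)
  }
})

test_that("constant input gives an explicit undefined result", {
  r <- spearman_corr(rep(2, 10), rnorm(10))
  expect_true(r$undefined)
  expect_true(is.na(r$rho))
  expect_true(is.na(r$p_value))
})

test_that("wilcoxon exact p matches full enumeration on the extreme case", {
  # a = (1,2), b = (10,20): the most extreme of the C(4,2) = 6 labelings,
  # two-sided p = 2 * 1/6 = 1/3
  w <- wilcoxon_rank_sum(c(1, 2), c(10, 20))
  expect_equal(w$method, "exact_permutation")
  expect_equal(w$p_value, 1 / 3)
  expect_equal(w$statistic, 0)
})

test_that("identical groups are direction-free with p near 1", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_gte(w$p_value, 0.9)
  big <- wilcoxon_rank_sum(rnorm(30), rnorm(30))
  expect_true(big$method == "normal_approx")
})

test_that("a large shift is detected at p < 0.001", {
  set.seed(53)
  w <- wilcoxon_rank_sum(rnorm(40), rnorm(40) + 3)
  expect_lt(w$p_value, 1e-3)
})

test_that("wilcoxon agrees with base wilcox.test where both are exact", {
  set.seed(54)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(6)        # no ties -> wilcox.test exact
    ours <- wilcoxon_rank_sum(a, b)
    ref <- stats::wilcox.test(a, b)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("JT attains its extremes on perfectly ordered groups", {
  up <- jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)),
                            alternative = "increasing")
  expect_equal(up$jt_statistic, 12)       # max = sum n_i n_j
  down <- jonckheere_terpstra(list(c(5, 6), c(3, 4), c(1, 2)),
                              alternative = "increasing")
  expect_equal(down$jt_statistic, 0)
  expect_gt(down$p_value, 0.95)
  expect_lt(up$p_value, 0.05)
})

test_that("JT exact permutation equals the label-sequence enumeration oracle", {
  set.seed(55)
  for (i in 1:3) {
    groups <- split(sample(1:50, 9), rep(1:3, each = 3))  # all distinct
    ours <- jonckheere_terpstra(groups)
    expect_equal(ours$method, "exact_permutation")
    expect_equal(ours$jt_statistic, oracle_jt_stat(groups))
    dist <- oracle_jt_dist(unlist(groups), c(3L, 3L, 3L))
    expect_equal(length(dist), 1680L)
    p_oracle <- min(1, 2 * min(mean(dist >= ours$jt_statistic - 1e-9),
                               mean(dist <= ours$jt_statistic + 1e-9)))
    expect_equal(ours$p_value, p_oracle)
  }
})

test_that("JT normal approximation tracks the exact tail at n = 12", {
  set.seed(56)
  for (i in 1:5) {
    x <- rnorm(12) + 0.4 * rep(1:3, each = 4)      # continuous, untied
    groups <- split(x, rep(1:3, each = 4))
    exact <- jonckheere_terpstra(groups, method = "exact_permutation")
    approx <- jonckheere_terpstra(groups, method = "normal_approx")
    expect_lt(abs(exact$p_value - approx$p_value), 0.02)
    # heavy ties coarsen the lattice; agreement degrades but stays close
    tied <- split(round(x, 1), rep(1:3, each = 4))
    expect_lt(abs(jonckheere_terpstra(tied, method = "exact_permutation")$p_value -
                    jonckheere_terpstra(tied, method = "normal_approx")$p_value),
              0.05)
  }
})

test_that("ROC separates the separable and matches the pair-counting oracle", {
  perfect <- roc_analysis(c(1, 2, 3, 10, 11, 12),
                          c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE), boot = 0)
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$sensitivity, 1.0)
  expect_equal(perfect$specificity, 1.0)
  expect_equal(perfect$cut_point, 10)     # smallest maximizing threshold

  # 6-point toy with one tie straddling the classes
  scores <- c(1, 2, 2, 3, 4, 5)
  labels <- c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  r <- roc_analysis(scores, labels, boot = 0)
  expect_equal(r$auc, oracle_auc(scores, labels))

  set.seed(57)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    scores <- round(runif(n, 0, 4), 1)
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    r <- roc_analysis(scores, labels, boot = 0)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("label-independent scores give AUC near one half", {
  set.seed(58)
  r <- roc_analysis(rnorm(2000), rep(c(TRUE, FALSE), 1000), boot = 0)
  expect_lt(abs(r$auc - 0.5), 0.05)
  expect_gt(r$p_vs_half, 0.05)
})

test_that("the bootstrap CI brackets the point estimate and is seeded", {
  set.seed(59)
  scores <- c(rnorm(20), rnorm(20) + 1.5)
  labels <- rep(c(FALSE, TRUE), each = 20)
  set.seed(100); a <- roc_analysis(scores, labels, boot = 500)
  set.seed(100); b <- roc_analysis(scores, labels, boot = 500)
  expect_identical(a$ci_95, b$ci_95)
  expect_lte(a$ci_95[1], a$auc); expect_gte(a$ci_95[2], a$auc)
  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "both classes")
})
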