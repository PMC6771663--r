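test_that("one-way ANOVA matches hand-computed sums of squares", {
  vals <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- oneway_anova(vals, grp)
  # SSB = 42, SSW = 6 -> F = 21 on (2, 6)
  expect_equal(res$statistic, 21, tolerance = 1e-12)
  expect_equal(res$df, c(2, 6))
  expect_lt(res$p_value, 0.01)

  # identical groups: F = 0
  same <- oneway_anova(rep(c(1, 2, 3), 3), grp)
  expect_equal(same$statistic, 0, tolerance = 1e-12)

  # two groups: F equals the squared pooled-variance t statistic
  x <- c(4.1, 5.2, 6.3, 5.5); y <- c(7.7, 8.1, 6.9, 9 , 8.4)
  f2 <- oneway_anova(c(x, y), rep(c("g1", "g2"), c(4, 5)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(f2$statistic, unname(tt$statistic)^2, tolerance = 1e-12)

  expect_error(oneway_anova(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("Tukey HSD separates distant means and is order-invariant", {
  set.seed(9)
  vals <- c(rnorm(8, 0), rnorm(8, 0.2), rnorm(8, 8))
  grp <- rep(c("x", "y", "z"), each = 8)
  tk <- tukey_hsd(vals, grp)
  det <- tk$details
  expect_lt(det$p_adj[det$comparison == "z-x"], 0.001)
  expect_gt(det$p_adj[det$comparison == "y-x"], 0.1)

  # identical groups: all adjusted p near 1
  tk0 <- tukey_hsd(rep(c(1, 2, 3, 4), 3), rep(c("x", "y", "z"), each = 4))
  expect_true(all(tk0$details$p_adj > 0.999))

  # relabelling groups permutes rows but not the p-values
  tk2 <- tukey_hsd(vals, factor(grp, levels = c("z", "y", "x")))
  expect_equal(sort(tk2$details$p_adj), sort(det$p_adj), tolerance = 1e-10)
})

test_that("normality and variance-homogeneity gates report standard stats", {
  set.seed(10)
  sw <- normality_test(rnorm(30))
  expect_true(sw$p_value >= 0 && sw$p_value <= 1)
  expect_error(normality_test(c(1, 2)), "at least 3")

  # equal variances: Bartlett statistic ~ 0
  b0 <- variance_homogeneity_test(c(1, 2, 3, 11, 12, 13),
                                  rep(c("a", "b"), each = 3))
  expect_equal(b0$statistic, 0, tolerance = 1e-10)

  # hand-evaluated Bartlett formula on a 2-group fixture
  g1 <- c(1, 2, 3); g2 <- c(10, 20, 30)
  k <- 2; n <- c(3, 3); N <- 6
  s2 <- c(var(g1), var(g2))
  sp2 <- sum((n - 1) * s2) / (N - k)
  stat <- ((N - k) * log(sp2) - sum((n - 1) * log(s2))) /
    (1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1)))
  bt <- variance_homogeneity_test(c(g1, g2), rep(c("a", "b"), each = 3))
  expect_equal(bt$statistic, stat, tolerance = 1e-12)
  expect_equal(bt$df, 1)
})

test_that("distance-distribution homogeneity uses the pooled chi-square", {
  mk <- function(counts, bw = 4, w = 8) {
    # construct binned objects from explicit per-bin counts
    x <- unlist(mapply(function(k, lo) rep(lo + bw / 2, k), counts,
                       seq(0, w - bw, by = bw)))
    bin_distances(x, bw, w)
  }
  # 2 x 2 fixture {{10,10},{10,30}} -> X2 = 3.75 on 1 df
  res <- distance_distribution_homogeneity(list(a = mk(c(10, 10)),
                                                b = mk(c(10, 30))))
  expect_equal(res$statistic, 3.75, tolerance = 1e-12)
  expect_equal(res$df, 1)

  # proportional distributions: statistic ~ 0
  res0 <- distance_distribution_homogeneity(list(a = mk(c(10, 20)),
                                                 b = mk(c(30, 60))))
  expect_equal(res0$statistic, 0, tolerance = 1e-10)

  # df follows the contingency rule on the pooled table
  mk3 <- function(counts) mk(counts, 4, 12)
  res3 <- distance_distribution_homogeneity(list(
    a = mk3(c(20, 15, 10)), b = mk3(c(18, 12, 9)), c = mk3(c(25, 20, 12))))
  expect_equal(res3$df, (3 - 1) * (3 - 1))

  expect_error(distance_distribution_homogeneity(list(mk(c(1, 2)))), "2")
  expect_error(distance_distribution_homogeneity(
    list(a = mk(c(10, 10)), b = bin_distances(1:5, 4, 12))), "bin edges")
})

test_that("comparison tests are pure functions of their inputs", {
  vals <- c(1.2, 3.1, 2.2, 4.5, 3.3, 5.1)
  grp <- rep(c("a", "b"), each = 3)
  expect_identical(oneway_anova(vals, grp), oneway_anova(vals, grp))
  expect_identical(variance_homogeneity_test(vals, grp),
                   variance_homogeneity_test(vals, grp))
})
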