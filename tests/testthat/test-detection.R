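test_that("distances are binned half-open with truncation", {
  b <- bin_distances(c(0.5, 3.9, 4.0, 39.9, 41.2))
  expect_equal(length(b$counts), 10)         # 40 m / 4 m
  expect_equal(b$counts[1], 2)               # [0, 4)
  expect_equal(b$counts[2], 1)               # [4, 8): the 4.0 boundary value
  expect_equal(b$counts[10], 1)              # [36, 40)
  expect_equal(b$n_discarded, 1)
  expect_equal(sum(b$counts) + b$n_discarded, 5)

  empty <- bin_distances(numeric(0))
  expect_equal(sum(empty$counts), 0)
  expect_equal(length(empty$counts), 10)

  # a distance exactly at w falls outside the half-open final bin
  expect_equal(bin_distances(40)$n_discarded, 1)
  expect_error(bin_distances(1, bin_width_m = 0), "> 0")
})

test_that("detection keys evaluate to their closed forms with g(0)=1", {
  expect_equal(detection_probability(0, "half_normal", sigma = 12), 1)
  expect_equal(detection_probability(12, "half_normal", sigma = 12),
               exp(-0.5))
  expect_equal(detection_probability(c(0, 7, 39), "uniform"), c(1, 1, 1))
  expect_equal(detection_probability(0, "hazard_rate", sigma = 10,
                                     shape = 3), 1)
  expect_error(detection_probability(1, "half_normal", sigma = -1), "sigma")
  expect_error(detection_probability(1, "hazard_rate", sigma = 1,
                                     shape = 0), "shape")
  # cosine adjustment is rescaled so that g(0) stays 1
  expect_equal(detection_probability(0, "half_normal", sigma = 12,
                                     adjustment = "cosine",
                                     adj_coefs = 0.3), 1)
})

test_that("binned likelihood matches brute-force multinomial evaluation", {
  # uniform key, no adjustments: pi_i = bin width / w in closed form
  set.seed(1)
  b <- bin_distances(runif(200, 0, 40))
  f <- fit_detection(b, "uniform", "none")
  expect_equal(f$log_likelihood, sum(b$counts * log(4 / 40)))
  expect_equal(f$n_params, 0)
  expect_equal(f$aic, -2 * f$log_likelihood)

  # 3-bin toy at an arbitrary half-normal parameter point
  toy <- bin_distances(c(1, 2, 6, 7, 8, 13), bin_width_m = 5,
                       truncation_w_m = 15)
  sigma <- 8
  ints <- nestdensity:::.cell_integrals(toy$bin_edges_m, "half_normal",
                                        sigma, NULL, "none", numeric(0))
  # independent oracle: normal-CDF integrals of exp(-x^2 / 2 sigma^2)
  cdf_int <- sigma * sqrt(2 * pi) *
    diff(pnorm(toy$bin_edges_m / sigma))
  expect_equal(ints, cdf_int, tolerance = 1e-12)
  pi_i <- cdf_int / sum(cdf_int)
  ll_brute <- log(prod(pi_i^toy$counts))
  expect_equal(nestdensity:::.binned_loglik(toy$counts, ints), ll_brute,
               tolerance = 1e-10)
})

test_that("effective strip width matches closed forms and bounds", {
  set.seed(2)
  b <- bin_distances(runif(300, 0, 40))
  unif <- fit_detection(b, "uniform", "none")
  expect_equal(effective_strip_width(unif), 40, tolerance = 1e-9)

  set.seed(3)
  hb <- bin_distances(rhalfnorm(800, 10))
  hn <- fit_detection(hb, "half_normal", "none")
  expect_equal(effective_strip_width(hn),
               esw_halfnormal(hn$sigma, 40), tolerance = 1e-6)
  expect_lte(hn$esw_m, 40)

  # with the truncation pushed far out, ESW approaches sigma * sqrt(pi/2)
  expect_equal(effective_strip_width(hn, truncation_w_m = 300),
               hn$sigma * sqrt(pi / 2), tolerance = 1e-6)

  # ESW depends only on proportions: replicating every nest changes nothing
  set.seed(4)
  x <- rhalfnorm(400, 12)
  f1 <- fit_detection(bin_distances(x), "half_normal", "cosine")
  f3 <- fit_detection(bin_distances(rep(x, 3)), "half_normal", "cosine")
  expect_equal(f1$esw_m, f3$esw_m, tolerance = 1e-4)
})

test_that("half-normal parameters are recovered from binned data", {
  set.seed(42)
  b <- bin_distances(rhalfnorm(1000, 12.4))
  f <- fit_detection(b, "half_normal", "cosine")
  expect_true(f$converged)
  expect_lt(abs(f$sigma - 12.4) / 12.4, 0.10)
  expect_true(f$monotone_ok)
  expect_equal(f$aic, -2 * f$log_likelihood + 2 * f$n_params)
})

test_that("degenerate single-bin data is flagged, not fatal", {
  b <- bin_distances(runif(50, 0, 3.9))
  f <- fit_detection(b, "half_normal", "none")
  expect_true(f$boundary)
})

test_that("model selection follows AIC with deterministic tie-breaking", {
  fake <- function(aic, n_params, key) {
    structure(list(key = key, adjustment = "cosine", n_adj_terms = 0L,
                   sigma = 10, shape = NA_real_, adj_coefs = numeric(0),
                   log_likelihood = -aic / 2, n_params = n_params,
                   aic = aic, esw_m = 15,
                   gof = list(chi2 = 1, df = 1, p = 0.5),
                   monotone_ok = TRUE, converged = TRUE, boundary = FALSE,
                   binned = bin_distances(1:10)),
              class = "detection_fit")
  }
  a <- fake(100.0, 3, "hazard_rate"); b <- fake(102.3, 2, "half_normal")
  expect_equal(select_best_model(list(a, b))$aic, 100.0)

  # equal AIC: fewest parameters wins
  c2 <- fake(100.0, 2, "hazard_rate")
  expect_equal(select_best_model(list(a, c2))$n_params, 2)

  # equal AIC and parameters: fixed key order
  u <- fake(100.0, 2, "uniform")
  expect_equal(select_best_model(list(c2, u))$key, "uniform")

  # non-monotone and non-converged fits are never selected
  bad <- fake(90, 1, "half_normal"); bad$monotone_ok <- FALSE
  expect_equal(select_best_model(list(bad, a))$aic, 100.0)
  expect_error(select_best_model(list(bad)), "monotone")
})

test_that("goodness of fit pools sparse bins and matches hand values", {
  # uniform fit on two equal bins: expected = (7.5, 7.5) against (10, 5)
  x <- c(runif(10, 0, 4), runif(5, 4, 8))
  b <- bin_distances(x, bin_width_m = 4, truncation_w_m = 8)
  f <- fit_detection(b, "uniform", "none")
  g <- f$gof
  expect_equal(g$chi2, 2.5^2 / 7.5 + 2.5^2 / 7.5, tolerance = 1e-12)
  expect_equal(g$df, 1)
  expect_true(g$p >= 0 && g$p <= 1)

  # observed equal to expected gives chi-square zero
  xb <- bin_distances(rep(c(1, 5), each = 6), bin_width_m = 4,
                      truncation_w_m = 8)
  f2 <- fit_detection(xb, "uniform", "none")
  expect_equal(f2$gof$chi2, 0, tolerance = 1e-12)
})

test_that("the six-model set reports and selects sensibly on real shapes", {
  set.seed(7)
  b <- bin_distances(rhalfnorm(600, 12.4))
  fits <- fit_detection_set(b)
  expect_length(fits, 6)
  tab <- detection_table(fits)
  expect_setequal(unique(tab$key), c("uniform", "half_normal", "hazard_rate"))
  best <- select_best_model(fits)
  truth <- esw_halfnormal(12.4, 40)
  expect_lt(abs(best$esw_m - truth) / truth, 0.10)
})
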