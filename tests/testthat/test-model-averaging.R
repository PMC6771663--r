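test_that("Gelman standardisation rescales to sd 0.5 and centres dummies", {
  s <- standardize_predictors(data.frame(x = c(1, 2, 3)))
  expect_equal(s$x, c(-0.5, 0, 0.5))
  expect_equal(sd(s$x), 0.5)

  # idempotence
  s2 <- standardize_predictors(s)
  expect_equal(s2$x, s$x, tolerance = 1e-12)

  # binary dummy: centred, never rescaled
  d <- standardize_predictors(data.frame(z = c(0, 1, 1)))
  expect_equal(d$z, c(-2 / 3, 1 / 3, 1 / 3))

  expect_error(standardize_predictors(data.frame(k = c(2, 2, 2))), "'k'")

  rec <- attr(standardize_predictors(data.frame(x = 1:4, z = rep(0:1, 2))),
              "standardization")
  expect_equal(rec$binary, c(FALSE, TRUE))
})

test_that("collinearity screening flags pairs at the 0.7 boundary", {
  set.seed(11)
  x <- rnorm(200)
  dup <- data.frame(a = x, b = x, c = rnorm(200))
  sc <- collinearity_screen(dup)
  expect_true(any(sc$pairs$var1 == "a" & sc$pairs$var2 == "b"))
  expect_equal(abs(sc$pairs$r[1]), 1, tolerance = 1e-12)

  # strict threshold: r = 0.69 passes, r = 0.70 is flagged
  mk_pair <- function(r, n = 400) {
    u <- rnorm(n); v <- residuals(lm(rnorm(n) ~ u))
    u <- as.numeric(scale(u)); v <- as.numeric(scale(v))
    data.frame(p = u, q = r * u + sqrt(1 - r^2) * v)
  }
  just_below <- mk_pair(0.69)
  expect_equal(cor(just_below$p, just_below$q), 0.69, tolerance = 1e-9)
  expect_equal(nrow(collinearity_screen(just_below)$pairs), 0)
  at <- mk_pair(0.70)
  expect_equal(nrow(collinearity_screen(at)$pairs), 1)

  # independent standard normals at n = 1000: no flags
  set.seed(12)
  ind <- as.data.frame(matrix(rnorm(5000), 1000, 5))
  sc2 <- collinearity_screen(ind)
  expect_equal(nrow(sc2$pairs), 0)
  expect_length(sc2$flagged_gvif, 0)
})

test_that("the determinant GVIF matches car's on a factor design", {
  skip_if_not_installed("car")
  set.seed(13)
  n <- 120
  h <- factor(rep(c("logged_forest", "salvage_logged", "oil_palm_remnant"),
                  length.out = n))
  x1 <- rnorm(n) + as.integer(h)
  x2 <- rnorm(n)
  y <- rnorm(n)
  mm <- stats::model.matrix(~h)[, -1]
  dat <- data.frame(x1 = x1, x2 = x2, mm)
  sc <- collinearity_screen(dat, term_cols = list(x1 = 1, x2 = 2,
                                                  habitat = c(3, 4)))
  vf <- car::vif(stats::lm(y ~ x1 + x2 + h))
  expect_equal(unname(sc$gvif[c("x1", "x2", "habitat")]),
               unname(vf[c("x1", "x2", "h"), "GVIF"]), tolerance = 1e-8)
})

test_that("model enumeration respects exclusions and always keeps the null", {
  m3 <- enumerate_models(c("a", "b", "c"))
  expect_length(m3, 8)
  expect_identical(m3[[1]], character(0))

  excl <- data.frame(var1 = "a", var2 = "b")
  m7 <- enumerate_models(letters[1:7], excl)
  expect_length(m7, 2^7 - 2^5)     # 96: subsets containing both a and b drop
  expect_true(all(!vapply(m7, function(s) all(c("a", "b") %in% s),
                          logical(1))))
  expect_error(enumerate_models(c("a", "b"),
                                data.frame(var1 = "a", var2 = "zz")), "zz")
})

test_that("OLS fits report ML likelihood and the small-sample AICc", {
  x <- 1:10
  f <- fit_linear_model(2 * x, data.frame(x = x))
  expect_equal(unname(f$coefficients["x"]), 2)
  expect_equal(f$sigma2_ml, 0)

  set.seed(14)
  y <- rnorm(20); X <- data.frame(x = rnorm(20))
  f0 <- fit_linear_model(y)
  expect_equal(unname(f0$coefficients["(Intercept)"]), mean(y))
  f1 <- fit_linear_model(y, X)
  expect_gt(f1$aicc, f1$aic)
  # against stats::lm ML likelihood and coefficient covariance
  lf <- lm(y ~ x, data = X)
  expect_equal(f1$log_likelihood, as.numeric(logLik(lf)), tolerance = 1e-10)
  expect_equal(f1$k, attr(logLik(lf), "df"))
  expect_equal(unname(f1$coefficients), unname(coef(lf)), tolerance = 1e-10)
  expect_equal(unname(f1$vcov), unname(vcov(lf)), tolerance = 1e-10)

  expect_error(fit_linear_model(y, data.frame(a = rep(1, 20))), "singular")
})

test_that("Akaike weights follow the closed form and sum to one", {
  w <- akaike_weights(c(100, 102))
  expect_equal(round(w, 3), c(0.731, 0.269))
  expect_equal(akaike_weights(55.5), 1)
  set.seed(15)
  expect_equal(sum(akaike_weights(runif(40, 100, 150))), 1)
})

test_that("full averaging matches the brute-force oracle to 1e-10", {
  set.seed(16)
  n <- 24
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- 1 + 0.8 * X$x1 - 0.3 * X$x3 + rnorm(n, 0, 0.5)

  subsets <- enumerate_models(c("x1", "x2", "x3"))
  fits <- lapply(subsets, function(s)
    fit_linear_model(y, X[, s, drop = FALSE]))
  avg <- average_coefficients(fits)

  oracle <- brute_force_average(y, as.matrix(X), subsets)
  idx <- match(avg$term, oracle$coefficients$term)
  expect_equal(avg$estimate, oracle$coefficients$estimate[idx],
               tolerance = 1e-10)
  expect_equal(avg$se, oracle$coefficients$se[idx], tolerance = 1e-10)
  expect_equal(avg$importance, oracle$coefficients$importance[idx],
               tolerance = 1e-10)
  # the CI is the normal interval around the full-average estimate
  expect_equal(avg$ci_upper - avg$estimate, qnorm(0.975) * avg$se)
  expect_true(all(avg$ci_lower <= avg$estimate & avg$estimate <= avg$ci_upper))
})

test_that("zero substitution and zero-weight models behave as defined", {
  mk_fit <- function(coefs, vars, aicc) {
    vc <- diag(vars, length(coefs))
    dimnames(vc) <- list(names(coefs), names(coefs))
    structure(list(coefficients = coefs, vcov = vc, aicc = aicc),
              class = "ols_fit")
  }
  f1 <- mk_fit(c(`(Intercept)` = 1, x = 4), c(0.1, 0.2), 100)
  f2 <- mk_fit(c(`(Intercept)` = 1.5), 0.1, 100)
  avg <- average_coefficients(list(f1, f2), weights = c(0.5, 0.5))
  expect_equal(avg$estimate[avg$term == "x"], 2)       # 0.5*4 + 0.5*0
  expect_equal(avg$importance[avg$term == "x"], 0.5)

  # a single model: averaging is the identity
  one <- average_coefficients(list(f1), weights = 1)
  expect_equal(one$estimate[one$term == "x"], 4)
  expect_equal(one$importance, c(1, 1))

  # removing a zero-weight model changes nothing
  f3 <- mk_fit(c(`(Intercept)` = 9, x = -50), c(1, 1), 100 + 2000)
  with3 <- average_coefficients(list(f1, f2, f3))
  without3 <- average_coefficients(list(f1, f2))
  expect_equal(with3$estimate, without3$estimate, tolerance = 1e-10)
  expect_equal(with3$se, without3$se, tolerance = 1e-10)
})

test_that("model_average equals the oracle on standardised predictors", {
  set.seed(17)
  n <- 30
  dat <- data.frame(canopy_height_mean_m = rnorm(n, 15, 3),
                    canopy_height_sd_m = rnorm(n, 6, 1.5),
                    n_layers = rnorm(n, 4, 1))
  y <- 2 + 0.2 * dat$canopy_height_sd_m + rnorm(n, 0, 0.4)
  ma <- model_average(y, dat)
  expect_length(ma$fits, 8)

  Xstd <- standardize_predictors(dat)
  oracle <- brute_force_average(y, as.matrix(Xstd))
  idx <- match(ma$coefficients$term, oracle$coefficients$term)
  expect_equal(ma$coefficients$estimate, oracle$coefficients$estimate[idx],
               tolerance = 1e-10)
  expect_equal(ma$coefficients$se, oracle$coefficients$se[idx],
               tolerance = 1e-10)
  expect_equal(sum(ma$weights), 1)
  expect_equal(ma$models$weight[1], max(ma$weights))
})

test_that("Cook's distance flags a gross high-leverage outlier", {
  x <- c(seq(1, 10), 25)
  y <- 2 * x + rnorm(11, 0, 0.3)
  y[11] <- 200                      # gross outlier at the leverage point
  f <- fit_linear_model(y, data.frame(x = x))
  d <- cooks.distance(f)
  expect_true(all(d >= 0))
  expect_gt(d[11], 1)
  # agrees with the stats implementation on the same design
  expect_equal(unname(d), unname(cooks.distance(lm(y ~ x))),
               tolerance = 1e-10)

  # balanced design without outliers: all D below 1
  set.seed(18)
  xb <- rep(1:6, 4); yb <- 1 + 0.5 * xb + rnorm(24, 0, 0.5)
  fb <- fit_linear_model(yb, data.frame(x = xb))
  expect_true(all(cooks.distance(fb) < 1))

  # model_average reports both coefficient sets when a row is flagged
  dat <- data.frame(canopy_height_sd_m = x)
  ma <- model_average(y, dat)
  expect_equal(ma$cooks$flagged, 11L)
  expect_false(is.null(ma$without_outliers))
})

test_that("averaged intervals cover zero at the nominal rate", {
  set.seed(19)
  n_sim <- 200
  covered <- 0; total <- 0
  for (i in seq_len(n_sim)) {
    n <- 40
    X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    y <- rnorm(n)                  # all true effects zero
    subsets <- enumerate_models(c("a", "b", "c"))
    fits <- lapply(subsets, function(s)
      fit_linear_model(y, X[, s, drop = FALSE]))
    avg <- average_coefficients(fits)
    sl <- avg[avg$term != "(Intercept)", ]
    covered <- covered + sum(sl$ci_lower <= 0 & 0 <= sl$ci_upper)
    total <- total + nrow(sl)
  }
  expect_gt(covered / total, 0.90)
})
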