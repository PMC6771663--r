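# in-code fixtures shared across test files

tiny_transects <- function() {
  data.frame(id = c("T1", "T2", "T3"),
             habitat = c("logged_forest", "salvage_logged",
                         "oil_palm_remnant"),
             length_km = c(1.5, 2.0, 1.0), stringsAsFactors = FALSE)
}

tiny_nests <- function() {
  data.frame(transect_id = c("T1", "T1", "T2", "T3", "T3"),
             perp_distance_m = c(0.5, 12.3, 7.7, 30.1, 2.0),
             decay_class = c("A", "C", "B", "E", "D"),
             stringsAsFactors = FALSE)
}

tiny_covariates <- function() {
  data.frame(transect_id = c("T1", "T2", "T3"),
             canopy_height_mean_m = c(22, 14, 10),
             canopy_height_sd_m = c(6.5, 6.0, 5.0),
             n_layers = c(5, 4, 3), shannon_pai = c(1.8, 1.5, 1.2),
             forest_cover_pct = c(95, 70, 35),
             dist_to_forest_m = c(400, 1500, 3500),
             stringsAsFactors = FALSE)
}

write_tiny_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  tp <- file.path(dir, "transects.csv")
  np <- file.path(dir, "nests.csv")
  cp <- file.path(dir, "covariates.csv")
  write.csv(tiny_transects(), tp, row.names = FALSE)
  write.csv(tiny_nests(), np, row.names = FALSE)
  write.csv(tiny_covariates(), cp, row.names = FALSE)
  list(transects = tp, nests = np, covariates = cp, dir = dir)
}

# draw n half-normal perpendicular distances (scale sigma)
rhalfnorm <- function(n, sigma) abs(rnorm(n, 0, sigma))

# closed-form half-normal ESW at truncation w
esw_halfnormal <- function(sigma, w) {
  sigma * sqrt(pi / 2) * pracma::erf(w / (sigma * sqrt(2)))
}

# brute-force full-model-averaging oracle built on stats::lm; enumerates
# the given term subsets independently of the package machinery
brute_force_average <- function(y, X, subsets = NULL) {
  vars <- colnames(X)
  if (is.null(subsets)) {
    subsets <- list(character(0))
    for (k in seq_along(vars))
      subsets <- c(subsets, combn(vars, k, simplify = FALSE))
  }
  df <- data.frame(y = y, X)
  fits <- lapply(subsets, function(s) {
    f <- if (length(s)) stats::reformulate(s, "y") else y ~ 1
    stats::lm(f, data = df)
  })
  n <- length(y)
  ll <- vapply(fits, function(f) as.numeric(stats::logLik(f)), numeric(1))
  k <- vapply(fits, function(f) attr(stats::logLik(f), "df"), numeric(1))
  aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  d <- aicc - min(aicc)
  w <- exp(-d / 2); w <- w / sum(w)
  terms <- unique(unlist(lapply(fits, function(f) names(stats::coef(f)))))
  out <- lapply(terms, function(tm) {
    est <- vapply(fits, function(f) {
      cf <- stats::coef(f)
      if (tm %in% names(cf)) unname(cf[tm]) else 0
    }, numeric(1))
    vr <- vapply(fits, function(f) {
      vc <- stats::vcov(f)
      if (tm %in% rownames(vc)) vc[tm, tm] else 0
    }, numeric(1))
    has <- vapply(fits, function(f) tm %in% names(stats::coef(f)), logical(1))
    bbar <- sum(w * est)
    se <- sqrt(sum(w * (vr + (est - bbar)^2)))
    data.frame(term = tm, estimate = bbar, se = se,
               importance = sum(w[has]), stringsAsFactors = FALSE)
  })
  list(coefficients = do.call(rbind, out), weights = w, aicc = aicc)
}
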