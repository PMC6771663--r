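#' Bin perpendicular distances for detection-function fitting
#'
#' Aggregates perpendicular nest distances into equal-width distance
#' classes and truncates the tail. Spiked or heaped distance data are
#' conventionally grouped before fitting; the defaults (4 m classes,
#' 40 m truncation) follow common practice for orang-utan nest surveys.
#' Bins are half-open `[lower, upper)`; distances at or beyond the
#' truncation point are discarded and counted in `n_discarded`.
#'
#' @param distances_m numeric vector of perpendicular distances (m), >= 0.
#' @param bin_width_m distance-class width in metres, default 4.
#' @param truncation_w_m truncation distance `w` in metres, default 40.
#' @return An object of class `binned_distances`: list with
#'   `bin_edges_m`, `counts`, `truncation_w_m`, `n_discarded`.
#' @examples
#' bin_distances(c(0.5, 3.9, 4.0, 39.9, 41.2))
#' @export
bin_distances <- function(distances_m, bin_width_m = 4, truncation_w_m = 40) {
  if (!is.numeric(bin_width_m) || bin_width_m <= 0)
    stop("'bin_width_m' must be > 0")
  if (!is.numeric(truncation_w_m) || truncation_w_m <= 0)
    stop("'truncation_w_m' must be > 0")
  distances_m <- as.numeric(distances_m)
  if (any(!is.finite(distances_m)) || any(distances_m < 0))
    stop("distances must be finite and >= 0")
  edges <- seq(0, truncation_w_m, by = bin_width_m)
  if (edges[length(edges)] < truncation_w_m) edges <- c(edges, truncation_w_m)
  nb <- length(edges) - 1L
  keep <- distances_m < truncation_w_m
  idx <- findInterval(distances_m[keep], edges)  # [edges[i], edges[i+1])
  counts <- tabulate(idx, nbins = nb)
  structure(list(bin_edges_m = edges, counts = counts,
                 truncation_w_m = truncation_w_m,
                 n_discarded = sum(!keep)),
            class = "binned_distances")
}

#' @export
print.binned_distances <- function(x, ...) {
  nb <- length(x$counts)
  cat(sprintf("Binned distances: %d nests in %d bins to w = %g m (%d discarded)\n",
              sum(x$counts), nb, x$truncation_w_m, x$n_discarded))
  lab <- sprintf("[%g,%g)", x$bin_edges_m[-(nb + 1)], x$bin_edges_m[-1])
  print(setNames(x$counts, lab))
  invisible(x)
}

DETECTION_KEYS <- c("uniform", "half_normal", "hazard_rate")
ADJUSTMENTS <- c("none", "cosine", "simple_poly", "hermite")
.key_npar <- c(uniform = 0L, half_normal = 1L, hazard_rate = 2L)

# probabilists' Hermite polynomial He_n(z) by recurrence
.hermite <- function(z, n) {
  if (n == 0) return(rep(1, length(z)))
  hm1 <- rep(1, length(z)); h <- z
  if (n == 1) return(h)
  for (k in 1L:(n - 1L)) {
    hp1 <- z * h - k * hm1
    hm1 <- h; h <- hp1
  }
  h
}

# series terms evaluated at x: one column per adjustment term j = 1..m
.series_matrix <- function(x, adjustment, m, w, sigma) {
  vapply(seq_len(m), function(j) {
    switch(adjustment,
      cosine      = cos(j * pi * x / w),
      simple_poly = (x / w)^(2 * j),
      hermite     = .hermite(x / sigma, 2L * j),
      stop("unknown adjustment series: ", adjustment))
  }, numeric(length(x)))
}

# unscaled detection function: key(x) * (1 + sum_j a_j s_j(x))
.g_base <- function(x, key, sigma = NULL, shape = NULL,
                    adjustment = "none", adj_coefs = numeric(0), w) {
  k <- switch(key,
    uniform     = rep(1, length(x)),
    half_normal = exp(-x^2 / (2 * sigma^2)),
    hazard_rate = ifelse(x <= 0, 1, 1 - exp(-(x / sigma)^(-shape))))
  if (length(adj_coefs)) {
    s <- .series_matrix(x, adjustment, length(adj_coefs), w, sigma)
    k <- k * (1 + drop(s %*% adj_coefs))
  }
  k
}

#' Detection probability g(x)
#'
#' Evaluates the detection function at perpendicular distance `x`:
#' `uniform` g(x) = 1, `half_normal` g(x) = exp(-x^2 / (2 sigma^2)),
#' `hazard_rate` g(x) = 1 - exp(-(x/sigma)^-b). With a series adjustment
#' the key is multiplied by `1 + sum_j a_j s_j(x)` and rescaled so that
#' g(0) = 1 (certain detection on the line).
#'
#' @param x_m perpendicular distance(s), metres, within `[0, w]`.
#' @param key one of `"uniform"`, `"half_normal"`, `"hazard_rate"`.
#' @param sigma key scale parameter (m), required except for the uniform key.
#' @param shape hazard-rate shape parameter b > 0.
#' @param adjustment series type: `"none"`, `"cosine"` (term j:
#'   `cos(j*pi*x/w)`), `"simple_poly"` (`(x/w)^(2j)`) or `"hermite"`
#'   (`He_[2j](x/sigma)`).
#' @param adj_coefs numeric vector of adjustment coefficients `a_j`.
#' @param truncation_w_m truncation distance `w` (m), default 40.
#' @return Numeric vector of detection probabilities (g(0) = 1).
#' @examples
#' detection_probability(12, "half_normal", sigma = 12)  # exp(-0.5)
#' @export
detection_probability <- function(x_m, key = DETECTION_KEYS, sigma = NULL,
                                  shape = NULL, adjustment = "none",
                                  adj_coefs = numeric(0),
                                  truncation_w_m = 40) {
  key <- match.arg(key)
  adjustment <- match.arg(adjustment, ADJUSTMENTS)
  if (key != "uniform") {
    if (is.null(sigma) || !is.finite(sigma) || sigma <= 0)
      stop("'sigma' must be > 0 for the ", key, " key")
  }
  if (key == "hazard_rate") {
    if (is.null(shape) || !is.finite(shape) || shape <= 0)
      stop("'shape' must be > 0 for the hazard-rate key")
  }
  if (adjustment == "hermite" && is.null(sigma))
    stop("hermite adjustments require a key with a scale parameter")
  if (length(adj_coefs) == 0 && adjustment != "none") adjustment <- "none"
  g0 <- .g_base(0, key, sigma, shape, adjustment, adj_coefs, truncation_w_m)
  if (!is.finite(g0) || g0 <= 0)
    stop("invalid adjustment coefficients: g(0) <= 0 before rescaling")
  .g_base(x_m, key, sigma, shape, adjustment, adj_coefs, truncation_w_m) / g0
}

# Gauss-Legendre nodes/weights on [0,1], cached
.gl01 <- local({
  cache <- NULL
  function(n = 10) {
    if (is.null(cache)) {
      gl <- pracma::gaussLegendre(n, 0, 1)
      cache <<- gl
    }
    cache
  }
})

# integral of the rescaled g over each bin; NA signals an invalid shape
.cell_integrals <- function(edges, key, sigma, shape, adjustment, coefs) {
  w <- edges[length(edges)]
  g0 <- .g_base(0, key, sigma, shape, adjustment, coefs, w)
  if (!is.finite(g0) || g0 <= 0) return(NULL)
  gl <- .gl01()
  nb <- length(edges) - 1L
  lower <- edges[-(nb + 1L)]; width <- diff(edges)
  # quadrature nodes for all bins at once
  xq <- rep(lower, each = length(gl$x)) + rep(width, each = length(gl$x)) * gl$x
  gq <- .g_base(xq, key, sigma, shape, adjustment, coefs, w) / g0
  if (any(!is.finite(gq)) || min(gq) < -1e-9) return(NULL)
  ints <- width * colSums(matrix(gl$w * gq, nrow = length(gl$x)))
  if (any(ints <= 0)) return(NULL)
  ints
}

# multinomial log-likelihood of binned counts under cell probabilities
.binned_loglik <- function(counts, ints) {
  pi <- ints / sum(ints)
  pos <- counts > 0
  sum(counts[pos] * log(pi[pos]))
}

.unpack_par <- function(th, key, m) {
  npk <- .key_npar[[key]]
  sigma <- if (npk >= 1) exp(th[1]) else NULL
  shape <- if (npk >= 2) exp(th[2]) else NULL
  coefs <- if (m > 0) th[npk + seq_len(m)] else numeric(0)
  list(sigma = sigma, shape = shape, coefs = coefs)
}

#' Fit a binned detection function by maximum likelihood
#'
#' Maximises the multinomial log-likelihood of the binned distance counts,
#' with cell probabilities proportional to the integral of the detection
#' function over each distance class. Adjustment terms are added forward
#' (0 up to `max_adj_terms`), refitting at each order, and the AIC-best
#' order is kept. Key scale parameters are optimised on the log scale by
#' bounded quasi-Newton (L-BFGS-B) from five deterministic starts on a
#' log-spaced sigma grid; fit failure is flagged, never an error.
#'
#' @param binned a [bin_distances()] object.
#' @param key detection key: `"uniform"`, `"half_normal"` or
#'   `"hazard_rate"`.
#' @param adjustment series adjustment: `"none"`, `"cosine"`,
#'   `"simple_poly"` or `"hermite"`.
#' @param max_adj_terms maximum number of adjustment terms, default 3.
#' @return An object of class `detection_fit` with elements `key`,
#'   `adjustment`, `n_adj_terms`, `sigma`, `shape`, `adj_coefs`,
#'   `log_likelihood`, `n_params`, `aic`, `esw_m`, `gof` (chi2/df/p),
#'   `monotone_ok`, `converged`, `boundary`, and the data (`binned`).
#' @seealso [fit_detection_set()] for the conventional six-model set,
#'   [select_best_model()], [effective_strip_width()], [gof_chisquare()].
#' @export
fit_detection <- function(binned, key = DETECTION_KEYS,
                          adjustment = ADJUSTMENTS, max_adj_terms = 3) {
  stopifnot(inherits(binned, "binned_distances"))
  key <- match.arg(key)
  adjustment <- match.arg(adjustment)
  if (key == "uniform" && adjustment == "hermite")
    stop("hermite adjustments require a key with a scale parameter")
  counts <- binned$counts
  if (sum(counts) < 1) stop("cannot fit a detection function to zero nests")
  edges <- binned$bin_edges_m
  w <- binned$truncation_w_m
  npk <- .key_npar[[key]]
  m_max <- if (adjustment == "none") 0L else as.integer(max_adj_terms)

  negll <- function(th, m) {
    p <- .unpack_par(th, key, m)
    ints <- .cell_integrals(edges, key, p$sigma, p$shape, adjustment, p$coefs)
    if (is.null(ints)) return(1e10)
    ll <- .binned_loglik(counts, ints)
    if (!is.finite(ll)) return(1e10) else -ll
  }

  bounds <- function(m) {
    lo <- c(log(w / 100), log(0.2))[seq_len(npk)]
    hi <- c(log(20 * w), log(20))[seq_len(npk)]
    list(lower = c(lo, rep(-5, m)), upper = c(hi, rep(5, m)))
  }

  run_optim <- function(start, m) {
    b <- bounds(m)
    tryCatch(
      optim(start, negll, m = m, method = "L-BFGS-B",
            lower = b$lower, upper = b$upper,
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
  }

  sigma_starts <- w * exp(seq(log(0.05), log(1), length.out = 5))
  best_by_m <- vector("list", m_max + 1L)
  for (m in 0:m_max) {
    np <- npk + m
    if (np == 0) {
      ints <- .cell_integrals(edges, key, NULL, NULL, "none", numeric(0))
      best_by_m[[m + 1L]] <- list(par = numeric(0),
                                  value = -.binned_loglik(counts, ints),
                                  convergence = 0L)
      next
    }
    starts <- list()
    if (m == 0 || npk == 0) {
      if (npk > 0) {
        for (s in sigma_starts)
          starts <- c(starts, list(c(log(s), if (npk == 2) log(2),
                                     rep(0, m))))
      } else {
        starts <- list(rep(0, m))
      }
    } else {
      prev <- best_by_m[[m]]
      if (!is.null(prev) && length(prev$par) == np - 1L)
        starts <- c(starts, list(c(prev$par, 0)))
      starts <- c(starts, list(c(log(w / 4), if (npk == 2) log(2),
                                 rep(0, m))))
    }
    res <- NULL
    for (st in starts) {
      r <- run_optim(st, m)
      if (!is.null(r) && (is.null(res) || r$value < res$value)) res <- r
    }
    best_by_m[[m + 1L]] <- res
  }

  # keep the AIC-best adjustment order among successful fits
  aics <- vapply(0:m_max, function(m) {
    r <- best_by_m[[m + 1L]]
    if (is.null(r) || r$value >= 1e9) Inf else 2 * r$value + 2 * (npk + m)
  }, numeric(1))
  if (all(!is.finite(aics))) {
    return(structure(list(key = key, adjustment = adjustment,
      n_adj_terms = NA_integer_, sigma = NA_real_, shape = NA_real_,
      adj_coefs = numeric(0), log_likelihood = NA_real_,
      n_params = NA_integer_, aic = Inf, esw_m = NA_real_,
      gof = list(chi2 = NA_real_, df = NA_integer_, p = NA_real_),
      monotone_ok = FALSE, converged = FALSE, boundary = FALSE,
      binned = binned), class = "detection_fit"))
  }
  m_best <- which.min(aics) - 1L
  res <- best_by_m[[m_best + 1L]]
  p <- .unpack_par(res$par, key, m_best)
  np <- npk + m_best
  ll <- -res$value
  b <- bounds(m_best)
  key_idx <- seq_len(npk)
  boundary <- npk > 0 &&
    (any(abs(res$par[key_idx] - b$lower[key_idx]) < 1e-4 |
         abs(res$par[key_idx] - b$upper[key_idx]) < 1e-4) ||
     sum(counts > 0) == 1L)   # a single occupied bin cannot pin the scale

  adj_used <- if (m_best > 0) adjustment else "none"
  gfun <- function(x) detection_probability(x, key, sigma = p$sigma,
    shape = p$shape, adjustment = adj_used, adj_coefs = p$coefs,
    truncation_w_m = w)
  grid <- gfun(seq(0, w, length.out = 200))
  monotone_ok <- all(diff(grid) <= 1e-6)
  esw <- tryCatch(integrate(gfun, 0, w, rel.tol = 1e-8,
                            subdivisions = 200L)$value,
                  error = function(e) NA_real_)

  fit <- structure(list(key = key, adjustment = adjustment,
    n_adj_terms = m_best, sigma = p$sigma %||% NA_real_,
    shape = p$shape %||% NA_real_, adj_coefs = p$coefs,
    log_likelihood = ll, n_params = np, aic = 2 * (-ll) + 2 * np,
    esw_m = esw, gof = NULL, monotone_ok = monotone_ok,
    converged = res$convergence == 0L, boundary = boundary,
    binned = binned), class = "detection_fit")
  fit$gof <- gof_chisquare(fit)
  fit
}

#' Fit the conventional six-model detection set
#'
#' Fits the six standard key/adjustment pairings used for great-ape nest
#' data: uniform key with cosine or simple polynomial adjustments,
#' half-normal key with cosine or Hermite polynomial adjustments, and
#' hazard-rate key with cosine or simple polynomial adjustments.
#'
#' @inheritParams fit_detection
#' @return A list of class `detection_set` of six [fit_detection()] fits.
#' @export
fit_detection_set <- function(binned, max_adj_terms = 3) {
  spec <- list(c("uniform", "cosine"), c("uniform", "simple_poly"),
               c("half_normal", "cosine"), c("half_normal", "hermite"),
               c("hazard_rate", "cosine"), c("hazard_rate", "simple_poly"))
  fits <- lapply(spec, function(s)
    fit_detection(binned, key = s[1], adjustment = s[2],
                  max_adj_terms = max_adj_terms))
  names(fits) <- vapply(spec, paste, "", collapse = "+")
  structure(fits, class = "detection_set")
}

#' Summarise a set of detection fits as a table
#'
#' @param fits a `detection_set` or list of `detection_fit` objects.
#' @return A data frame with one row per model: key, adjustment, number of
#'   adjustment terms and parameters, log-likelihood, AIC, effective strip
#'   width and goodness-of-fit columns.
#' @export
detection_table <- function(fits) {
  rows <- lapply(fits, function(f) data.frame(
    key = f$key, adjustment = f$adjustment, n_adj_terms = f$n_adj_terms,
    n_params = f$n_params, logLik = f$log_likelihood, aic = f$aic,
    esw_m = f$esw_m, gof_chi2 = f$gof$chi2, gof_df = f$gof$df,
    gof_p = f$gof$p, monotone_ok = f$monotone_ok, converged = f$converged,
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the best detection model by AIC
#'
#' Among converged, monotone non-increasing fits, returns the fit with the
#' smallest AIC. Ties (within 1e-6) are broken by fewest parameters, then
#' by key in the fixed order uniform, half-normal, hazard-rate.
#'
#' @param fits a `detection_set` or list of `detection_fit` objects.
#' @return The selected `detection_fit`, with the full comparison table
#'   attached as attribute `"comparison"`.
#' @export
select_best_model <- function(fits) {
  fits <- unclass(fits)
  valid <- vapply(fits, function(f)
    isTRUE(f$converged) && isTRUE(f$monotone_ok) && is.finite(f$aic),
    logical(1))
  if (!any(valid))
    stop("no converged, monotone detection fit to select from")
  cand <- fits[valid]
  aic <- vapply(cand, `[[`, numeric(1), "aic")
  near <- which(aic - min(aic) < 1e-6)
  if (length(near) > 1) {
    np <- vapply(cand[near], `[[`, numeric(1), "n_params")
    near <- near[np == min(np)]
    if (length(near) > 1) {
      kr <- match(vapply(cand[near], `[[`, "", "key"), DETECTION_KEYS)
      near <- near[order(kr)][1]
    }
  }
  best <- cand[[near[1]]]
  attr(best, "comparison") <- detection_table(fits)
  best
}

#' Effective strip width of a fitted detection function
#'
#' The effective strip width (ESW) is the integral of the fitted g(x) from
#' the line to the truncation distance: the half-width of the strip that,
#' surveyed perfectly, would yield the same expected count. Computed by
#' adaptive quadrature at relative tolerance 1e-8.
#'
#' @param fit a `detection_fit`.
#' @param truncation_w_m upper limit of integration; defaults to the
#'   truncation distance the fit was made with.
#' @return ESW in metres.
#' @export
effective_strip_width <- function(fit, truncation_w_m = NULL) {
  stopifnot(inherits(fit, "detection_fit"))
  w <- truncation_w_m %||% fit$binned$truncation_w_m
  if (is.null(truncation_w_m) && !is.null(fit$esw_m) && is.finite(fit$esw_m))
    return(fit$esw_m)
  integrate(function(x) predict(fit, x), 0, w, rel.tol = 1e-8,
            subdivisions = 200L)$value
}

#' Chi-square goodness of fit for a binned detection fit
#'
#' Compares observed bin counts with those expected under the fitted
#' detection function. Bins with expected count below 0.5 are merged
#' rightward (pooled with following bins) before computing the statistic.
#' Degrees of freedom are the pooled bin count minus one minus the number
#' of estimated parameters, floored at 1.
#'
#' @param fit a `detection_fit`.
#' @param binned optionally, a different [bin_distances()] object to test
#'   against (defaults to the data the model was fitted to).
#' @return A list with `chi2`, `df` and `p`.
#' @export
gof_chisquare <- function(fit, binned = NULL) {
  stopifnot(inherits(fit, "detection_fit"))
  binned <- binned %||% fit$binned
  if (!isTRUE(fit$converged) && is.na(fit$log_likelihood))
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_))
  counts <- binned$counts
  adj_used <- if (fit$n_adj_terms > 0) fit$adjustment else "none"
  ints <- .cell_integrals(binned$bin_edges_m, fit$key,
    if (is.na(fit$sigma)) NULL else fit$sigma,
    if (is.na(fit$shape)) NULL else fit$shape, adj_used, fit$adj_coefs)
  if (is.null(ints))
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_))
  expected <- sum(counts) * ints / sum(ints)
  pooled <- .pool_small(counts, expected, min_expected = 0.5)
  chi2 <- sum((pooled$obs - pooled$exp)^2 / pooled$exp)
  df <- max(1L, length(pooled$obs) - 1L - fit$n_params)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

# pool bins left-to-right until each group's expected count reaches the
# threshold; a short final group is merged into its predecessor
.pool_small <- function(obs, expected, min_expected) {
  go <- numeric(0); ge <- numeric(0)
  co <- 0; ce <- 0
  for (i in seq_along(obs)) {
    co <- co + obs[i]; ce <- ce + expected[i]
    if (ce >= min_expected) {
      go <- c(go, co); ge <- c(ge, ce)
      co <- 0; ce <- 0
    }
  }
  if (ce > 0) {
    if (length(go)) {
      go[length(go)] <- go[length(go)] + co
      ge[length(ge)] <- ge[length(ge)] + ce
    } else {
      go <- co; ge <- ce
    }
  }
  list(obs = go, exp = ge)
}
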