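#' Standardise predictors for effect-size comparison
#'
#' Rescales each numeric predictor to mean 0 and standard deviation 0.5,
#' i.e. `(x - mean) / (2 sd)`, so that coefficients of continuous
#' predictors are comparable in magnitude with those of (centred) binary
#' contrasts. Columns with exactly two distinct values are treated as
#' binary and centred only, not rescaled. The transformation record is
#' kept for back-transformation.
#'
#' @param data data frame of numeric predictor columns (factor contrasts
#'   already expanded to dummies).
#' @return The standardised data frame, with a data frame attribute
#'   `"standardization"` holding `term`, `center`, `scale`, `binary`.
#' @export
standardize_predictors <- function(data) {
  data <- as.data.frame(data)
  if (!all(vapply(data, is.numeric, logical(1))))
    stop("all predictor columns must be numeric (expand factors to dummies first)")
  rec <- data.frame(term = names(data), center = NA_real_, scale = NA_real_,
                    binary = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(data)) {
    x <- data[[i]]
    ux <- unique(x)
    if (length(ux) < 2)
      stop("predictor '", names(data)[i], "' is constant and cannot be standardized")
    if (length(ux) == 2) {            # binary contrast: centre only
      rec$center[i] <- mean(x); rec$scale[i] <- 1; rec$binary[i] <- TRUE
      data[[i]] <- x - mean(x)
    } else {
      rec$center[i] <- mean(x); rec$scale[i] <- 2 * stats::sd(x)
      data[[i]] <- (x - mean(x)) / (2 * stats::sd(x))
    }
  }
  attr(data, "standardization") <- rec
  data
}

# generalised VIF by the determinant formulation on the predictor
# correlation matrix; `term_cols` maps term name -> column indices
.gvif <- function(R, term_cols) {
  detR <- det(R)
  vapply(term_cols, function(idx) {
    if (length(idx) == ncol(R)) return(1)
    det(as.matrix(R[idx, idx])) *
      det(as.matrix(R[-idx, -idx])) / detR
  }, numeric(1))
}

#' Screen predictors for collinearity
#'
#' Flags unordered pairs of numeric predictors whose Pearson correlation
#' reaches `r_threshold` in absolute value, and predictors (terms) whose
#' generalised variance inflation factor in the global design reaches
#' `gvif_threshold`. Factors are handled as column blocks through the
#' determinant formulation of the GVIF. Flagged pairs are barred from
#' co-occurring in any candidate model of [enumerate_models()].
#'
#' @param data data frame of numeric predictor columns.
#' @param r_threshold absolute-correlation threshold, default 0.7
#'   (a pair at exactly the threshold is flagged).
#' @param gvif_threshold GVIF threshold, default 5.
#' @param term_cols optional named list mapping term names to column
#'   indices of `data` (used to treat a dummy block as one term);
#'   defaults to one term per column.
#' @return A list of class `collinearity_screen`: `pairs` (data frame
#'   `var1`, `var2`, `r`), `gvif` (named vector), `flagged_gvif`
#'   (character), `rank_warning` (logical).
#' @export
collinearity_screen <- function(data, r_threshold = 0.7, gvif_threshold = 5,
                                term_cols = NULL) {
  data <- as.data.frame(data)
  if (ncol(data) < 2) stop("need at least 2 predictors to screen")
  if (is.null(term_cols))
    term_cols <- setNames(as.list(seq_len(ncol(data))), names(data))
  X <- as.matrix(data)
  # pairwise correlations between single-column terms
  single <- names(term_cols)[lengths(term_cols) == 1L]
  pairs <- data.frame(var1 = character(), var2 = character(), r = numeric(),
                      stringsAsFactors = FALSE)
  if (length(single) >= 2) {
    cm <- cor(X[, vapply(term_cols[single], function(i) as.integer(i[1]),
                         integer(1)), drop = FALSE])
    for (i in seq_len(length(single) - 1)) for (j in (i + 1):length(single)) {
      if (abs(cm[i, j]) >= r_threshold)
        pairs[nrow(pairs) + 1L, ] <- list(single[i], single[j], cm[i, j])
    }
  }
  rank_warning <- nrow(X) < ncol(X) + 1L
  if (rank_warning)
    warning("fewer rows than predictors in the global model; GVIFs unreliable")
  R <- cor(X)
  gv <- tryCatch(.gvif(R, term_cols), error = function(e)
    setNames(rep(NA_real_, length(term_cols)), names(term_cols)))
  structure(list(pairs = pairs, gvif = gv,
                 flagged_gvif = names(gv)[!is.na(gv) & gv >= gvif_threshold],
                 rank_warning = rank_warning),
            class = "collinearity_screen")
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat("Collinearity screen\n")
  if (nrow(x$pairs)) {
    cat("  excluded pairs (|r| at/above threshold):\n")
    for (i in seq_len(nrow(x$pairs)))
      cat(sprintf("    %s ~ %s (r = %.3f)\n",
                  x$pairs$var1[i], x$pairs$var2[i], x$pairs$r[i]))
  } else cat("  no pairwise exclusions\n")
  cat("  GVIF:", paste(sprintf("%s = %.2f", names(x$gvif), x$gvif),
                       collapse = ", "), "\n")
  if (length(x$flagged_gvif))
    cat("  GVIF-flagged:", paste(x$flagged_gvif, collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate all candidate model subsets
#'
#' All subsets of the predictor terms (a factor's dummy block enters and
#' leaves as one unit), always including the intercept-only (empty)
#' model, minus any subset containing an excluded pair. Order is
#' deterministic: by subset size, then by predictor order.
#'
#' @param predictors character vector of term names.
#' @param exclusions optional 2-column data frame / matrix of term pairs
#'   that may not co-occur.
#' @return List of character vectors (the first is `character(0)`, the
#'   intercept-only model).
#' @export
enumerate_models <- function(predictors, exclusions = NULL) {
  stopifnot(is.character(predictors), !anyDuplicated(predictors))
  excl <- NULL
  if (!is.null(exclusions) && NROW(exclusions) > 0) {
    excl <- as.matrix(exclusions)[, 1:2, drop = FALSE]
    unknown <- setdiff(as.vector(excl), predictors)
    if (length(unknown))
      stop("exclusion pairs reference unknown predictor(s): ",
           paste(unknown, collapse = ", "))
  }
  ok <- function(s) {
    if (is.null(excl)) return(TRUE)
    for (i in seq_len(nrow(excl)))
      if (all(excl[i, ] %in% s)) return(FALSE)
    TRUE
  }
  out <- list(character(0))
  for (size in seq_along(predictors)) {
    cmb <- combn(predictors, size, simplify = FALSE)
    out <- c(out, Filter(ok, cmb))
  }
  out
}

#' Ordinary least squares fit with AICc
#'
#' Gaussian linear model fitted by least squares, with the maximum-
#' likelihood log-likelihood (ML residual variance) and the small-sample
#' corrected AIC. The parameter count `k` includes the intercept and the
#' residual variance.
#'
#' @param response numeric response vector.
#' @param predictors data frame or matrix of predictor columns (may have
#'   zero columns for the intercept-only model).
#' @return An object of class `ols_fit`: coefficients, `vcov`,
#'   `sigma2_ml`, `log_likelihood`, `k`, `aic`, `aicc`, residuals,
#'   fitted values and the design matrix.
#' @export
fit_linear_model <- function(response, predictors = NULL) {
  y <- as.numeric(response)
  n <- length(y)
  Xp <- if (is.null(predictors)) matrix(numeric(0), n, 0)
        else as.matrix(as.data.frame(predictors))
  if (nrow(Xp) != n) stop("predictor rows must match the response length")
  X <- cbind(`(Intercept)` = rep(1, n), Xp)
  p <- ncol(X)
  if (n <= p + 1) stop("too few observations (need n > k)")
  if (qr(X)$rank < p) stop("singular design matrix")
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  rss <- sum(res^2)
  sigma2_ml <- rss / n
  ll <- if (rss <= 0) Inf else -n / 2 * (log(2 * pi) + log(sigma2_ml) + 1)
  k <- p + 1L                       # + residual variance
  aic <- -2 * ll + 2 * k
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  xtx_inv <- solve(crossprod(X))
  vc <- if (n > p) rss / (n - p) * xtx_inv else xtx_inv * NA
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(coefficients = fit$coefficients, vcov = vc,
                 sigma2_ml = sigma2_ml, rss = rss, n = n,
                 df_residual = n - p, log_likelihood = ll, k = k,
                 aic = aic, aicc = aicc, fitted = y - res, residuals = res,
                 design = X, terms = colnames(Xp)),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: %d obs, k = %d (incl. intercept, variance)\n",
              x$n, x$k))
  print(round(x$coefficients, 4))
  cat(sprintf("  logLik = %.3f, AIC = %.3f, AICc = %.3f\n",
              x$log_likelihood, x$aic, x$aicc))
  invisible(x)
}

#' @export
logLik.ols_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
cooks.distance.ols_fit <- function(model, ...) {
  X <- model$design
  h <- rowSums((X %*% solve(crossprod(X))) * X)
  p <- ncol(X)
  s2 <- model$rss / model$df_residual
  if (s2 <= 0) return(rep(0, model$n))
  model$residuals^2 * h / (p * s2 * (1 - h)^2)
}

#' Akaike weights from AICc values
#'
#' `w_m = exp(-delta_m / 2) / sum(exp(-delta / 2))` with deltas relative
#' to the best (smallest) AICc.
#'
#' @param aicc numeric vector of AICc values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aicc) {
  if (!length(aicc)) stop("need at least one model")
  d <- aicc - min(aicc)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Full (zero-substitution) model-averaged coefficients
#'
#' Averages each coefficient over the whole model set with weight
#' `w_m`, substituting zero in models that exclude the predictor — the
#' "full average", which shrinks weakly supported effects towards zero.
#' The unconditional standard error combines within-model variance and
#' between-model spread,
#' `se_j = sqrt( sum_m w_m (var_m(b_j) + (b_jm - bbar_j)^2) )`, and the
#' confidence interval uses the normal quantile. A predictor's relative
#' importance is the summed weight of the models containing it.
#'
#' @param fits list of [fit_linear_model()] objects.
#' @param weights model weights; computed from the fits' AICc values via
#'   [akaike_weights()] when omitted.
#' @param level confidence level, default 0.95.
#' @return Data frame of class `averaged_coefficients`: `term`,
#'   `estimate`, `se`, `ci_lower`, `ci_upper`, `importance`.
#' @export
average_coefficients <- function(fits, weights = NULL, level = 0.95) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "ols_fit")))
  if (is.null(weights))
    weights <- akaike_weights(vapply(fits, `[[`, numeric(1), "aicc"))
  stopifnot(length(weights) == length(fits))
  weights <- weights / sum(weights)
  terms <- unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  z <- qnorm(1 - (1 - level) / 2)
  rows <- lapply(terms, function(tm) {
    est <- vapply(fits, function(f)
      if (tm %in% names(f$coefficients)) unname(f$coefficients[tm]) else 0,
      numeric(1))
    vr <- vapply(fits, function(f)
      if (tm %in% names(f$coefficients)) f$vcov[tm, tm] else 0, numeric(1))
    has <- vapply(fits, function(f) tm %in% names(f$coefficients), logical(1))
    bbar <- sum(weights * est)
    se <- sqrt(sum(weights * (vr + (est - bbar)^2)))
    data.frame(term = tm, estimate = bbar, se = se,
               ci_lower = bbar - z * se, ci_upper = bbar + z * se,
               importance = sum(weights[has]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("averaged_coefficients", "data.frame")
  attr(out, "level") <- level
  out
}

#' @export
print.averaged_coefficients <- function(x, digits = 3, ...) {
  cat(sprintf("Model-averaged coefficients (full average, %g%% CI)\n",
              100 * (attr(x, "level") %||% 0.95)))
  show <- as.data.frame(x)
  for (cl in c("estimate", "se", "ci_lower", "ci_upper", "importance"))
    show[[cl]] <- round(show[[cl]], digits)
  print(show, row.names = FALSE)
  invisible(x)
}

#' All-subsets AICc model averaging of density predictors
#'
#' The covariate-inference workflow in one call: expand habitat into
#' treatment contrasts (logged forest as reference), standardise
#' predictors ([standardize_predictors()]), screen for collinearity
#' ([collinearity_screen()]) and bar flagged pairs from co-occurring,
#' enumerate all remaining subsets including the intercept-only model,
#' fit each by OLS, rank by AICc, and report full model-averaged
#' coefficients with unconditional confidence intervals and relative
#' importances. Influence is checked through Cook's distance on the
#' global model; if any observation exceeds `cooks_threshold` the
#' averaging is repeated without the flagged rows and both coefficient
#' sets are reported.
#'
#' @param response numeric response per transect (density or encounter
#'   rate).
#' @param data data frame holding the predictor columns (and optionally
#'   `habitat`).
#' @param predictors character vector of numeric predictor column names;
#'   defaults to the canonical covariate columns present in `data`.
#' @param habitat optional habitat vector (defaults to `data$habitat`
#'   when present); enters and leaves candidate models as one block.
#' @param r_threshold,gvif_threshold collinearity thresholds (0.7, 5).
#' @param cooks_threshold Cook's distance flag level, default 1.
#' @param level confidence level for the averaged intervals.
#' @return An object of class `model_avg`: `coefficients` (the
#'   [average_coefficients()] table), `models` (selection table with k,
#'   AICc, delta, weight), `fits`, `screen`, `exclusions`, `cooks`
#'   (distances and flagged rows), `without_outliers` (second coefficient
#'   table, or `NULL`), `n`.
#' @export
model_average <- function(response, data, predictors = NULL, habitat = NULL,
                          r_threshold = 0.7, gvif_threshold = 5,
                          cooks_threshold = 1, level = 0.95) {
  data <- as.data.frame(data)
  y <- as.numeric(response)
  if (length(y) != nrow(data)) stop("response length must match data rows")
  predictors <- predictors %||% intersect(COVARIATE_COLUMNS, names(data))
  if (!length(predictors) && is.null(habitat) && !"habitat" %in% names(data))
    stop("no predictors to model")
  habitat <- habitat %||% data[["habitat"]]

  Xdf <- data[, predictors, drop = FALSE]
  term_cols <- setNames(as.list(seq_along(predictors)), predictors)
  if (!is.null(habitat)) {
    h <- factor(as.character(habitat),
                levels = intersect(HABITAT_LEVELS, unique(as.character(habitat))))
    if (nlevels(h) > 1) {
      mm <- stats::model.matrix(~h)[, -1, drop = FALSE]
      colnames(mm) <- paste0("habitat_", sub("^h", "", colnames(mm)))
      first <- ncol(Xdf) + 1L
      Xdf <- cbind(Xdf, as.data.frame(mm))
      term_cols$habitat <- seq(first, ncol(Xdf))
    }
  }
  if (anyNA(Xdf) || anyNA(y)) stop("missing values in response or predictors")

  Xstd <- standardize_predictors(Xdf)
  screen <- if (ncol(Xstd) >= 2)
    collinearity_screen(Xstd, r_threshold, gvif_threshold, term_cols)
  else list(pairs = data.frame(var1 = character(), var2 = character(),
                               r = numeric()), gvif = NULL,
            flagged_gvif = character(0))
  exclusions <- screen$pairs[, c("var1", "var2"), drop = FALSE]

  terms <- names(term_cols)
  subsets <- enumerate_models(terms, exclusions)
  fits <- lapply(subsets, function(s) {
    cols <- unlist(term_cols[s], use.names = FALSE)
    fit_linear_model(y, Xstd[, cols, drop = FALSE])
  })
  aicc <- vapply(fits, `[[`, numeric(1), "aicc")
  weights <- akaike_weights(aicc)
  coefs <- average_coefficients(fits, weights, level = level)

  models <- data.frame(
    model = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = " + ") else "(intercept only)", ""),
    n_terms = lengths(subsets),
    k = vapply(fits, `[[`, numeric(1), "k"),
    aicc = aicc, delta = aicc - min(aicc), weight = weights,
    stringsAsFactors = FALSE)
  models <- models[order(models$aicc), ]
  rownames(models) <- NULL

  global_cols <- unlist(term_cols, use.names = FALSE)
  global <- tryCatch(fit_linear_model(y, Xstd[, global_cols, drop = FALSE]),
                     error = function(e) NULL)
  cooks <- if (!is.null(global)) cooks.distance.ols_fit(global)
           else rep(NA_real_, length(y))
  flagged <- which(is.finite(cooks) & cooks > cooks_threshold)

  without_outliers <- NULL
  if (length(flagged) && length(flagged) < length(y) - length(global_cols) - 2) {
    keep <- setdiff(seq_along(y), flagged)
    redo <- model_average(y[keep], data[keep, , drop = FALSE],
                          predictors = predictors,
                          habitat = if (!is.null(habitat)) habitat[keep],
                          r_threshold = r_threshold,
                          gvif_threshold = gvif_threshold,
                          cooks_threshold = Inf, level = level)
    without_outliers <- redo$coefficients
  }

  structure(list(coefficients = coefs, models = models, fits = fits,
                 subsets = subsets, weights = weights, screen = screen,
                 exclusions = exclusions,
                 cooks = list(distances = cooks, flagged = flagged,
                              threshold = cooks_threshold),
                 without_outliers = without_outliers,
                 n = length(y), terms = terms, level = level),
            class = "model_avg")
}

#' @export
print.model_avg <- function(x, n_models = 5, ...) {
  cat(sprintf("All-subsets AICc model averaging: %d models on %d transects\n",
              nrow(x$models), x$n))
  if (nrow(x$exclusions))
    cat("  collinearity exclusions:",
        paste(paste(x$exclusions$var1, x$exclusions$var2, sep = " ~ "),
              collapse = "; "), "\n")
  cat("Top models:\n")
  show <- utils::head(x$models, n_models)
  show$aicc <- round(show$aicc, 2); show$delta <- round(show$delta, 2)
  show$weight <- round(show$weight, 3)
  print(show, row.names = FALSE)
  print(x$coefficients)
  if (length(x$cooks$flagged))
    cat(sprintf("Influence: %d row(s) with Cook's D > %g (re-averaged without them; see $without_outliers)\n",
                length(x$cooks$flagged), x$cooks$threshold))
  invisible(x)
}

#' @export
summary.model_avg <- function(object, ...) {
  print(object, n_models = 10, ...)
}

#' @export
coef.model_avg <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.model_avg <- function(object, parm, level, ...) {
  ci <- as.matrix(object$coefficients[, c("ci_lower", "ci_upper")])
  rownames(ci) <- object$coefficients$term
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
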