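#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf("Detection function: %s key, %s adjustments (%d term%s)\n",
              x$key, x$adjustment, x$n_adj_terms,
              if (isTRUE(x$n_adj_terms == 1)) "" else "s"))
  if (!is.na(x$sigma)) cat(sprintf("  sigma = %.3f m", x$sigma))
  if (!is.na(x$shape)) cat(sprintf(", shape b = %.3f", x$shape))
  if (!is.na(x$sigma)) cat("\n")
  if (length(x$adj_coefs))
    cat("  adjustment coefficients:",
        paste(sprintf("%.4f", x$adj_coefs), collapse = ", "), "\n")
  cat(sprintf("  logLik = %.3f on %d parameter(s), AIC = %.3f\n",
              x$log_likelihood, x$n_params, x$aic))
  cat(sprintf("  effective strip width = %.2f m (w = %g m)\n",
              x$esw_m, x$binned$truncation_w_m))
  if (!is.null(x$gof) && is.finite(x$gof$chi2))
    cat(sprintf("  GOF: chi2 = %.3f, df = %d, p = %.3f\n",
                x$gof$chi2, x$gof$df, x$gof$p))
  if (!isTRUE(x$converged)) cat("  WARNING: fit did not converge\n")
  if (isTRUE(x$boundary)) cat("  WARNING: parameter at bound (degenerate fit)\n")
  if (!isTRUE(x$monotone_ok)) cat("  WARNING: fitted g(x) is not monotone\n")
  invisible(x)
}

#' @export
coef.detection_fit <- function(object, ...) {
  out <- c(if (!is.na(object$sigma)) c(sigma = object$sigma),
           if (!is.na(object$shape)) c(shape = object$shape))
  if (length(object$adj_coefs))
    out <- c(out, setNames(object$adj_coefs,
                           paste0("a", seq_along(object$adj_coefs))))
  out
}

#' @export
logLik.detection_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_params,
            nobs = sum(object$binned$counts), class = "logLik")
}

#' Evaluate the fitted detection function
#'
#' @param object a `detection_fit`.
#' @param x_m perpendicular distances (m) at which to evaluate g(x);
#'   defaults to a 101-point grid over `[0, w]`.
#' @param ... unused.
#' @return Detection probabilities g(x).
#' @export
predict.detection_fit <- function(object, x_m = NULL, ...) {
  w <- object$binned$truncation_w_m
  x_m <- x_m %||% seq(0, w, length.out = 101)
  adj_used <- if (object$n_adj_terms > 0) object$adjustment else "none"
  detection_probability(x_m, object$key,
    sigma = if (is.na(object$sigma)) NULL else object$sigma,
    shape = if (is.na(object$shape)) NULL else object$shape,
    adjustment = adj_used, adj_coefs = object$adj_coefs,
    truncation_w_m = w)
}

#' Plot a fitted detection function over the distance histogram
#'
#' Draws the binned distance data rescaled to the detection scale
#' (so a perfectly uniform histogram under g = 1 has unit height) with
#' the fitted g(x) overlaid.
#'
#' @param x a `detection_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.detection_fit <- function(x, ...) {
  b <- x$binned
  w <- b$truncation_w_m
  widths <- diff(b$bin_edges_m)
  # rescale bar heights so that area matches the fitted ESW
  dens <- b$counts / (sum(b$counts) * widths)
  bars <- dens * x$esw_m
  xs <- seq(0, w, length.out = 200)
  plot(NA, xlim = c(0, w), ylim = c(0, max(1, bars) * 1.05),
       xlab = "Perpendicular distance (m)", ylab = "Detection probability",
       main = sprintf("%s key, %s adjustment", x$key, x$adjustment), ...)
  for (i in seq_along(bars)) {
    graphics::rect(b$bin_edges_m[i], 0, b$bin_edges_m[i + 1], bars[i],
                   col = "grey85", border = "grey40")
  }
  lines(xs, predict(x, xs), lwd = 2)
  invisible(x)
}

#' @export
print.detection_set <- function(x, ...) {
  cat("Detection model set (", length(x), " models)\n", sep = "")
  print(detection_table(x), digits = 4)
  invisible(x)
}
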