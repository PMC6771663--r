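#' Nest-to-ape conversion parameters
#'
#' The three parameters dividing nest density down to orang-utan density:
#' the proportion of nest-building individuals in the population `p`, the
#' nest production rate `r` (nests per individual per day) and the mean
#' nest decay time `t` (days). Standing-crop surveys count every nest once,
#' so the expected number of nests standing per individual is `p * r * t`.
#'
#' Defaults are literature values commonly applied to Bornean orang-utans:
#' a conservative builder proportion of 0.85, one nest per individual per
#' day, and a decay time of 259 days.
#'
#' @param p proportion of nest builders, in (0, 1].
#' @param r nest production rate, nests/individual/day, > 0.
#' @param t nest decay time in days, > 0.
#' @return An object of class `nest_params`.
#' @examples
#' nest_params()            # p = 0.85, r = 1, t = 259
#' nest_params(0.9, 1.1, 300)
#' @export
nest_params <- function(p = 0.85, r = 1.00, t = 259) {
  stopifnot(length(p) == 1, length(r) == 1, length(t) == 1)
  if (!is.finite(p) || p <= 0 || p > 1)
    stop("'p' must lie in (0, 1], got ", p)
  if (!is.finite(r) || r <= 0) stop("'r' must be > 0, got ", r)
  if (!is.finite(t) || t <= 0) stop("'t' must be > 0, got ", t)
  structure(list(p = p, r = r, t = t), class = "nest_params")
}

#' @export
print.nest_params <- function(x, ...) {
  cat(sprintf(
    "Nest conversion parameters: p = %.3g, r = %.3g nests/ind/day, t = %.4g days\n",
    x$p, x$r, x$t))
  cat(sprintf("  nests standing per individual (p*r*t): %.4g\n",
              x$p * x$r * x$t))
  invisible(x)
}

as_nest_params <- function(x) {
  if (inherits(x, "nest_params")) return(x)
  if (is.list(x) || (is.numeric(x) && !is.null(names(x))))
    return(nest_params(x[["p"]], x[["r"]], x[["t"]]))
  if (is.numeric(x) && length(x) == 3)
    return(nest_params(x[1], x[2], x[3]))
  stop("cannot interpret 'params' as nest parameters (p, r, t)")
}
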