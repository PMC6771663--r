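#' Nest encounter rate
#'
#' Nests recorded per kilometre of transect walked.
#'
#' @param n_nests nest count (>= 0).
#' @param length_km transect length in km (> 0).
#' @return Encounter rate in nests/km.
#' @examples
#' encounter_rate(31, 1.8)   # 17.22
#' @export
encounter_rate <- function(n_nests, length_km) {
  if (any(!is.finite(length_km)) || any(length_km <= 0))
    stop("'length_km' must be finite and > 0")
  if (any(!is.finite(n_nests)) || any(n_nests < 0))
    stop("'n_nests' must be finite and >= 0")
  n_nests / length_km
}

#' Nest density from a strip of effective width
#'
#' Converts a transect nest count to nests per square kilometre,
#' `D_nest = N / (L * 2w)`, where the strip half-width `w` is the
#' effective strip width of the detection function in metres (converted
#' to km internally).
#'
#' @param n_nests nest count.
#' @param length_km transect length (km).
#' @param esw_m effective strip width (m), > 0.
#' @return Nest density in nests/km^2.
#' @examples
#' nest_density(31, 1.8, 15.5)   # 555.56
#' @export
nest_density <- function(n_nests, length_km, esw_m) {
  if (any(!is.finite(esw_m)) || any(esw_m <= 0))
    stop("'esw_m' must be finite and > 0")
  if (any(!is.finite(length_km)) || any(length_km <= 0))
    stop("'length_km' must be finite and > 0")
  n_nests / (length_km * 2 * esw_m / 1000)
}

#' Orang-utan density from nest density
#'
#' Divides standing-crop nest density by the expected number of standing
#' nests per individual, `D_orang = D_nest / (p * r * t)`.
#'
#' @param nest_density nest density in nests/km^2.
#' @param params a [nest_params()] object (or coercible list/vector).
#' @return Orang-utan density in individuals/km^2.
#' @examples
#' orangutan_density(555.56, nest_params(0.85, 1, 259))   # 2.52
#' @export
orangutan_density <- function(nest_density, params = nest_params()) {
  params <- as_nest_params(params)
  nest_density / (params$p * params$r * params$t)
}

#' Per-transect density estimates
#'
#' Computes encounter rate, nest density and orang-utan density for every
#' transect. Each transect uses the effective strip width of its habitat
#' (detection functions are fitted to habitat-pooled distances), and all
#' quantities are kept at full precision; rounding happens only in print
#' methods and written reports.
#'
#' Nest counts are taken from the observation table when present (counting
#' observations within the truncation distance), otherwise from an
#' `n_nests` column on the transect table (counts assumed already
#' truncated, as in published per-transect summaries).
#'
#' @param data a [survey_data] object, or a transect data frame with
#'   columns `id`, `habitat`, `length_km`, `n_nests`.
#' @param esw named vector of effective strip widths (m) by habitat, e.g.
#'   `c(logged_forest = 15.5, ...)`; may also be a list of
#'   `detection_fit` objects by habitat, or `NULL` to use an `esw_m`
#'   column on the transect table.
#' @param params a [nest_params()] object.
#' @param truncation_w_m truncation distance used when counting
#'   observation-level nests, default 40 m.
#' @return A data frame of class `density_estimates` with one row per
#'   transect: `transect_id`, `habitat`, `n_nests`, `length_km`, `esw_m`,
#'   `encounter_rate` (nests/km), `nest_density` (nests/km^2),
#'   `ape_density` (ind/km^2). The conversion parameters are attached as
#'   attribute `"params"`.
#' @export
estimate_density <- function(data, esw = NULL, params = nest_params(),
                             truncation_w_m = 40) {
  params <- as_nest_params(params)
  if (inherits(data, "survey_data")) {
    tr <- data$transects
    if (!is.null(data$observations)) {
      obs <- data$observations
      kept <- obs[obs$perp_distance_m < truncation_w_m, , drop = FALSE]
      n <- table(factor(kept$transect_id, levels = tr$id))
      tr$n_nests <- as.integer(n[tr$id])
    } else if (!"n_nests" %in% names(tr)) {
      stop("no observations and no 'n_nests' column to estimate from")
    }
  } else {
    tr <- as.data.frame(data)
    need <- c("id", "habitat", "length_km", "n_nests")
    miss <- setdiff(need, names(tr))
    if (length(miss))
      stop("transect table is missing column(s): ", paste(miss, collapse = ", "))
  }

  if (is.null(esw)) {
    if (!"esw_m" %in% names(tr))
      stop("no 'esw' argument and no 'esw_m' column on the transect table")
    esw_m <- tr$esw_m
  } else {
    if (is.list(esw))
      esw <- vapply(esw, function(f)
        if (inherits(f, "detection_fit")) f$esw_m else as.numeric(f),
        numeric(1))
    miss <- setdiff(unique(tr$habitat), names(esw))
    if (length(miss))
      stop("no effective strip width supplied for habitat(s): ",
           paste(miss, collapse = ", "))
    esw_m <- unname(esw[tr$habitat])
  }

  out <- data.frame(
    transect_id = tr$id,
    habitat = tr$habitat,
    n_nests = tr$n_nests,
    length_km = tr$length_km,
    esw_m = esw_m,
    encounter_rate = encounter_rate(tr$n_nests, tr$length_km),
    nest_density = nest_density(tr$n_nests, tr$length_km, esw_m),
    stringsAsFactors = FALSE)
  out$ape_density <- orangutan_density(out$nest_density, params)
  attr(out, "params") <- params
  class(out) <- c("density_estimates", "data.frame")
  out
}

#' @export
print.density_estimates <- function(x, digits = 1, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "Per-transect density estimates (p = %.2f, r = %.2f, t = %g)\n",
    p$p, p$r, p$t))
  show <- data.frame(
    transect = x$transect_id, habitat = x$habitat, nests = x$n_nests,
    km = x$length_km, esw_m = x$esw_m,
    nests_per_km = round(x$encounter_rate, digits),
    ind_per_km2 = round(x$ape_density, digits))
  print(show, row.names = FALSE)
  invisible(x)
}

#' Habitat-level density summaries
#'
#' Mean, spread and range of per-transect orang-utan densities for each
#' habitat, plus a landscape-wide row computed as the unweighted mean over
#' all transects. The standard deviation is the sample (n - 1) value and
#' is reported as `NA` for single-transect habitats.
#'
#' @param estimates a [estimate_density()] result.
#' @return A data frame of class `habitat_summary`: `habitat`,
#'   `n_transects`, `mean`, `sd`, `se`, `min`, `max` (ind/km^2), with the
#'   landscape row labelled `"landscape"`.
#' @export
habitat_summary <- function(estimates) {
  stopifnot(inherits(estimates, "density_estimates"))
  one <- function(label, v) data.frame(
    habitat = label, n_transects = length(v), mean = mean(v),
    sd = if (length(v) > 1) stats::sd(v) else NA_real_,
    se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
    min = min(v), max = max(v), stringsAsFactors = FALSE)
  habs <- intersect(HABITAT_LEVELS, unique(estimates$habitat))
  rows <- lapply(habs, function(h)
    one(h, estimates$ape_density[estimates$habitat == h]))
  rows <- c(rows, list(one("landscape", estimates$ape_density)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("habitat_summary", "data.frame")
  out
}

#' @export
print.habitat_summary <- function(x, digits = 2, ...) {
  cat("Orang-utan density by habitat (ind/km^2)\n")
  show <- x
  for (cl in c("mean", "sd", "se", "min", "max"))
    show[[cl]] <- round(show[[cl]], digits)
  print(as.data.frame(show), row.names = FALSE)
  invisible(x)
}
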