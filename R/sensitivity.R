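#' Factorial grid over the conversion parameters
#'
#' Builds the full 3 x 3 x 3 factorial over low/medium/high values of the
#' builder proportion `p`, production rate `r` and decay time `t` used to
#' probe how strongly the density estimates depend on literature-derived
#' parameters. Defaults are the published Bornean ranges: t in
#' {202, 259, 602} days, r in {0.84, 1.00, 1.16}, p in {0.82, 0.85, 0.88}.
#'
#' @param p,r,t increasing numeric triples (low, medium, high).
#' @return A data frame of class `parameter_grid` with 27 rows in
#'   deterministic order (p slowest, then r, then t) and columns
#'   `p`, `r`, `t`; the level triples are kept as attribute `"levels"`.
#' @export
parameter_grid <- function(p = c(0.82, 0.85, 0.88),
                           r = c(0.84, 1.00, 1.16),
                           t = c(202, 259, 602)) {
  for (nm in c("p", "r", "t")) {
    v <- get(nm)
    if (length(v) != 3 || any(!is.finite(v)) || is.unsorted(v, strictly = TRUE))
      stop("'", nm, "' must be a strictly increasing (low, medium, high) triple")
  }
  g <- expand.grid(t = t, r = r, p = p, KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("p", "r", "t")]
  rownames(g) <- NULL
  structure(g, levels = list(p = p, r = r, t = t),
            class = c("parameter_grid", "data.frame"))
}

#' Fixed-parameter subsets of the sensitivity grid
#'
#' Splits the factorial grid into the three 9-combination subsets in
#' which one parameter is held at its medium value while the other two
#' range over all levels, isolating each parameter's influence.
#'
#' @param grid a [parameter_grid()].
#' @return Named list `t_fixed`, `r_fixed`, `p_fixed` of 9-row data
#'   frames.
#' @export
fixed_parameter_subsets <- function(grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  lv <- attr(grid, "levels")
  list(t_fixed = grid[grid$t == lv$t[2], , drop = FALSE],
       r_fixed = grid[grid$r == lv$r[2], , drop = FALSE],
       p_fixed = grid[grid$p == lv$p[2], , drop = FALSE])
}

#' Recompute densities over a parameter grid
#'
#' Converts each transect's full-precision nest density to orang-utan
#' density under every parameter combination in `grid`, producing the
#' long table behind a sensitivity analysis.
#'
#' @param estimates a [estimate_density()] result (its `nest_density`
#'   column is reused at full precision).
#' @param grid a [parameter_grid()], one of its
#'   [fixed_parameter_subsets()], or any data frame with columns
#'   `p`, `r`, `t`.
#' @return A data frame of class `sensitivity_table`: `p`, `r`, `t`,
#'   `transect_id`, `habitat`, `ape_density`, one row per transect per
#'   parameter combination.
#' @export
sensitivity_densities <- function(estimates, grid) {
  stopifnot(inherits(estimates, "density_estimates"))
  grid <- as.data.frame(grid)
  stopifnot(all(c("p", "r", "t") %in% names(grid)))
  if (nrow(estimates) == 0 || nrow(grid) == 0) {
    out <- data.frame(p = numeric(), r = numeric(), t = numeric(),
                      transect_id = character(), habitat = character(),
                      ape_density = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("sensitivity_table", "data.frame")
    return(out)
  }
  combos <- lapply(seq_len(nrow(grid)), function(i) {
    ps <- nest_params(grid$p[i], grid$r[i], grid$t[i])
    data.frame(p = ps$p, r = ps$r, t = ps$t,
               transect_id = estimates$transect_id,
               habitat = estimates$habitat,
               ape_density = orangutan_density(estimates$nest_density, ps),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, combos)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' Density ranges per habitat under fixed-parameter subsets
#'
#' Summarises a sensitivity analysis as the minimum and maximum
#' transect-level density reached within each habitat when one parameter
#' is fixed at its medium value and the other two vary (ranges are taken
#' over transects x parameter combinations, not over habitat means).
#'
#' @param estimates a [estimate_density()] result.
#' @param grid a [parameter_grid()].
#' @return A data frame with columns `subset`, `habitat`, `min`, `max`
#'   (ind/km^2), including a `"landscape"` row per subset.
#' @export
sensitivity_summary <- function(estimates, grid = parameter_grid()) {
  subs <- fixed_parameter_subsets(grid)
  rows <- lapply(names(subs), function(lab) {
    sens <- sensitivity_densities(estimates, subs[[lab]])
    habs <- intersect(HABITAT_LEVELS, unique(sens$habitat))
    per <- lapply(habs, function(h) {
      v <- sens$ape_density[sens$habitat == h]
      data.frame(subset = lab, habitat = h, min = min(v), max = max(v),
                 stringsAsFactors = FALSE)
    })
    per <- c(per, list(data.frame(subset = lab, habitat = "landscape",
                                  min = min(sens$ape_density),
                                  max = max(sens$ape_density),
                                  stringsAsFactors = FALSE)))
    do.call(rbind, per)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binned sensitivity histograms
#'
#' Counts sensitivity-table densities into fixed-width bins per
#' fixed-parameter subset (and habitat), the tabular analogue of the
#' histogram panels usually drawn for this analysis.
#'
#' @param estimates a [estimate_density()] result.
#' @param grid a [parameter_grid()].
#' @param bin_width histogram bin width in ind/km^2, default 0.25.
#' @return A data frame with `subset`, `habitat`, `bin_lower`,
#'   `bin_upper`, `count`.
#' @export
sensitivity_histogram <- function(estimates, grid = parameter_grid(),
                                  bin_width = 0.25) {
  stopifnot(bin_width > 0)
  subs <- fixed_parameter_subsets(grid)
  rows <- list()
  for (lab in names(subs)) {
    sens <- sensitivity_densities(estimates, subs[[lab]])
    for (h in intersect(HABITAT_LEVELS, unique(sens$habitat))) {
      v <- sens$ape_density[sens$habitat == h]
      top <- ceiling(max(v) / bin_width)
      idx <- pmin(top, floor(v / bin_width) + 1L)  # [lower, upper)
      cnt <- tabulate(idx, nbins = top)
      rows[[length(rows) + 1L]] <- data.frame(
        subset = lab, habitat = h,
        bin_lower = (seq_len(top) - 1) * bin_width,
        bin_upper = seq_len(top) * bin_width,
        count = cnt, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
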