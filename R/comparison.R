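.check_groups <- function(values, groups, min_per_group = 2, min_groups = 2) {
  if (length(values) != length(groups))
    stop("'values' and 'groups' must have equal length")
  g <- factor(groups)
  g <- droplevels(g)
  sizes <- table(g)
  if (length(sizes) < min_groups)
    stop("need at least ", min_groups, " groups")
  if (any(sizes < min_per_group))
    stop("every group needs at least ", min_per_group, " values; too few in: ",
         paste(names(sizes)[sizes < min_per_group], collapse = ", "))
  g
}

.nest_test <- function(test, statistic, df, p_value, groups = NULL,
                       details = NULL) {
  structure(list(test = test, statistic = unname(statistic), df = df,
                 p_value = unname(p_value), groups = groups,
                 details = details),
            class = "nest_test")
}

#' @export
print.nest_test <- function(x, ...) {
  dfs <- if (length(x$df) == 2)
    sprintf("df = (%g, %g)", x$df[1], x$df[2]) else sprintf("df = %g", x$df)
  cat(sprintf("%s: statistic = %.4f, %s, p = %.4g\n",
              x$test, x$statistic, dfs, x$p_value))
  if (!is.null(x$details)) print(x$details, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA across habitats
#'
#' Classical fixed-effects one-way analysis of variance,
#' F = MS_between / MS_within on (k - 1, n - k) degrees of freedom, for
#' comparing transect-level densities or encounter rates among habitats.
#'
#' @param values numeric response (e.g. ind/km^2 per transect).
#' @param groups habitat labels, same length as `values`; each group
#'   needs at least two values.
#' @return A `nest_test` with the F statistic, df pair and p-value.
#' @export
oneway_anova <- function(values, groups) {
  g <- .check_groups(values, groups)
  ht <- oneway.test(values ~ g, var.equal = TRUE)
  .nest_test("One-way ANOVA (F)", ht$statistic,
             unname(c(ht$parameter[1], ht$parameter[2])), ht$p.value,
             groups = levels(g))
}

#' Tukey HSD pairwise habitat comparisons
#'
#' Studentised-range pairwise mean comparisons using the within-group
#' mean square from the one-way ANOVA, with family-wise adjusted
#' p-values.
#'
#' @inheritParams oneway_anova
#' @return A `nest_test` whose `details` data frame has one row per pair:
#'   `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  g <- .check_groups(values, groups)
  fit <- aov(values ~ g)
  tk <- TukeyHSD(fit)$g
  det <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(det) <- NULL
  .nest_test("Tukey HSD", NA_real_, NA_real_, min(det$p_adj),
             groups = levels(g), details = det)
}

#' Shapiro-Wilk normality test
#'
#' @param values numeric vector, n >= 3.
#' @return A `nest_test` with the W statistic and p-value. Used as a
#'   report-only gate: the pipeline proceeds regardless of the outcome.
#' @export
normality_test <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("Shapiro-Wilk test needs at least 3 values")
  ht <- shapiro.test(values)
  .nest_test("Shapiro-Wilk normality (W)", ht$statistic, NA_real_, ht$p.value)
}

#' Bartlett test of variance homogeneity
#'
#' @inheritParams oneway_anova
#' @return A `nest_test` with the K statistic, df and p-value
#'   (report-only, as for [normality_test()]).
#' @export
variance_homogeneity_test <- function(values, groups) {
  g <- .check_groups(values, groups)
  ht <- bartlett.test(values, g)
  .nest_test("Bartlett variance homogeneity (K)", ht$statistic,
             unname(ht$parameter), ht$p.value, groups = levels(g))
}

#' Homogeneity of binned distance distributions across habitats
#'
#' Chi-square test of homogeneity on the habitat x distance-class
#' contingency table. All habitats must share the same bin edges; distance
#' classes are merged rightward (each sparse column pooled with the next)
#' until every expected count is at least 1. Detection functions may only
#' be pooled across habitats when this test shows no difference.
#'
#' @param binned_by_habitat named list of [bin_distances()] objects, one
#'   per habitat (>= 2).
#' @return A `nest_test` with the X^2 statistic,
#'   df = (habitats - 1) * (pooled bins - 1), and p-value; the pooled
#'   contingency table is attached as `details`.
#' @export
distance_distribution_homogeneity <- function(binned_by_habitat) {
  if (!is.list(binned_by_habitat) || length(binned_by_habitat) < 2)
    stop("need binned distances for at least 2 habitats")
  stopifnot(all(vapply(binned_by_habitat, inherits, logical(1),
                       "binned_distances")))
  edges <- binned_by_habitat[[1]]$bin_edges_m
  same <- vapply(binned_by_habitat, function(b)
    length(b$bin_edges_m) == length(edges) &&
      all(b$bin_edges_m == edges), logical(1))
  if (!all(same)) stop("all habitats must share the same bin edges")
  tab <- do.call(rbind, lapply(binned_by_habitat, `[[`, "counts"))
  tab <- .merge_columns_rightward(tab, min_expected = 1)
  if (ncol(tab) < 2)
    stop("too few occupied distance classes for a homogeneity test")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  .nest_test("Distance-distribution homogeneity (X2)", ht$statistic,
             unname(ht$parameter), ht$p.value,
             groups = names(binned_by_habitat), details = as.data.frame(tab))
}

# pool contingency-table columns left-to-right until every column's
# expected counts are all >= the threshold
.merge_columns_rightward <- function(tab, min_expected = 1) {
  repeat {
    if (ncol(tab) <= 1) return(tab)
    n <- sum(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / n
    bad <- which(apply(expected, 2, min) < min_expected)
    if (!length(bad)) return(tab)
    j <- bad[1]
    k <- if (j < ncol(tab)) j + 1L else j - 1L
    tab[, k] <- tab[, k] + tab[, j]
    tab <- tab[, -j, drop = FALSE]
  }
}
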