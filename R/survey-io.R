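#' Assemble a validated survey dataset
#'
#' Bundles a transect table, an optional nest-observation table and an
#' optional covariate table into a single validated object used by all
#' estimation functions. Referential integrity (every observation and
#' covariate row pointing at an existing transect) and field invariants
#' (positive lengths, non-negative distances, known habitat and decay
#' labels, unique transect ids) are enforced here, so downstream code can
#' assume a clean dataset.
#'
#' @param transects data frame with columns `id`, `habitat`
#'   (one of `"logged_forest"`, `"salvage_logged"`, `"oil_palm_remnant"`)
#'   and `length_km` (> 0). Extra columns (e.g. `n_nests`, `esw_m` for
#'   count-level data) are carried through untouched.
#' @param observations optional data frame with columns `transect_id`,
#'   `perp_distance_m` (>= 0) and `decay_class` (`"A"`–`"E"`).
#' @param covariates optional data frame with column `transect_id` plus
#'   the per-transect predictors; at most one row per transect.
#' @return An object of class `survey_data`: a list with elements
#'   `transects`, `observations`, `covariates`.
#' @seealso [read_survey()] to build one from delimited files,
#'   [validate_survey()] for soft design checks.
#' @export
survey_data <- function(transects, observations = NULL, covariates = NULL) {
  transects <- as.data.frame(transects)
  need <- c("id", "habitat", "length_km")
  miss <- setdiff(need, names(transects))
  if (length(miss))
    stop("transect table is missing column(s): ", paste(miss, collapse = ", "))
  transects$id <- as.character(transects$id)
  transects$habitat <- as.character(transects$habitat)
  bad_hab <- setdiff(unique(transects$habitat), HABITAT_LEVELS)
  if (length(bad_hab))
    stop("unknown habitat label(s): ", paste(bad_hab, collapse = ", "),
         " (expected ", paste(HABITAT_LEVELS, collapse = ", "), ")")
  if (anyDuplicated(transects$id))
    stop("duplicate transect id(s): ",
         paste(unique(transects$id[duplicated(transects$id)]), collapse = ", "))
  if (!is.numeric(transects$length_km) || any(!is.finite(transects$length_km)) ||
      any(transects$length_km <= 0))
    stop("'length_km' must be finite and > 0 for every transect")

  if (!is.null(observations)) {
    observations <- as.data.frame(observations)
    need <- c("transect_id", "perp_distance_m", "decay_class")
    miss <- setdiff(need, names(observations))
    if (length(miss))
      stop("nest table is missing column(s): ", paste(miss, collapse = ", "))
    observations$transect_id <- as.character(observations$transect_id)
    observations$decay_class <- as.character(observations$decay_class)
    if (!is.numeric(observations$perp_distance_m) ||
        any(!is.finite(observations$perp_distance_m)) ||
        any(observations$perp_distance_m < 0))
      stop("'perp_distance_m' must be finite and >= 0 for every nest")
    bad_cls <- setdiff(unique(observations$decay_class), DECAY_CLASSES)
    if (length(bad_cls))
      stop("unknown decay class(es): ", paste(bad_cls, collapse = ", "))
    orphans <- setdiff(unique(observations$transect_id), transects$id)
    if (length(orphans))
      stop("nest rows reference unknown transect id(s): ",
           paste(orphans, collapse = ", "))
  }

  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (!"transect_id" %in% names(covariates))
      stop("covariate table is missing column(s): transect_id")
    covariates$transect_id <- as.character(covariates$transect_id)
    orphans <- setdiff(unique(covariates$transect_id), transects$id)
    if (length(orphans))
      stop("covariate rows reference unknown transect id(s): ",
           paste(orphans, collapse = ", "))
    if (anyDuplicated(covariates$transect_id))
      stop("more than one covariate row for transect(s): ",
           paste(unique(covariates$transect_id[duplicated(covariates$transect_id)]),
                 collapse = ", "))
  }

  structure(list(transects = transects, observations = observations,
                 covariates = covariates),
            class = "survey_data")
}

COVARIATE_COLUMNS <- c("canopy_height_mean_m", "canopy_height_sd_m",
                       "n_layers", "shannon_pai", "forest_cover_pct",
                       "dist_to_forest_m")

#' Read survey tables from delimited files
#'
#' Reads the transect, nest and (optionally) covariate tables and returns
#' a validated [survey_data] object. Columns are matched by header name,
#' case-insensitively and in any order, so hand-built field sheets do not
#' need a fixed layout.
#'
#' @param transect_path path to the transect file
#'   (columns `id`, `habitat`, `length_km`).
#' @param nest_path optional path to the nest file (columns `transect_id`,
#'   `perp_distance_m`, `decay_class`).
#' @param covariate_path optional path to the covariate file
#'   (`transect_id` plus the predictor columns).
#' @param sep field separator, default `","`.
#' @return A [survey_data] object.
#' @export
read_survey <- function(transect_path, nest_path = NULL,
                        covariate_path = NULL, sep = ",") {
  read_one <- function(path, required, label) {
    if (!file.exists(path)) stop(label, " file not found: ", path)
    df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
    names(df) <- tolower(trimws(names(df)))
    miss <- setdiff(required, names(df))
    if (length(miss))
      stop(label, " file is missing column(s): ", paste(miss, collapse = ", "))
    df
  }
  tr <- read_one(transect_path, c("id", "habitat", "length_km"), "transect")
  obs <- if (!is.null(nest_path))
    read_one(nest_path, c("transect_id", "perp_distance_m", "decay_class"),
             "nest")
  cov <- if (!is.null(covariate_path))
    read_one(covariate_path, c("transect_id", COVARIATE_COLUMNS), "covariate")
  survey_data(tr, obs, cov)
}

#' @export
print.survey_data <- function(x, ...) {
  cat("Nest survey dataset\n")
  cat(sprintf("  transects:    %d (%.1f km total effort)\n",
              nrow(x$transects), sum(x$transects$length_km)))
  by_hab <- table(factor(x$transects$habitat, levels = HABITAT_LEVELS))
  cat("  habitats:     ",
      paste(sprintf("%s (%d)", names(by_hab), by_hab), collapse = ", "), "\n")
  if (!is.null(x$observations))
    cat(sprintf("  observations: %d nests\n", nrow(x$observations)))
  else if ("n_nests" %in% names(x$transects))
    cat(sprintf("  nest counts:  %d nests (count-level data)\n",
                sum(x$transects$n_nests)))
  if (!is.null(x$covariates))
    cat(sprintf("  covariates:   %d transects\n", nrow(x$covariates)))
  invisible(x)
}

#' Soft design checks for a survey dataset
#'
#' Reports survey-design warnings without rejecting the data: distance
#' sampling of great-ape nests is commonly held to need at least 60
#' observations per stratum for a stable detection function, and at least
#' 3 km of transect per stratum for density work in low-density habitat.
#' Violations are reported, never enforced, and the dataset is not
#' altered: estimates computed with or without warnings are identical.
#'
#' @param data a [survey_data] object.
#' @param min_nests minimum nests per habitat before a warning, default 60.
#' @param min_effort_km minimum summed transect length per habitat before
#'   a warning, default 3.
#' @return A data frame of class `survey_validation` with columns
#'   `habitat`, `check`, `value`, `threshold`, `message` (zero rows when
#'   the design meets both rules).
#' @export
validate_survey <- function(data, min_nests = 60, min_effort_km = 3) {
  stopifnot(inherits(data, "survey_data"))
  tr <- data$transects
  habs <- unique(tr$habitat)
  nests <- if (!is.null(data$observations)) {
    tab <- table(factor(data$observations$transect_id, levels = tr$id))
    tapply(as.numeric(tab), tr$habitat, sum)
  } else if ("n_nests" %in% names(tr)) {
    tapply(tr$n_nests, tr$habitat, sum)
  } else {
    setNames(rep(NA_real_, length(habs)), habs)
  }
  effort <- tapply(tr$length_km, tr$habitat, sum)

  out <- data.frame(habitat = character(), check = character(),
                    value = numeric(), threshold = numeric(),
                    message = character(), stringsAsFactors = FALSE)
  for (h in habs) {
    if (!is.na(nests[[h]]) && nests[[h]] < min_nests)
      out[nrow(out) + 1L, ] <- list(h, "n_nests", as.numeric(nests[[h]]),
        min_nests,
        sprintf("habitat '%s' has %d nest observations, below the %d-nest minimum for reliable detection fitting",
                h, as.integer(nests[[h]]), as.integer(min_nests)))
    if (effort[[h]] < min_effort_km)
      out[nrow(out) + 1L, ] <- list(h, "effort_km", as.numeric(effort[[h]]),
        min_effort_km,
        sprintf("habitat '%s' has %.2f km of transect, below the %.1f km minimum effort",
                h, effort[[h]], min_effort_km))
  }
  class(out) <- c("survey_validation", "data.frame")
  out
}

#' @export
print.survey_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("Survey design checks: no warnings\n")
  } else {
    cat("Survey design warnings:\n")
    for (m in x$message) cat("  - ", m, "\n", sep = "")
  }
  invisible(x)
}

#' Write result tables and a run summary
#'
#' Writes each table as a CSV file (one per name) and a machine-readable
#' JSON run summary beside them. Output is deterministic: re-running with
#' identical inputs produces byte-identical files.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory, created if needed.
#' @param summary list of run metadata (configuration echo, seed, ...);
#'   package and R versions are added automatically.
#' @return Invisibly, the character vector of files written.
#' @export
write_results <- function(tables, out_dir, summary = list()) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    ok <- tryCatch({
      write.csv(as.data.frame(tables[[nm]]), p, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(p)) stop("failed to write table to ", p)
    paths <- c(paths, p)
  }
  summary$package <- as.character(packageVersion("nestdensity"))
  summary$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  summary$tables <- names(tables)
  sp <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(paths, sp))
}
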