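# habitat-specific covariate generator settings: mean by habitat and a
# common sd, loosely calibrated to a logged-forest / oil-palm mosaic
.cov_truth <- list(
  canopy_height_mean_m = list(mean = c(logged_forest = 22, salvage_logged = 14,
                                       oil_palm_remnant = 10), sd = 3),
  canopy_height_sd_m   = list(mean = c(logged_forest = 6.5, salvage_logged = 6.0,
                                       oil_palm_remnant = 5.0), sd = 1.5),
  n_layers             = list(mean = c(logged_forest = 5, salvage_logged = 4,
                                       oil_palm_remnant = 3), sd = 0.8),
  shannon_pai          = list(mean = c(logged_forest = 1.8, salvage_logged = 1.5,
                                       oil_palm_remnant = 1.2), sd = 0.25),
  forest_cover_pct     = list(mean = c(logged_forest = 95, salvage_logged = 70,
                                       oil_palm_remnant = 35), sd = 8),
  dist_to_forest_m     = list(mean = c(logged_forest = 400, salvage_logged = 1500,
                                       oil_palm_remnant = 3500), sd = 400))

#' Configuration for the survey simulator
#'
#' Collects the ground truth for a synthetic nest survey: habitat
#' densities, conversion parameters, detection functions, transect plan
#' and covariate effects. Defaults mimic the study system the package is
#' built around: three habitat strata at 2.32, 2.35 and 0.82 ind/km^2,
#' half-normal detection with scale 12.4 m (effective strip width near
#' 15.5 m at 40 m truncation), nests simulated out to 60 m so that the
#' 40 m truncation step discards real observations, and 30 transects of
#' 1.6 km per habitat.
#'
#' @param habitat_truth named vector of true orang-utan densities
#'   (ind/km^2) per habitat.
#' @param params true conversion parameters, a [nest_params()].
#' @param detection_truth named list per habitat:
#'   `list(key =, sigma =, shape =)`.
#' @param sim_half_width_m half-width of the simulated nest strip (m),
#'   must be at least 40.
#' @param transect_plan data frame with columns `habitat`, `length_km`;
#'   default 30 transects of 1.6 km per habitat.
#' @param covariate_effects named vector of linear effects of the
#'   (raw-scale, habitat-centred) covariates on density; default a
#'   positive effect of canopy-height variation only.
#' @param noise_sd sd of transect-level Gaussian density noise
#'   (ind/km^2) used by [simulate_covariates()].
#' @param seed default random seed carried with the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(habitat_truth = c(logged_forest = 2.32,
                                         salvage_logged = 2.35,
                                         oil_palm_remnant = 0.82),
                       params = nest_params(),
                       detection_truth = NULL,
                       sim_half_width_m = 60,
                       transect_plan = NULL,
                       covariate_effects = c(canopy_height_sd_m = 0.3),
                       noise_sd = 0.5,
                       seed = 1L) {
  params <- as_nest_params(params)
  if (any(!is.finite(habitat_truth)) || any(habitat_truth < 0))
    stop("'habitat_truth' densities must be finite and >= 0")
  bad <- setdiff(names(habitat_truth), HABITAT_LEVELS)
  if (length(bad)) stop("unknown habitat(s) in 'habitat_truth': ",
                        paste(bad, collapse = ", "))
  if (!is.finite(sim_half_width_m) || sim_half_width_m < 40)
    stop("'sim_half_width_m' must be >= 40 (the truncation distance)")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (is.null(detection_truth))
    detection_truth <- setNames(rep(list(list(key = "half_normal",
                                              sigma = 12.4, shape = NULL)),
                                    length(habitat_truth)),
                                names(habitat_truth))
  miss <- setdiff(names(habitat_truth), names(detection_truth))
  if (length(miss)) stop("no detection truth for habitat(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(transect_plan))
    transect_plan <- data.frame(
      habitat = rep(names(habitat_truth), each = 30),
      length_km = 1.6, stringsAsFactors = FALSE)
  transect_plan <- as.data.frame(transect_plan)
  stopifnot(all(c("habitat", "length_km") %in% names(transect_plan)))
  if (any(transect_plan$length_km <= 0))
    stop("transect lengths must be > 0")
  bad <- setdiff(unique(transect_plan$habitat), names(habitat_truth))
  if (length(bad)) stop("transect plan uses habitat(s) without truth: ",
                        paste(bad, collapse = ", "))
  unknown_eff <- setdiff(names(covariate_effects), COVARIATE_COLUMNS)
  if (length(unknown_eff)) stop("unknown covariate effect(s): ",
                                paste(unknown_eff, collapse = ", "))
  structure(list(habitat_truth = habitat_truth, params = params,
                 detection_truth = detection_truth,
                 sim_half_width_m = sim_half_width_m,
                 transect_plan = transect_plan,
                 covariate_effects = covariate_effects,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Expected nests standing in a surveyed strip
#'
#' Inverts the density chain: an area of density `D` ind/km^2 holds
#' `D * p * r * t` standing nests per km^2, so a strip of length `L` km
#' and half-width `w_m` metres is expected to hold
#' `D * p * r * t * L * 2 * (w_m / 1000)` nests (before detection).
#'
#' @param density_ind_km2 true density (ind/km^2), >= 0.
#' @param params a [nest_params()].
#' @param length_km transect length (km), > 0.
#' @param half_width_m strip half-width (m), > 0.
#' @return Expected nest count (dimensionless).
#' @examples
#' expected_nest_count(2, nest_params(0.85, 1, 259), 1.5, 50)  # 66.045
#' @export
expected_nest_count <- function(density_ind_km2, params, length_km,
                                half_width_m) {
  params <- as_nest_params(params)
  if (any(!is.finite(density_ind_km2)) || any(density_ind_km2 < 0))
    stop("'density_ind_km2' must be finite and >= 0")
  if (any(length_km <= 0) || any(half_width_m <= 0))
    stop("'length_km' and 'half_width_m' must be > 0")
  density_ind_km2 * params$p * params$r * params$t *
    length_km * 2 * (half_width_m / 1000)
}

.g_truth <- function(x, det) {
  detection_probability(x, det$key, sigma = det$sigma, shape = det$shape,
                        truncation_w_m = Inf)
}

# decay-class age thresholds as fractions of the decay time t
DECAY_AGE_QUANTILES <- c(0.1, 0.3, 0.6, 0.85)

#' Simulate a nest survey with known truth
#'
#' Generates a [survey_data] object from a [sim_config()]: per transect
#' the standing nest count is Poisson with mean [expected_nest_count()],
#' perpendicular distances are uniform across the simulated strip
#' (uniform nest availability), each nest is retained with probability
#' g(distance) under the habitat's true detection function, and a decay
#' class is assigned by drawing a nest age uniform on (0, t) and cutting
#' at fixed age quantiles (0.1, 0.3, 0.6, 0.85). Identical
#' (config, seed) pairs give identical datasets.
#'
#' @param config a [sim_config()].
#' @param seed random seed; defaults to the seed stored in `config`.
#' @return A list with `data` (a [survey_data]) and `truth`: per-transect
#'   expected and realised nest counts before detection, the true
#'   effective strip widths at 40 m truncation, and the config.
#' @export
simulate_survey <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  plan <- config$transect_plan
  hw <- config$sim_half_width_m
  ids <- sprintf("%s_%03d", c(logged_forest = "LF", salvage_logged = "SL",
                              oil_palm_remnant = "OP")[plan$habitat],
                 stats::ave(seq_len(nrow(plan)), plan$habitat,
                            FUN = seq_along))
  expected <- expected_nest_count(config$habitat_truth[plan$habitat],
                                  config$params, plan$length_km, hw)
  obs <- vector("list", nrow(plan))
  realized <- integer(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    n <- rpois(1, expected[i])
    realized[i] <- n
    if (n == 0) next
    x <- runif(n, 0, hw)
    det <- config$detection_truth[[plan$habitat[i]]]
    keep <- runif(n) < .g_truth(x, det)
    if (!any(keep)) next
    age <- runif(sum(keep), 0, config$params$t)
    cls <- DECAY_CLASSES[findInterval(age / config$params$t,
                                      DECAY_AGE_QUANTILES) + 1L]
    obs[[i]] <- data.frame(transect_id = ids[i],
                           perp_distance_m = x[keep],
                           decay_class = cls, stringsAsFactors = FALSE)
  }
  observations <- do.call(rbind, obs[!vapply(obs, is.null, logical(1))])
  if (is.null(observations))
    observations <- data.frame(transect_id = character(),
                               perp_distance_m = numeric(),
                               decay_class = character(),
                               stringsAsFactors = FALSE)
  transects <- data.frame(id = ids, habitat = plan$habitat,
                          length_km = plan$length_km,
                          stringsAsFactors = FALSE)
  true_esw <- vapply(config$detection_truth, function(det)
    integrate(function(x) .g_truth(x, det), 0, 40, rel.tol = 1e-8)$value,
    numeric(1))
  list(data = survey_data(transects, observations),
       truth = list(transect_id = ids, habitat = plan$habitat,
                    expected_counts = unname(expected),
                    realized_counts = realized,
                    true_esw_m = true_esw, seed = seed, config = config))
}

#' Simulate per-transect covariates with linked densities
#'
#' Draws the forest-structure and landscape covariates from
#' habitat-specific normal distributions and generates a realised
#' transect density as `habitat intercept + sum(effects * centred
#' covariates) + Gaussian noise`, floored at zero. The habitat intercepts
#' are the configured true densities; covariates are centred on their
#' cross-habitat mean inside the linear predictor so that zero effects
#' leave habitat means untouched.
#'
#' @inheritParams simulate_survey
#' @return A list with `covariates` (a per-transect covariate data frame
#'   including `transect_id` and `habitat`), `density` (realised
#'   densities, the simulation response) and `truth` (linear predictor
#'   and effects used).
#' @export
simulate_covariates <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed + 1L)   # decoupled from the survey stream
  plan <- config$transect_plan
  n <- nrow(plan)
  ids <- sprintf("%s_%03d", c(logged_forest = "LF", salvage_logged = "SL",
                              oil_palm_remnant = "OP")[plan$habitat],
                 stats::ave(seq_len(n), plan$habitat, FUN = seq_along))
  cov <- data.frame(transect_id = ids, habitat = plan$habitat,
                    stringsAsFactors = FALSE)
  for (nm in names(.cov_truth)) {
    tr <- .cov_truth[[nm]]
    x <- rnorm(n, tr$mean[plan$habitat], tr$sd)
    if (nm == "forest_cover_pct") x <- pmin(100, pmax(0, x))
    if (nm %in% c("dist_to_forest_m", "canopy_height_sd_m", "n_layers",
                  "shannon_pai")) x <- pmax(0, x)
    cov[[nm]] <- x
  }
  lp <- unname(config$habitat_truth[plan$habitat])
  for (nm in names(config$covariate_effects)) {
    centre <- mean(.cov_truth[[nm]]$mean)
    lp <- lp + config$covariate_effects[[nm]] * (cov[[nm]] - centre)
  }
  density <- pmax(0, lp + rnorm(n, 0, config$noise_sd))
  list(covariates = cov, density = density,
       truth = list(linear_predictor = lp,
                    effects = config$covariate_effects,
                    noise_sd = config$noise_sd, seed = seed))
}
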