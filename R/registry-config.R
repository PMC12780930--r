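#' Configuration for the synthetic transplant registry generator
#'
#' Builds and validates the parameter set that [generate_registry()] consumes.
#' Defaults describe the stated study world: a national cohort of roughly
#' 2020 adolescent liver transplants over 2002--2024, about 30% of them from
#' age-mismatched donors, with acuity-driven confounding of graft acceptance
#' and a late-emerging exposure effect on the graft hazard. All distributional
#' choices are synthetic stand-ins for a restricted-access registry; none is
#' an estimate from real data.
#'
#' @param n_adolescent_tx Number of adolescent-recipient transplants.
#' @param n_adult_tx Number of adult-recipient transplants of adolescent
#'   donor grafts (the exogenous supply stream for reallocation).
#' @param date_window Length-2 `Date` vector, first and last transplant date.
#' @param frac_mismatched_target Target marginal fraction of age-mismatched
#'   transplants in `[0, 1]`; the assignment intercept is calibrated to it.
#' @param confounding_strength Log-odds increment of mismatched-graft
#'   acceptance per standard-deviation of the latent acuity score.
#' @param exposure_log_hr_early Log hazard ratio of exposure on years (0, 1].
#' @param exposure_log_hr_late Log hazard ratio of exposure on years (5, 10].
#'   The exposure effect on (1, 5] is fixed at zero.
#' @param acuity_log_hr Log hazard ratio per standard deviation of the latent
#'   acuity score (makes acuity a true confounder, not just an imbalance).
#' @param baseline_hazard Piecewise-constant baseline graft-failure rates per
#'   year; recycled to 10 annual pieces, last rate extends beyond 10 years.
#' @param censor_rate Per-year rate of loss to follow-up (0 disables).
#' @param admin_censor_date Administrative censoring date.
#' @param n_hospitals Number of hospitals (transplant centers are drawn from
#'   them with skewed volume weights).
#' @param geography Named numeric bounding box `lat_min`, `lat_max`,
#'   `lon_min`, `lon_max` in degrees.
#' @param frac_split Fraction of split-or-reduced grafts.
#' @param frac_dcd,frac_living,frac_multiorgan Fractions of circulatory-death
#'   donors, living donors and multiorgan transplants in the adolescent
#'   stream (all excluded downstream; nonzero defaults exercise the filters).
#' @param seed Integer seed; the whole registry is reproducible from it.
#' @return A validated list of class `"registry_config"`.
#' @seealso [generate_registry()], [read_registry_config()]
#' @examples
#' cfg <- registry_config(n_adolescent_tx = 200, n_adult_tx = 100, seed = 7)
#' cfg$frac_mismatched_target
#' @export
registry_config <- function(n_adolescent_tx = 2020L,
                            n_adult_tx = 5401L,
                            date_window = as.Date(c("2002-03-01", "2024-12-31")),
                            frac_mismatched_target = 0.303,
                            confounding_strength = 1.0,
                            exposure_log_hr_early = 0,
                            exposure_log_hr_late = log(1.67),
                            acuity_log_hr = log(1.3),
                            baseline_hazard = c(0.08, rep(0.025, 9)),
                            censor_rate = 0.02,
                            admin_censor_date = as.Date("2025-04-04"),
                            n_hospitals = 103L,
                            geography = c(lat_min = 25, lat_max = 49,
                                          lon_min = -124, lon_max = -67),
                            frac_split = 0.075,
                            frac_dcd = 0.03,
                            frac_living = 0.02,
                            frac_multiorgan = 0.02,
                            seed = 1L) {
  cfg <- list(
    n_adolescent_tx = as.integer(n_adolescent_tx),
    n_adult_tx = as.integer(n_adult_tx),
    date_window = as.Date(date_window),
    frac_mismatched_target = frac_mismatched_target,
    confounding_strength = confounding_strength,
    exposure_log_hr_early = exposure_log_hr_early,
    exposure_log_hr_late = exposure_log_hr_late,
    acuity_log_hr = acuity_log_hr,
    baseline_hazard = baseline_hazard,
    censor_rate = censor_rate,
    admin_censor_date = as.Date(admin_censor_date),
    n_hospitals = as.integer(n_hospitals),
    geography = geography,
    frac_split = frac_split,
    frac_dcd = frac_dcd,
    frac_living = frac_living,
    frac_multiorgan = frac_multiorgan,
    seed = as.integer(seed)
  )
  class(cfg) <- "registry_config"
  validate_registry_config(cfg)
  cfg
}

#' Validate a registry configuration
#'
#' Checks every invariant of the configuration and signals a classed
#' condition (`adolgraft_config_error`) naming the offending field.
#'
#' @param config A `"registry_config"` list.
#' @return `config`, invisibly, if valid.
#' @export
validate_registry_config <- function(config) {
  if (!inherits(config, "registry_config")) {
    abort("`config` must be created by `registry_config()`",
          class = "adolgraft_config_error")
  }
  for (f in c("n_adolescent_tx", "n_adult_tx", "n_hospitals")) {
    if (!is.numeric(config[[f]]) || length(config[[f]]) != 1L ||
        is.na(config[[f]]) || config[[f]] < 1) {
      config_abort(f, "must be a positive count")
    }
  }
  p <- config$frac_mismatched_target
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    config_abort("frac_mismatched_target", "must be a proportion in [0, 1]")
  }
  for (f in c("frac_split", "frac_dcd", "frac_living", "frac_multiorgan")) {
    v <- config[[f]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) {
      config_abort(f, "must be a proportion in [0, 1]")
    }
  }
  if (!is.numeric(config$censor_rate) || config$censor_rate < 0) {
    config_abort("censor_rate", "must be a non-negative rate")
  }
  if (!is.numeric(config$baseline_hazard) || length(config$baseline_hazard) < 1 ||
      any(!is.finite(config$baseline_hazard)) || any(config$baseline_hazard < 0) ||
      all(config$baseline_hazard == 0)) {
    config_abort("baseline_hazard", "must be non-negative rates, not all zero")
  }
  for (f in c("confounding_strength", "exposure_log_hr_early",
              "exposure_log_hr_late", "acuity_log_hr")) {
    if (!is.numeric(config[[f]]) || length(config[[f]]) != 1L ||
        !is.finite(config[[f]])) {
      config_abort(f, "must be a finite number")
    }
  }
  if (!inherits(config$date_window, "Date") || length(config$date_window) != 2L ||
      anyNA(config$date_window)) {
    config_abort("date_window", "must be two non-missing Dates")
  }
  stopifnot_scalar_date(config$admin_censor_date, "admin_censor_date")
  if (!(config$date_window[1] < config$date_window[2])) {
    config_abort("date_window", "start must precede end")
  }
  if (config$date_window[2] > config$admin_censor_date) {
    config_abort("admin_censor_date", "must be on or after date_window end")
  }
  g <- config$geography
  need <- c("lat_min", "lat_max", "lon_min", "lon_max")
  if (!is.numeric(g) || !all(need %in% names(g))) {
    config_abort("geography", "must name lat_min, lat_max, lon_min, lon_max")
  }
  if (g["lat_min"] < -90 || g["lat_max"] > 90 || g["lat_min"] >= g["lat_max"] ||
      g["lon_min"] < -180 || g["lon_max"] > 180 || g["lon_min"] >= g["lon_max"]) {
    config_abort("geography", "bounding box must lie in valid lat/lon ranges")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1L || is.na(config$seed)) {
    config_abort("seed", "must be a single integer")
  }
  invisible(config)
}

#' Read a registry configuration from a JSON file
#'
#' Key-value JSON with the same field names as [registry_config()]; missing
#' keys take the defaults, unknown keys are an error.
#'
#' @param path Path to a JSON file.
#' @return A validated `"registry_config"`.
#' @export
read_registry_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(registry_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    config_abort(bad[1], "unknown configuration field")
  }
  for (f in intersect(c("date_window", "admin_censor_date"), names(raw))) {
    raw[[f]] <- as.Date(raw[[f]])
  }
  if ("geography" %in% names(raw)) raw$geography <- unlist(raw$geography)
  do.call(registry_config, raw)
}
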