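# Synthetic registry generator.
#
# Every quantity here is a synthetic stand-in chosen to reproduce the
# *structure* the downstream analysis assumes (confounded exposure, a
# late-emerging exposure effect, right censoring, hospital geography), not
# the marginal distributions of any real registry extract.

# --- piecewise-exponential sampling ----------------------------------------

# Draw event times from subject-specific piecewise-constant hazards.
# rate_mat: n x K matrix of rates; pieces start at `starts` (last piece
# extends to infinity). Standard inversion of the cumulative hazard.
sample_pwexp <- function(rate_mat, starts) {
  n <- nrow(rate_mat)
  K <- ncol(rate_mat)
  widths <- diff(starts)
  cumH <- matrix(0, n, K)
  for (k in 2:K) {
    cumH[, k] <- cumH[, k - 1] + rate_mat[, k - 1] * widths[k - 1]
  }
  e <- rexp(n)
  piece <- rowSums(cumH <= e)
  idx <- cbind(seq_len(n), piece)
  starts[piece] + (e - cumH[idx]) / rate_mat[idx]
}

# per-subject annual graft-failure rates out to 30 years
graft_rate_matrix <- function(config, n, lp, exposed) {
  base <- rep_len(config$baseline_hazard, 10)
  starts <- c(0:10)                      # pieces [0,1), ..., [9,10), [10,Inf)
  rates <- c(base, base[10])             # last rate extends past the horizon
  rate_mat <- matrix(rates, n, 11, byrow = TRUE) * exp(lp)
  # exposure acts on (0,1] and (5,10]; no effect on (1,5] or beyond 10 y
  emult <- matrix(1, n, 11)
  emult[exposed, 1] <- exp(config$exposure_log_hr_early)
  emult[exposed, 6:10] <- exp(config$exposure_log_hr_late)
  list(rates = rate_mat * emult, starts = starts)
}

# --- component generators ---------------------------------------------------

gen_hospitals <- function(config) {
  g <- config$geography
  n <- config$n_hospitals
  tibble::tibble(
    hospital_id = sprintf("H%03d", seq_len(n)),
    latitude = runif(n, g[["lat_min"]], g[["lat_max"]]),
    longitude = runif(n, g[["lon_min"]], g[["lon_max"]])
  )
}

sample_dates <- function(n, window) {
  window[1] + sample.int(as.integer(window[2] - window[1]) + 1L, n,
                         replace = TRUE) - 1L
}

# adolescent heights/weights (also used for adolescent donors)
adolescent_body <- function(n, sex) {
  male <- sex == "M"
  height <- ifelse(male, rnorm(n, 166, 9), rnorm(n, 160, 7))
  height <- clip(height, 130, 195)
  bmi <- clip(rnorm(n, 21.5, 3.5), 14, 40)
  weight <- clip(bmi * (height / 100)^2, 30, 130)
  list(height = round(height, 1), weight = round(weight, 1))
}

adult_body <- function(n, sex) {
  male <- sex == "M"
  height <- clip(ifelse(male, rnorm(n, 176, 7), rnorm(n, 163, 7)), 140, 205)
  bmi <- clip(rnorm(n, 26, 4.5), 16, 45)
  weight <- clip(bmi * (height / 100)^2, 40, 160)
  list(height = round(height, 1), weight = round(weight, 1))
}

# calibrate the assignment intercept so the marginal mismatched fraction
# hits the configured target given the realized acuity scores
calibrate_alpha <- function(z, slope, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  f <- function(a) mean(plogis(a + slope * z)) - target
  uniroot(f, c(-30, 30), tol = 1e-10)$root
}

# observed follow-up from latent event time + censoring; returns dates
resolve_followup <- function(tx_date, t_event, config) {
  n <- length(t_event)
  c_loss <- if (config$censor_rate > 0) rexp(n, config$censor_rate) else rep(Inf, n)
  admin_years <- as.numeric(config$admin_censor_date - tx_date) / 365.25
  obs <- pmin(t_event, c_loss, admin_years)
  event <- t_event <= pmin(c_loss, admin_years)
  end_date <- tx_date + round(obs * 365.25)
  # among graft events: ~65% are deaths, the rest retransplants
  death <- event & (runif(n) < 0.65)
  retx <- event & !death
  tibble::tibble(
    graft_loss_date = dplyr::if_else(retx, end_date, as.Date(NA)),
    death_date = dplyr::if_else(death, end_date, as.Date(NA)),
    last_followup_date = end_date
  )
}

gen_adolescent_stream <- function(config, hospitals) {
  n <- config$n_adolescent_tx
  tx_date <- sample_dates(n, config$date_window)
  recipient_age <- sample(12:17, n, replace = TRUE)
  recipient_sex <- ifelse(runif(n) < 0.535, "F", "M")
  body <- adolescent_body(n, recipient_sex)

  # single latent acuity score drives admission, status 1, MELD, diagnosis
  # and (through confounding_strength) mismatched-graft acceptance
  z <- rnorm(n)
  admission <- dplyr::case_when(
    z > qnorm(1 - 0.266) ~ "ICU",
    z > qnorm(1 - 0.266 - 0.136) ~ "hospital",
    TRUE ~ "home"
  )
  status1 <- runif(n) < plogis(-1.1 + 1.4 * z)
  meld <- as.integer(clip(round(18 + 6.5 * z + rnorm(n, 0, 3)), 6, 40))
  is_alf <- runif(n) < plogis(-2.1 + 0.9 * z)
  other_dx <- sample(c("biliary_atresia", "metabolic", "other_cholestatic",
                       "other_noncholestatic"),
                     n, replace = TRUE,
                     prob = c(0.11, 0.15, 0.17, 0.57))
  diagnosis <- ifelse(is_alf, "acute_liver_failure", other_dx)

  alpha <- calibrate_alpha(z, config$confounding_strength,
                           config$frac_mismatched_target)
  exposed <- runif(n) < plogis(alpha + config$confounding_strength * z)

  # donors: mismatched donors are adults (gap >= 10 y), matched donors peers
  gap_mm <- 10L + pmin(as.integer(round(rexp(n, 1 / 11))), 50L)
  gap_ok <- as.integer(clip(round(rnorm(n, 1, 3)), -12, 9))
  donor_age <- ifelse(exposed, recipient_age + gap_mm,
                      pmax(recipient_age + gap_ok, 0L))
  donor_sex <- ifelse(runif(n) < ifelse(exposed, 0.52, 0.40), "F", "M")
  donor_adult <- donor_age >= 18
  b_adult <- adult_body(n, donor_sex)
  b_adol <- adolescent_body(n, donor_sex)
  donor_height <- ifelse(donor_adult, b_adult$height, b_adol$height)
  donor_weight <- ifelse(donor_adult, b_adult$weight, b_adol$weight)

  donor_type <- sample(c("DBD", "DCD", "living"), n, replace = TRUE,
                       prob = c(1 - config$frac_dcd - config$frac_living,
                                config$frac_dcd, config$frac_living))
  graft_type <- ifelse(runif(n) < config$frac_split, "split_or_reduced", "whole")
  multiorgan <- runif(n) < config$frac_multiorgan
  prior_transplant <- runif(n) < 0.11
  cit_hours <- round(clip(rlnorm(n, log(6.6), 0.35), 1, 24), 1)
  waiting_days <- as.integer(round(clip(rlnorm(n, log(60) - 0.6 * z, 1.2), 0, 3000)))

  # transplant centers have skewed volumes; recipients present at the center
  center_w <- exp(rnorm(config$n_hospitals, 0, 1))
  center <- sample(hospitals$hospital_id, n, replace = TRUE, prob = center_w)
  donor_hospital <- sample(hospitals$hospital_id, n, replace = TRUE)

  rm <- graft_rate_matrix(config, n, config$acuity_log_hr * z, exposed)
  t_event <- sample_pwexp(rm$rates, rm$starts)
  fup <- resolve_followup(tx_date, t_event, config)

  tibble::tibble(
    tx_id = sprintf("T%06d", seq_len(n)),
    tx_date = tx_date,
    donor_id = sprintf("D%06d", seq_len(n)),
    recipient_id = sprintf("R%06d", seq_len(n)),
    donor_age = as.integer(donor_age),
    donor_sex = donor_sex,
    donor_height = donor_height,
    donor_weight = donor_weight,
    donor_type = donor_type,
    donor_hospital = donor_hospital,
    recipient_age = as.integer(recipient_age),
    recipient_sex = recipient_sex,
    recipient_height = body$height,
    recipient_weight = body$weight,
    recipient_category = "adolescent",
    diagnosis = diagnosis,
    meld = meld,
    status1 = status1,
    admission = admission,
    prior_transplant = prior_transplant,
    multiorgan = multiorgan,
    graft_type = graft_type,
    cit_hours = cit_hours,
    center_id = center,
    recipient_hospital = center,
    waiting_days = waiting_days,
    fup
  )
}

gen_adult_stream <- function(config, hospitals) {
  n <- config$n_adult_tx
  tx_date <- sample_dates(n, config$date_window)
  recipient_age <- sample(18:70, n, replace = TRUE)
  recipient_sex <- ifelse(runif(n) < 0.4, "F", "M")
  body <- adult_body(n, recipient_sex)
  donor_age <- sample(12:17, n, replace = TRUE)         # adolescent donors
  donor_sex <- ifelse(runif(n) < 0.45, "F", "M")
  dbody <- adolescent_body(n, donor_sex)
  donor_type <- ifelse(runif(n) < config$frac_dcd, "DCD", "DBD")
  graft_type <- ifelse(runif(n) < config$frac_split, "split_or_reduced", "whole")
  meld <- as.integer(clip(round(rnorm(n, 21, 8)), 6, 40))
  admission <- sample(c("ICU", "hospital", "home"), n, replace = TRUE,
                      prob = c(0.2, 0.15, 0.65))
  t_event <- rexp(n, 0.04)
  fup <- resolve_followup(tx_date, t_event, config)

  tibble::tibble(
    tx_id = sprintf("A%06d", seq_len(n)),
    tx_date = tx_date,
    donor_id = sprintf("AD%05d", seq_len(n)),
    recipient_id = sprintf("AR%05d", seq_len(n)),
    donor_age = as.integer(donor_age),
    donor_sex = donor_sex,
    donor_height = dbody$height,
    donor_weight = dbody$weight,
    donor_type = donor_type,
    donor_hospital = sample(hospitals$hospital_id, n, replace = TRUE),
    recipient_age = as.integer(recipient_age),
    recipient_sex = recipient_sex,
    recipient_height = body$height,
    recipient_weight = body$weight,
    recipient_category = "adult",
    diagnosis = sample(c("other_noncholestatic", "other_cholestatic",
                         "acute_liver_failure", "metabolic"),
                       n, replace = TRUE, prob = c(0.7, 0.12, 0.1, 0.08)),
    meld = meld,
    status1 = runif(n) < 0.05,
    admission = admission,
    prior_transplant = runif(n) < 0.05,
    multiorgan = runif(n) < config$frac_multiorgan,
    graft_type = graft_type,
    cit_hours = round(clip(rlnorm(n, log(6.6), 0.35), 1, 24), 1),
    center_id = sample(hospitals$hospital_id, n, replace = TRUE),
    recipient_hospital = sample(hospitals$hospital_id, n, replace = TRUE),
    waiting_days = as.integer(round(clip(rlnorm(n, log(90), 1.2), 0, 3000))),
    fup
  )
}

# --- public surface ----------------------------------------------------------

#' Generate a seeded synthetic transplant registry
#'
#' Produces hospitals plus two transplant streams: adolescent recipients
#' (the analysis cohort, with acuity-confounded age-mismatch assignment and
#' piecewise-exponential graft survival carrying the configured early/late
#' exposure effects) and adult recipients of adolescent donor grafts (the
#' exogenous supply the reallocation simulation reassigns). Output is fully
#' deterministic given `config$seed`.
#'
#' @param config A [registry_config()].
#' @return A list of class `"registry"` with tibbles `hospitals`,
#'   `adolescent_tx` and `adult_tx`. Both transplant tables share one
#'   column schema (see [registry_schema()]).
#' @examples
#' reg <- generate_registry(registry_config(n_adolescent_tx = 100,
#'                                          n_adult_tx = 50, seed = 1))
#' nrow(reg$adolescent_tx)
#' @export
generate_registry <- function(config) {
  validate_registry_config(config)
  withr::with_seed(derive_seed(config$seed, 1L), {
    hospitals <- gen_hospitals(config)
    adolescent_tx <- gen_adolescent_stream(config, hospitals)
    adult_tx <- gen_adult_stream(config, hospitals)
  })
  structure(list(hospitals = hospitals,
                 adolescent_tx = adolescent_tx,
                 adult_tx = adult_tx,
                 config = config),
            class = "registry")
}

#' Column schema of a transplant stream
#'
#' @return Character vector of required transplant-record column names.
#' @export
registry_schema <- function() {
  c("tx_id", "tx_date", "donor_id", "recipient_id", "donor_age", "donor_sex",
    "donor_height", "donor_weight", "donor_type", "donor_hospital",
    "recipient_age", "recipient_sex", "recipient_height", "recipient_weight",
    "recipient_category", "diagnosis", "meld", "status1", "admission",
    "prior_transplant", "multiorgan", "graft_type", "cit_hours", "center_id",
    "recipient_hospital", "waiting_days", "graft_loss_date", "death_date",
    "last_followup_date")
}

#' Write / read a registry as CSV files
#'
#' `write_registry()` writes `hospitals.csv`, `adolescent_tx.csv`,
#' `adult_tx.csv` and the combined `transplants.csv` with ISO-8601 dates.
#' `read_registry()` reads them back.
#'
#' @param registry A `"registry"` list from [generate_registry()].
#' @param dir Directory to write to / read from (created if missing).
#' @return `write_registry()` the directory invisibly; `read_registry()` a
#'   `"registry"` list (without the generating config).
#' @export
write_registry <- function(registry, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(registry$hospitals, file.path(dir, "hospitals.csv"))
  readr::write_csv(registry$adolescent_tx, file.path(dir, "adolescent_tx.csv"))
  readr::write_csv(registry$adult_tx, file.path(dir, "adult_tx.csv"))
  readr::write_csv(dplyr::bind_rows(registry$adolescent_tx, registry$adult_tx),
                   file.path(dir, "transplants.csv"))
  invisible(dir)
}

#' @rdname write_registry
#' @export
read_registry <- function(dir) {
  read1 <- function(f) {
    readr::read_csv(file.path(dir, f), show_col_types = FALSE,
                    progress = FALSE)
  }
  structure(list(hospitals = read1("hospitals.csv"),
                 adolescent_tx = read1("adolescent_tx.csv"),
                 adult_tx = read1("adult_tx.csv")),
            class = "registry")
}
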