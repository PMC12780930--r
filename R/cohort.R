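# Cohort derivation: inclusion/exclusion rules and derived covariates.

#' Body surface area by the Du Bois formula
#'
#' `0.007184 * height^0.725 * weight^0.425`, with height in centimetres and
#' weight in kilograms, giving square metres.
#'
#' @param height_cm Height in cm, positive.
#' @param weight_kg Weight in kg, positive.
#' @return Body surface area in m^2 (vectorized).
#' @examples
#' bsa_du_bois(170, 70)
#' @export
bsa_du_bois <- function(height_cm, weight_kg) {
  ok <- !is.na(height_cm) & !is.na(weight_kg)
  if (any(ok & (height_cm <= 0 | weight_kg <= 0))) {
    abort("height and weight must be positive", class = "adolgraft_domain_error")
  }
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' Graft size class from the donor/recipient BSA index
#'
#' Small below 0.78, normal on the closed interval 0.78 to 1.24, large above
#' 1.24. The index is undefined for split or reduced grafts; see
#' [apply_inclusion()].
#'
#' @param bsa_index Ratio of donor to recipient body surface area, positive.
#' @return Character vector with levels `small`, `normal`, `large`.
#' @examples
#' classify_size(c(0.77, 0.78, 1.24, 1.25))
#' @export
classify_size <- function(bsa_index) {
  ok <- !is.na(bsa_index)
  if (any(ok & bsa_index <= 0)) {
    abort("bsa_index must be positive", class = "adolgraft_domain_error")
  }
  dplyr::case_when(
    is.na(bsa_index) ~ NA_character_,
    bsa_index < 0.78 ~ "small",
    bsa_index <= 1.24 ~ "normal",
    TRUE ~ "large"
  )
}

#' Donor-recipient age-mismatch exposure
#'
#' Exposure is a donor at least `cutoff` years *older* than the recipient
#' (signed difference; a much younger donor is not exposure).
#'
#' @param donor_age,recipient_age Ages in whole years, non-negative.
#' @param cutoff Exposure cutoff in years (default 10).
#' @return Logical vector.
#' @examples
#' classify_exposure(c(36, 25, 16), c(15, 15, 15))
#' @export
classify_exposure <- function(donor_age, recipient_age, cutoff = 10) {
  if (any(donor_age < 0 | recipient_age < 0, na.rm = TRUE)) {
    abort("ages must be non-negative", class = "adolgraft_domain_error")
  }
  (donor_age - recipient_age) >= cutoff
}

#' Center volume tertile class
#'
#' Classifies a transplant center by its total case count over the study
#' period. Default cutpoints follow the published tertiles: high at 57 or
#' more cases, middle at 28 to 56, low below 28.
#'
#' @param center_case_count Non-negative case count(s).
#' @param cutpoints Length-2 numeric `c(high, middle)` lower bounds.
#' @return Character vector with levels `high`, `middle`, `low`.
#' @examples
#' classify_center_volume(c(57, 28, 27))
#' @export
classify_center_volume <- function(center_case_count, cutpoints = c(57, 28)) {
  if (any(center_case_count < 0, na.rm = TRUE)) {
    abort("case counts must be non-negative", class = "adolgraft_domain_error")
  }
  dplyr::case_when(
    center_case_count >= cutpoints[1] ~ "high",
    center_case_count >= cutpoints[2] ~ "middle",
    TRUE ~ "low"
  )
}

# fields a row must have to be derivable at all
required_cohort_fields <- function() {
  c("tx_id", "tx_date", "donor_age", "recipient_age", "donor_type",
    "multiorgan", "graft_type", "center_id", "last_followup_date")
}

#' Derive the analysis cohort from a transplant stream
#'
#' Applies the study inclusion rules -- adolescent recipients (ages 12--17),
#' brain-death donors only, no multiorgan transplants, transplant date inside
#' the study window -- and derives every analysis covariate: the age-mismatch
#' exposure flag, donor and recipient BSA, the BSA index and size class
#' (undefined for split or reduced grafts), center-volume class, era and
#' allocation-policy flags, and right-censored graft and patient survival
#' outcomes.
#'
#' Graft survival runs from transplant to the earlier of retransplant
#' (`graft_loss_date`) or death; patients without events are censored at the
#' survival `horizon`, last recorded follow-up, or `admin_censor_date`,
#' whichever comes first. Rows missing a required field are dropped and
#' logged, never silently discarded: the returned tibble carries an
#' `attrition` attribute (counts per filter) and a `validation_log`
#' attribute (one row per dropped/flagged record with its reason).
#'
#' @param transplants Tibble with the [registry_schema()] columns.
#' @param date_window Optional length-2 `Date`; rows outside are excluded.
#' @param admin_censor_date Administrative censoring date.
#' @param horizon Survival horizon in years (default 10).
#' @param age_range Inclusive recipient age range (default `c(12, 17)`).
#' @param exposure_cutoff Age-mismatch cutoff in years (default 10).
#' @param volume_cutpoints Passed to [classify_center_volume()].
#' @param era_break First calendar year of the late era (default 2011).
#' @param policy_date Allocation-policy change date (default 2020-02-04).
#' @return A tibble of cohort rows with derived columns, one per retained
#'   transplant, with `attrition` and `validation_log` attributes.
#' @examples
#' reg <- generate_registry(registry_config(n_adolescent_tx = 200,
#'                                          n_adult_tx = 50, seed = 2))
#' cohort <- apply_inclusion(reg$adolescent_tx)
#' attr(cohort, "attrition")
#' @export
apply_inclusion <- function(transplants,
                            date_window = NULL,
                            admin_censor_date = as.Date("2025-04-04"),
                            horizon = 10,
                            age_range = c(12, 17),
                            exposure_cutoff = 10,
                            volume_cutpoints = c(57, 28),
                            era_break = 2011,
                            policy_date = as.Date("2020-02-04")) {
  tx <- tibble::as_tibble(transplants)
  missing_cols <- setdiff(required_cohort_fields(), names(tx))
  if (length(missing_cols) > 0) {
    abort(paste0("transplant table lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "adolgraft_validation_error")
  }

  log <- list()
  n0 <- nrow(tx)

  # row-level validation: required fields present
  req <- required_cohort_fields()
  bad <- !complete.cases(tx[req])
  if (any(bad)) {
    log[[length(log) + 1]] <- tibble::tibble(
      tx_id = as.character(tx$tx_id[bad]),
      stage = "validation",
      reason = "missing required field"
    )
    tx <- tx[!bad, ]
  }

  # inclusion filters (a pure conjunction, hence order-independent)
  keep_age <- tx$recipient_age >= age_range[1] & tx$recipient_age <= age_range[2]
  keep_dbd <- tx$donor_type == "DBD"
  keep_organ <- !tx$multiorgan
  keep_window <- if (is.null(date_window)) rep(TRUE, nrow(tx)) else {
    tx$tx_date >= date_window[1] & tx$tx_date <= date_window[2]
  }
  flags <- cbind(recipient_age = keep_age, donor_type_dbd = keep_dbd,
                 not_multiorgan = keep_organ, date_window = keep_window)
  for (f in colnames(flags)) {
    drop <- !flags[, f]
    if (any(drop)) {
      log[[length(log) + 1]] <- tibble::tibble(
        tx_id = as.character(tx$tx_id[drop]), stage = "inclusion", reason = f)
    }
  }
  keep <- rowSums(!flags) == 0
  cohort <- tx[keep, ]

  # derived covariates --------------------------------------------------
  cohort$age_mismatched <- classify_exposure(cohort$donor_age,
                                             cohort$recipient_age,
                                             cutoff = exposure_cutoff)
  cohort$donor_bsa <- bsa_du_bois(cohort$donor_height, cohort$donor_weight)
  cohort$recipient_bsa <- bsa_du_bois(cohort$recipient_height,
                                      cohort$recipient_weight)
  split <- cohort$graft_type == "split_or_reduced"
  cohort$bsa_index <- ifelse(split, NA_real_,
                             cohort$donor_bsa / cohort$recipient_bsa)
  cohort$size_class <- ifelse(split, "split_or_reduced",
                              classify_size(cohort$bsa_index))
  miss_size <- !split & is.na(cohort$bsa_index)
  if (any(miss_size)) {
    log[[length(log) + 1]] <- tibble::tibble(
      tx_id = as.character(cohort$tx_id[miss_size]),
      stage = "derivation", reason = "missing height/weight for size class")
  }
  cohort$sex_mismatch <- cohort$donor_sex != cohort$recipient_sex

  counts <- table(cohort$center_id)
  cohort$center_volume_class <- classify_center_volume(
    as.integer(counts[as.character(cohort$center_id)]),
    cutpoints = volume_cutpoints)

  yr <- as.integer(format(cohort$tx_date, "%Y"))
  cohort$era <- ifelse(yr < era_break,
                       paste0("pre_", era_break), paste0(era_break, "_on"))
  cohort$post_acuity_circles <- cohort$tx_date >= policy_date

  # survival outcomes ----------------------------------------------------
  admin <- pmin(cohort$last_followup_date, admin_censor_date)
  graft_event_date <- pmin(cohort$graft_loss_date, cohort$death_date,
                           na.rm = TRUE)
  g_end <- pmin(graft_event_date, admin, na.rm = TRUE)
  g_event <- !is.na(graft_event_date) & graft_event_date <= g_end
  g_time <- as.numeric(g_end - cohort$tx_date) / 365.25
  p_end <- pmin(cohort$death_date, admin, na.rm = TRUE)
  p_event <- !is.na(cohort$death_date) & cohort$death_date <= p_end
  p_time <- as.numeric(p_end - cohort$tx_date) / 365.25

  # horizon applied after time computation
  g_event[g_time > horizon] <- FALSE
  g_time <- pmin(g_time, horizon)
  p_event[p_time > horizon] <- FALSE
  p_time <- pmin(p_time, horizon)

  cohort$graft_survival_time <- pmax(g_time, 0)
  cohort$graft_event <- g_event
  cohort$patient_survival_time <- pmax(p_time, 0)
  cohort$patient_event <- p_event

  attrition <- tibble::tibble(
    stage = c("input", "validated", colnames(flags), "cohort"),
    n = c(n0, nrow(tx), vapply(colnames(flags),
                               function(f) sum(flags[, f]), integer(1)),
          nrow(cohort))
  )
  attr(cohort, "attrition") <- attrition
  attr(cohort, "validation_log") <-
    if (length(log) > 0) dplyr::bind_rows(log) else
      tibble::tibble(tx_id = character(), stage = character(),
                     reason = character())
  cohort
}

#' Write a cohort's validation log as JSON lines
#'
#' @param cohort Output of [apply_inclusion()].
#' @param path File to write (one JSON object per dropped/flagged row).
#' @return `path`, invisibly.
#' @export
write_validation_log <- function(cohort, path) {
  log <- attr(cohort, "validation_log")
  lines <- vapply(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
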