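# End-to-end orchestration: simulate (or load) -> cohort -> match ->
# survival -> reallocate -> report, with structured per-stage logging.

#' Pipeline run configuration
#'
#' Exactly one of `registry` (a [registry_config()], simulation mode) or
#' `input_dir` (a directory of registry CSVs, see [read_registry()]) must
#' be supplied.
#'
#' @param registry A [registry_config()] for simulation mode, or `NULL`.
#' @param input_dir Directory with `hospitals.csv`, `adolescent_tx.csv`,
#'   `adult_tx.csv`, or `NULL`.
#' @param out_dir Output directory for all artifacts.
#' @param exposure_cutoff Age-mismatch cutoff in years (default 10).
#' @param horizon Survival horizon in years (default 10).
#' @param landmarks Landmark times in years (default `c(1, 5)`).
#' @param caliper,caliper_scale Passed to [match_1to1()].
#' @param ceilings,window_days,weight_tolerance_kg,policy_start_date
#'   Reallocation settings (see [simulate_scenarios()]).
#' @param admin_censor_date Administrative censoring date.
#' @param seed Master seed for matching order (and simulation, unless the
#'   registry config carries its own).
#' @return Validated list of class `"run_config"`.
#' @export
run_config <- function(registry = NULL, input_dir = NULL,
                       out_dir = tempfile("adolgraft_run_"),
                       exposure_cutoff = 10, horizon = 10,
                       landmarks = c(1, 5), caliper = 0.1,
                       caliper_scale = "score",
                       ceilings = c(500, 1000, 1500, Inf),
                       window_days = 90L, weight_tolerance_kg = 20,
                       policy_start_date = as.Date("2020-02-04"),
                       admin_censor_date = as.Date("2025-04-04"),
                       seed = 1L) {
  if (is.null(registry) == is.null(input_dir)) {
    config_abort("registry/input_dir",
                 "exactly one of simulation config or input directory")
  }
  if (!is.null(registry)) validate_registry_config(registry)
  cfg <- list(registry = registry, input_dir = input_dir, out_dir = out_dir,
              exposure_cutoff = exposure_cutoff, horizon = horizon,
              landmarks = landmarks, caliper = caliper,
              caliper_scale = caliper_scale, ceilings = ceilings,
              window_days = window_days,
              weight_tolerance_kg = weight_tolerance_kg,
              policy_start_date = as.Date(policy_start_date),
              admin_censor_date = as.Date(admin_censor_date),
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

stage_log <- function(stage, ...) {
  inform(paste0("[", stage, "] ", sprintf(...)))
}

# Cox adjustment set used for the hazard-ratio tables
cox_covariates <- function() {
  c("age_mismatched", "size_class", "donor_sex", "sex_mismatch",
    "recipient_sex", "recipient_bsa", "diagnosis", "cit_ge8", "meld",
    "status1", "admission", "center_volume_class")
}

cox_hr_table <- function(dat, landmark, horizon) {
  d <- dat
  d$time <- d$graft_survival_time
  d$event <- d$graft_event
  d$cit_ge8 <- d$cit_hours >= 8
  covs <- cox_covariates()
  if (landmark > 0) d <- apply_landmark(d, landmark, horizon)
  covs <- covs[vapply(covs, function(v) length(unique(d[[v]])) > 1,
                      logical(1))]
  cox_fit(d, covs)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order -- simulate or load the registry, derive
#' the cohort, fit and match propensity scores, Kaplan-Meier / log-rank /
#' Cox analyses of graft survival (full cohort and each landmark), the
#' counterfactual reallocation -- writing every artifact as CSV plus a
#' machine-readable `summary.json` to `config$out_dir`. A stage failure
#' aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return The summary list (also written as JSON), invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", stage,
                    conditionMessage(e)),
            class = "adolgraft_pipeline_error", parent = e)
    })
  }

  # --- simulate / load ------------------------------------------------
  registry <- run_stage("registry", {
    if (!is.null(config$registry)) {
      reg <- generate_registry(config$registry)
      stage_log("registry", "simulated %d adolescent + %d adult transplants",
                nrow(reg$adolescent_tx), nrow(reg$adult_tx))
      reg
    } else {
      reg <- read_registry(config$input_dir)
      stage_log("registry", "loaded %d adolescent + %d adult transplants",
                nrow(reg$adolescent_tx), nrow(reg$adult_tx))
      reg
    }
  })
  write_registry(registry, config$out_dir)

  # --- cohort ----------------------------------------------------------
  cohort <- run_stage("cohort", {
    co <- apply_inclusion(registry$adolescent_tx,
                          admin_censor_date = config$admin_censor_date,
                          horizon = config$horizon,
                          exposure_cutoff = config$exposure_cutoff,
                          policy_date = config$policy_start_date)
    stage_log("cohort", "%d of %d rows retained (%d exposed)",
              nrow(co), nrow(registry$adolescent_tx), sum(co$age_mismatched))
    co
  })
  readr::write_csv(cohort, file.path(config$out_dir, "cohort.csv"))
  write_validation_log(cohort, file.path(config$out_dir, "validation_log.jsonl"))
  readr::write_csv(attr(cohort, "attrition"),
                   file.path(config$out_dir, "attrition.csv"))

  # --- propensity matching --------------------------------------------
  psm <- run_stage("psm", {
    m <- match_cohort(cohort, caliper = config$caliper,
                      caliper_scale = config$caliper_scale,
                      seed = config$seed)
    stage_log("psm", "%d pairs, max |SMD| %.3f -> %.3f",
              nrow(m$match$pairs), max(abs(m$balance$smd_before)),
              max(abs(m$balance$smd_after)))
    m
  })
  readr::write_csv(psm$match$pairs,
                   file.path(config$out_dir, "matched_pairs.csv"))
  readr::write_csv(psm$balance, file.path(config$out_dir, "balance.csv"))

  # --- survival --------------------------------------------------------
  surv_res <- run_stage("survival", {
    matched_ids <- c(psm$match$pairs$exposed_id, psm$match$pairs$control_id)
    matched <- cohort[cohort$tx_id %in% matched_ids, ]
    km_by_arm <- lapply(split(matched, matched$age_mismatched), function(d) {
      km_estimate(d$graft_survival_time, d$graft_event)
    })
    lr <- log_rank(matched$graft_survival_time, matched$graft_event,
                   matched$age_mismatched)
    cox_tables <- c(
      list(full = cox_hr_table(cohort, 0, config$horizon)),
      setNames(lapply(config$landmarks, function(l) {
        cox_hr_table(cohort, l, config$horizon)
      }), paste0("landmark_", config$landmarks, "y"))
    )
    stage_log("survival",
              "matched log-rank chi2 %.2f; full-cohort exposure HR %.2f",
              lr$chi2,
              cox_tables$full$table$hr[
                grep("age_mismatched", cox_tables$full$table$term)[1]])
    list(km_by_arm = km_by_arm, log_rank = lr, cox_tables = cox_tables,
         matched = matched)
  })
  for (arm in names(surv_res$km_by_arm)) {
    readr::write_csv(surv_res$km_by_arm[[arm]]$curve,
                     file.path(config$out_dir,
                               paste0("km_", ifelse(arm == "TRUE",
                                                    "mismatched", "matched"),
                                      ".csv")))
  }
  for (nm in names(surv_res$cox_tables)) {
    readr::write_csv(surv_res$cox_tables[[nm]]$table,
                     file.path(config$out_dir, paste0("cox_", nm, ".csv")))
  }

  # --- reallocation ----------------------------------------------------
  realloc <- run_stage("reallocation", {
    idx <- cohort[cohort$age_mismatched &
                    cohort$tx_date >= config$policy_start_date, ]
    if (nrow(idx) == 0) {
      stage_log("reallocation", "no index cases after the policy date; skipped")
      NULL
    } else {
      res <- simulate_scenarios(idx, registry$adult_tx, registry$hospitals,
                                ceilings = config$ceilings,
                                window_days = config$window_days,
                                weight_tolerance_kg = config$weight_tolerance_kg,
                                policy_start_date = config$policy_start_date)
      stage_log("reallocation", "%d index cases, p90 waits: %s", nrow(idx),
                paste(vapply(res, function(r) {
                  if (is.na(r$p90_wait)) paste0(">", r$window_days)
                  else as.character(r$p90_wait)
                }, character(1)), collapse = ", "))
      res
    }
  })
  if (!is.null(realloc)) {
    readr::write_csv(reallocation_summary(realloc),
                     file.path(config$out_dir, "reallocation_summary.csv"))
    for (r in realloc) {
      lab <- if (is.infinite(r$ceiling_nm)) "nolimit" else r$ceiling_nm
      readr::write_csv(r$first_arrivals,
                       file.path(config$out_dir,
                                 paste0("first_arrivals_", lab, "nm.csv")))
    }
  }

  # --- trend tabulation & summary -------------------------------------
  trends <- run_stage("trends", trend_tabulation(cohort, registry$adult_tx))
  readr::write_csv(trends$graft_destination,
                   file.path(config$out_dir, "trend_graft_destination.csv"))
  readr::write_csv(trends$mismatch_by_status,
                   file.path(config$out_dir, "trend_mismatch_by_status.csv"))

  surv_at_horizon <- lapply(surv_res$km_by_arm, function(km) {
    survival_at(km, config$horizon)
  })
  summary <- list(
    n_cohort = nrow(cohort),
    n_exposed = sum(cohort$age_mismatched),
    n_pairs = nrow(psm$match$pairs),
    balance = list(
      max_abs_smd_before = max(abs(psm$balance$smd_before)),
      max_abs_smd_after = max(abs(psm$balance$smd_after))
    ),
    km_survival_at_horizon = list(
      matched_arm = surv_at_horizon[["FALSE"]] %||% NA,
      mismatched_arm = surv_at_horizon[["TRUE"]] %||% NA
    ),
    log_rank_p = surv_res$log_rank$p,
    cox = lapply(surv_res$cox_tables, function(cf) {
      stats::setNames(lapply(seq_len(nrow(cf$table)), function(i) {
        as.list(cf$table[i, c("hr", "ci_lo", "ci_hi", "p")])
      }), cf$table$term)
    }),
    reallocation = if (is.null(realloc)) NULL else
      as.list(setNames(
        lapply(realloc, function(r) {
          list(p90_wait = r$p90_wait,
               fraction_matched = mean(!is.na(r$first_arrivals$first_day)))
        }),
        vapply(realloc, function(r) {
          if (is.infinite(r$ceiling_nm)) "no_limit"
          else paste0(r$ceiling_nm, "nm")
        }, character(1))))
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(summary)
}

#' Yearly trends in the destination of adolescent donor grafts
#'
#' Two tabulations: (1) per calendar year, the number and fraction of
#' adolescent donor grafts (donor age 12--17) going to adult, adolescent
#' and child recipients; (2) per year, the age-mismatched fraction of the
#' adolescent cohort stratified by pretransplant hospitalization (ICU or
#' ward versus home). Years with no grafts are omitted.
#'
#' @param cohort Cohort tibble from [apply_inclusion()].
#' @param adult_stream Adult-recipient transplant tibble (adolescent-donor
#'   grafts).
#' @return List with tibbles `graft_destination` (year, per-category
#'   counts and fractions summing to 1 per row) and `mismatch_by_status`.
#' @export
trend_tabulation <- function(cohort, adult_stream) {
  if (nrow(cohort) == 0 && nrow(adult_stream) == 0) {
    abort("no input rows", class = "adolgraft_domain_error")
  }
  adol_donor <- cohort[cohort$donor_age >= 12 & cohort$donor_age <= 17, ]
  dest <- dplyr::bind_rows(
    tibble::tibble(year = as.integer(format(adol_donor$tx_date, "%Y")),
                   category = adol_donor$recipient_category),
    tibble::tibble(year = as.integer(format(adult_stream$tx_date, "%Y")),
                   category = adult_stream$recipient_category)
  )
  graft_destination <- dest |>
    dplyr::count(.data$year, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L, names_prefix = "n_") |>
    dplyr::arrange(.data$year)
  cat_cols <- setdiff(names(graft_destination), "year")
  graft_destination$n_total <- rowSums(graft_destination[cat_cols])
  for (cc in cat_cols) {
    graft_destination[[sub("^n_", "frac_", cc)]] <-
      graft_destination[[cc]] / graft_destination$n_total
  }

  mismatch_by_status <- cohort |>
    dplyr::mutate(year = as.integer(format(.data$tx_date, "%Y")),
                  hospitalized = .data$admission != "home") |>
    dplyr::group_by(.data$year, .data$hospitalized) |>
    dplyr::summarise(n = dplyr::n(),
                     n_mismatched = sum(.data$age_mismatched),
                     fraction_mismatched = mean(.data$age_mismatched),
                     .groups = "drop") |>
    dplyr::arrange(.data$year, .data$hospitalized)

  list(graft_destination = graft_destination,
       mismatch_by_status = mismatch_by_status)
}
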