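# Kaplan-Meier, log-rank, Cox and landmark restriction for graft and
# overall survival. Estimation is delegated to the survival package; this
# module fixes the study's conventions (Efron ties, Wald CIs on the log-HR
# scale, events-before-censoring at tied times, landmark boundary rules).

#' Kaplan-Meier product-limit estimate
#'
#' @param time Follow-up times in years, finite and non-negative.
#' @param event Logical (or 0/1) event indicators; ties between an event
#'   and a censoring at the same time count the event first, the standard
#'   product-limit convention.
#' @return Object of class `"km_curve"`: a `curve` tibble (`time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `std_err`) and the sample
#'   size. `S(0) = 1`; the estimate is a right-continuous step function
#'   (see [survival_at()]).
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
#' survival_at(km, c(1, 3))
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) abort("empty sample", class = "adolgraft_domain_error")
  if (any(!is.finite(time)) || any(time < 0)) {
    abort("times must be finite and non-negative",
          class = "adolgraft_domain_error")
  }
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "log")
  structure(list(
    curve = tibble::tibble(
      time = fit$time,
      n_risk = fit$n.risk,
      n_event = fit$n.event,
      n_censor = fit$n.censor,
      surv = fit$surv,
      std_err = fit$std.err * fit$surv     # Greenwood SE on the surv scale
    ),
    n = length(time)
  ), class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km A `"km_curve"`.
#' @param t Times (years); values before the first observed time give 1.
#' @return Survival probabilities, right-continuous in `t`.
#' @export
survival_at <- function(km, t) {
  cv <- km$curve
  sf <- stats::stepfun(cv$time, c(1, cv$surv), right = FALSE)
  sf(t)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ",",
      sum(x$curve$n_event), "events\n")
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param time,event Follow-up times and event flags.
#' @param group Two-level grouping vector.
#' @return List with `chi2`, `df` (1) and `p`. With no events at all the
#'   statistic is 0 and p is 1.
#' @examples
#' log_rank(c(1, 2, 3, 4), c(1, 1, 1, 0), c("a", "a", "b", "b"))
#' @export
log_rank <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2 || any(tabulate(g) == 0)) {
    abort("log_rank requires two non-empty groups",
          class = "adolgraft_domain_error")
  }
  if (sum(event) == 0) return(list(chi2 = 0, df = 1L, p = 1))
  fit <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ g)
  list(chi2 = unname(fit$chisq), df = 1L,
       p = pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron handling of tied event times;
#' Wald 95% confidence intervals computed on the log-hazard-ratio scale.
#'
#' @param data Tibble with `time` and `event` columns (names configurable)
#'   plus the covariates.
#' @param covariates Character vector of covariate column names.
#' @param time_col,event_col Column names (defaults `"time"`, `"event"`).
#' @return Object of class `"cox_fit"`: `table` (tibble of `term`, `hr`,
#'   `ci_lo`, `ci_hi`, `se_log_hr`, `p`), `loglik` (log partial likelihood
#'   at the solution), `score_chi2`, `n`, `n_event` and the underlying
#'   `coxph` fit.
#' @examples
#' d <- tibble::tibble(time = c(1, 2, 3, 4, 5, 6),
#'                     event = c(1, 1, 1, 1, 0, 1),
#'                     x = c(0, 1, 0, 1, 0, 1))
#' cox_fit(d, "x")$table
#' @export
cox_fit <- function(data, covariates, time_col = "time",
                    event_col = "event") {
  if (sum(data[[event_col]]) < 1) {
    abort("Cox fit requires at least one event",
          class = "adolgraft_domain_error")
  }
  for (v in covariates) {
    if (length(unique(data[[v]])) < 2) {
      abort(sprintf("covariate `%s` is constant", v),
            class = "adolgraft_domain_error")
    }
  }
  fml <- as.formula(paste0("survival::Surv(", time_col, ", as.integer(",
                           event_col, ")) ~ ",
                           paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      if (grepl("Ran out of iterations|did not converge", conditionMessage(w))) {
        abort(paste0("Cox fit did not converge: ", conditionMessage(w)),
              class = "adolgraft_convergence_error")
      }
    })
  if (any(is.na(coef(fit)))) {
    abort("Cox fit produced undefined coefficients (collinearity?)",
          class = "adolgraft_convergence_error")
  }
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(0.975)
  structure(list(
    table = tibble::tibble(
      term = names(beta),
      hr = exp(beta),
      ci_lo = exp(beta - z * se),
      ci_hi = exp(beta + z * se),
      se_log_hr = se,
      p = 2 * pnorm(-abs(beta / se))
    ),
    loglik = fit$loglik[2],
    score_chi2 = unname(fit$score),
    n = fit$n,
    n_event = fit$nevent,
    fit = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox PH fit (Efron ties): n =", x$n, ",", x$n_event, "events\n")
  print(as.data.frame(x$table), digits = 3)
  invisible(x)
}

#' Restrict a survival sample to a landmark risk set
#'
#' Keeps only subjects still event-free *and under follow-up beyond* the
#' landmark (an event or censoring exactly at the landmark is excluded),
#' resets time 0 to the landmark, and applies the horizon on the original
#' time scale: a 5-year landmark with a 10-year horizon analyzes the 5
#' post-landmark years.
#'
#' @param data Tibble with time and event columns.
#' @param landmark Landmark time in years, `0 <= landmark < horizon`.
#' @param horizon Overall horizon in years (default 10).
#' @param time_col,event_col Column names.
#' @return The restricted tibble with shifted, truncated times.
#' @examples
#' d <- tibble::tibble(time = c(0.5, 2, 7, 12), event = c(1, 0, 1, 0))
#' apply_landmark(d, landmark = 1, horizon = 10)
#' @export
apply_landmark <- function(data, landmark, horizon = 10,
                           time_col = "time", event_col = "event") {
  if (landmark < 0 || landmark >= horizon) {
    abort("need 0 <= landmark < horizon", class = "adolgraft_domain_error")
  }
  keep <- data[[time_col]] > landmark
  out <- data[keep, ]
  if (nrow(out) == 0) {
    abort("empty risk set at the landmark", class = "adolgraft_domain_error")
  }
  t2 <- out[[time_col]] - landmark
  lim <- horizon - landmark
  ev <- as.logical(out[[event_col]])
  ev[t2 > lim] <- FALSE
  out[[time_col]] <- pmin(t2, lim)
  out[[event_col]] <- ev
  out
}
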