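# Propensity-score estimation, greedy 1:1 caliper matching, balance.

#' Default propensity-model covariates
#'
#' Graft type and size class (one combined factor), donor sex,
#' donor-recipient sex mismatch, center volume class, and recipient age,
#' sex, BSA, diagnosis, MELD, status 1 and pretransplant admission status.
#'
#' @return Character vector of cohort column names.
#' @export
psm_covariates <- function() {
  c("size_class", "donor_sex", "sex_mismatch", "center_volume_class",
    "recipient_age", "recipient_sex", "recipient_bsa", "diagnosis",
    "meld", "status1", "admission")
}

# small ridge-penalized logistic IRLS; fallback when glm separates.
# lambda is a per-observation penalty (total penalty scales with n) so the
# fit stays bounded under separation regardless of sample size.
ridge_logit <- function(x, y, lambda = 1e-2, maxit = 100, tol = 1e-9) {
  beta <- rep(0, ncol(x))
  pen <- diag(lambda * nrow(x), ncol(x))
  pen[1, 1] <- 0                       # no penalty on the intercept
  for (i in seq_len(maxit)) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    grad <- crossprod(x, y - mu) - pen %*% beta
    hess <- crossprod(x, x * w) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

#' Fit the propensity model for age-mismatch exposure
#'
#' Logistic regression of the exposure flag on the study covariates, fit by
#' maximum likelihood with one-hot encoding of categorical covariates
#' against their first (reference) level. Rows with incomplete covariates
#' are dropped (complete-case) and logged; constant covariates are dropped
#' with a warning. Perfect separation raises an error advising the ridge
#' fallback (`ridge = TRUE`, a small L2 penalty).
#'
#' @param cohort Tibble from [apply_inclusion()] (or any tibble with an
#'   `age_mismatched` flag and the covariate columns).
#' @param covariates Character vector of covariate columns.
#' @param ridge Use a ridge-penalized fit (default `FALSE`).
#' @param lambda Ridge penalty when `ridge = TRUE`.
#' @return An object of class `"propensity_model"`: coefficients, per-row
#'   scores aligned to the used rows (`row_id`), the model formula, and the
#'   dropped-row log.
#' @examples
#' reg <- generate_registry(registry_config(n_adolescent_tx = 500,
#'                                          n_adult_tx = 50, seed = 3))
#' cohort <- apply_inclusion(reg$adolescent_tx)
#' fit <- fit_propensity(cohort)
#' head(fit$scores)
#' @export
fit_propensity <- function(cohort, covariates = psm_covariates(),
                           ridge = FALSE, lambda = 1e-2) {
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov) > 0) {
    abort(paste0("cohort lacks covariate(s): ",
                 paste(missing_cov, collapse = ", ")))
  }
  if (length(unique(cohort$age_mismatched)) < 2) {
    abort("both exposure classes must be present")
  }
  dat <- cohort[c("tx_id", "age_mismatched", covariates)]
  cc <- complete.cases(dat)
  dropped <- dat$tx_id[!cc]
  dat <- dat[cc, ]

  # drop constant covariates (non-identifiable)
  keep <- vapply(covariates, function(v) length(unique(dat[[v]])) > 1,
                 logical(1))
  if (any(!keep)) {
    warn(paste0("dropping constant covariate(s): ",
                paste(covariates[!keep], collapse = ", ")))
  }
  covariates <- covariates[keep]
  if (length(covariates) == 0) abort("no usable covariates remain")

  fml <- as.formula(paste("age_mismatched ~",
                          paste(covariates, collapse = " + ")))
  x <- stats::model.matrix(fml, data = dat)
  y <- as.numeric(dat$age_mismatched)

  if (ridge) {
    beta <- ridge_logit(x, y, lambda = lambda)
    scores <- plogis(drop(x %*% beta))
    se <- rep(NA_real_, length(beta))
  } else {
    fit <- suppressWarnings(glm.fit(x, y, family = binomial()))
    beta <- coef(fit)
    scores <- fit$fitted.values
    separated <- any(scores > 1 - 1e-8) || any(scores < 1e-8) ||
      any(abs(beta) > 15, na.rm = TRUE)
    if (separated) {
      abort(paste("propensity model shows (near-)perfect separation;",
                  "refit with `ridge = TRUE` for a penalized score"),
            class = "adolgraft_separation_error")
    }
    wm <- scores * (1 - scores)
    se <- sqrt(diag(solve(crossprod(x, x * wm))))
  }

  structure(list(
    covariate_names = covariates,
    coefficients = setNames(beta, colnames(x)),
    std_errors = setNames(se, colnames(x)),
    scores = scores,
    row_id = dat$tx_id,
    exposure = dat$age_mismatched,
    formula = fml,
    dropped_rows = dropped,
    ridge = ridge
  ), class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model (", if (x$ridge) "ridge " else "", "logistic), ",
      length(x$scores), " rows, ", length(x$coefficients),
      " coefficients\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Greedy 1:1 nearest-neighbor matching within a caliper
#'
#' Matches each exposed unit to its nearest-scoring unused control, without
#' replacement, processing exposed units in a seeded random order. A pair
#' forms only if the nearest unused control lies within the caliper;
#' otherwise the exposed unit is left unmatched. Ties between equidistant
#' controls are broken by lowest row position.
#'
#' @param scores Propensity scores in (0, 1).
#' @param exposed Logical exposure flags, same length as `scores`.
#' @param caliper Caliper width (default 0.1).
#' @param caliper_scale `"score"` (caliper on the probability scale, the
#'   default, most literal reading of "set at 0.1") or `"logit_sd"`
#'   (caliper times the SD of the logit of the score, on the logit scale).
#' @param seed Seed for the processing order.
#' @param ids Optional row identifiers (default positions).
#' @return An object of class `"match_result"`: `pairs` (tibble of exposed
#'   and control ids, scores and distance), `unmatched_exposed`,
#'   `caliper_value` (resolved width on the matching scale), and `scores`.
#' @examples
#' m <- match_1to1(c(0.30, 0.90, 0.31, 0.50),
#'                 c(TRUE, TRUE, FALSE, FALSE), caliper = 0.1, seed = 1)
#' m$pairs
#' @export
match_1to1 <- function(scores, exposed, caliper = 0.1,
                       caliper_scale = c("score", "logit_sd"),
                       seed = 1L, ids = NULL) {
  caliper_scale <- match.arg(caliper_scale)
  if (any(scores <= 0 | scores >= 1)) {
    abort("scores must lie strictly in (0, 1)", class = "adolgraft_domain_error")
  }
  if (length(scores) != length(exposed)) {
    abort("scores and exposed must have equal length")
  }
  ids <- ids %||% seq_along(scores)

  if (caliper_scale == "score") {
    x <- scores
    cal <- caliper
  } else {
    x <- qlogis(scores)
    cal <- caliper * sd(qlogis(scores))
  }

  e_idx <- which(exposed)
  c_idx <- which(!exposed)
  if (length(c_idx) == 0) {
    warn("no control units available; returning empty match")
    return(structure(list(
      pairs = tibble::tibble(exposed_id = ids[integer(0)],
                             control_id = ids[integer(0)],
                             exposed_score = numeric(0),
                             control_score = numeric(0),
                             distance = numeric(0)),
      unmatched_exposed = ids[e_idx], caliper_value = cal,
      caliper_scale = caliper_scale, scores = scores),
      class = "match_result"))
  }

  # controls sorted by matching score; ties in score keep input order so the
  # lowest row id wins
  ord <- order(x[c_idx], c_idx)
  cx <- x[c_idx][ord]
  cid <- c_idx[ord]
  used <- rep(FALSE, length(cid))

  process <- withr::with_seed(derive_seed(seed, 2L), sample(e_idx))

  pair_e <- integer(0); pair_c <- integer(0); pair_d <- numeric(0)
  for (i in process) {
    pos <- findInterval(x[i], cx)
    # scan outward from the insertion point for nearest unused control
    lo <- pos; hi <- pos + 1L
    best <- NA_integer_; best_d <- Inf
    while (lo >= 1L || hi <= length(cx)) {
      d_lo <- if (lo >= 1L) x[i] - cx[lo] else Inf
      d_hi <- if (hi <= length(cx)) cx[hi] - x[i] else Inf
      if (min(d_lo, d_hi) >= best_d) break
      if (d_lo <= d_hi) {
        if (!used[lo] && d_lo < best_d - 1e-15) { best <- lo; best_d <- d_lo }
        else if (!used[lo] && abs(d_lo - best_d) <= 1e-15 &&
                 (is.na(best) || cid[lo] < cid[best])) best <- lo
        lo <- lo - 1L
      } else {
        if (!used[hi] && d_hi < best_d - 1e-15) { best <- hi; best_d <- d_hi }
        else if (!used[hi] && abs(d_hi - best_d) <= 1e-15 &&
                 (is.na(best) || cid[hi] < cid[best])) best <- hi
        hi <- hi + 1L
      }
    }
    if (!is.na(best) && best_d <= cal + 1e-12) {
      used[best] <- TRUE
      pair_e <- c(pair_e, i); pair_c <- c(pair_c, cid[best])
      pair_d <- c(pair_d, best_d)
    }
  }

  pairs <- tibble::tibble(
    exposed_id = ids[pair_e],
    control_id = ids[pair_c],
    exposed_score = scores[pair_e],
    control_score = scores[pair_c],
    distance = pair_d
  )
  pairs <- pairs[order(match(pairs$exposed_id, ids)), ]
  structure(list(pairs = pairs,
                 unmatched_exposed = ids[setdiff(e_idx, pair_e)],
                 caliper_value = cal,
                 caliper_scale = caliper_scale,
                 scores = scores),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("1:1 match:", nrow(x$pairs), "pairs,",
      length(x$unmatched_exposed), "unmatched exposed (caliper",
      signif(x$caliper_value, 4), "on the", x$caliper_scale, "scale)\n")
  invisible(x)
}

#' Standardized mean difference
#'
#' Continuous: difference in means over the pooled standard deviation
#' `sqrt((var_a + var_b)/2)` with unbiased variances. Binary: difference in
#' proportions over `sqrt((p_a(1-p_a) + p_b(1-p_b))/2)`. Zero pooled
#' variance with equal means is defined as 0; with unequal means it is an
#' error.
#'
#' @param values_a,values_b Numeric or logical vectors (group A and B).
#' @param type `"auto"` detects binary (all values 0/1), or force
#'   `"continuous"` / `"binary"`.
#' @return Signed dimensionless SMD (A minus B).
#' @examples
#' standardized_mean_difference(c(1, 1, 1, 0), c(1, 0, 0, 0))
#' @export
standardized_mean_difference <- function(values_a, values_b,
                                         type = c("auto", "continuous",
                                                  "binary")) {
  type <- match.arg(type)
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (type == "auto") {
    type <- if (all(c(a, b) %in% c(0, 1))) "binary" else "continuous"
  }
  if (type == "binary") {
    pa <- mean(a); pb <- mean(b)
    pooled <- (pa * (1 - pa) + pb * (1 - pb)) / 2
    num <- pa - pb
  } else {
    if (length(a) < 2 || length(b) < 2) {
      abort("continuous SMD needs at least 2 observations per group")
    }
    pooled <- (var(a) + var(b)) / 2
    num <- mean(a) - mean(b)
  }
  if (pooled == 0) {
    if (num == 0) return(0)
    abort("zero pooled variance with unequal means",
          class = "adolgraft_domain_error")
  }
  num / sqrt(pooled)
}

#' Covariate balance before and after matching
#'
#' Per-covariate standardized mean differences between exposed and control
#' units, before matching (all rows) and after matching (paired rows only).
#' Multi-level categorical covariates are summarized as the maximum
#' absolute SMD over their indicator levels.
#'
#' @param cohort Cohort tibble (must contain `tx_id` and `age_mismatched`).
#' @param match A `"match_result"` whose ids are `tx_id` values.
#' @param covariates Covariates to assess (default [psm_covariates()]).
#' @return Tibble with `covariate`, `smd_before`, `smd_after`.
#' @export
balance_table <- function(cohort, match, covariates = psm_covariates()) {
  smd_one <- function(dat, v) {
    x <- dat[[v]]
    e <- dat$age_mismatched
    if (is.character(x) || is.factor(x)) {
      lev <- sort(unique(as.character(x)))
      if (length(lev) <= 1) return(0)
      s <- vapply(lev, function(l) {
        standardized_mean_difference(as.numeric(x[e] == l),
                                     as.numeric(x[!e] == l), type = "binary")
      }, numeric(1))
      if (length(lev) == 2) s[2] else max(abs(s))
    } else {
      standardized_mean_difference(x[e], x[!e])
    }
  }
  matched_ids <- c(match$pairs$exposed_id, match$pairs$control_id)
  after <- cohort[cohort$tx_id %in% matched_ids, ]
  tibble::tibble(
    covariate = covariates,
    smd_before = vapply(covariates, function(v) smd_one(cohort, v), numeric(1)),
    smd_after = vapply(covariates, function(v) smd_one(after, v), numeric(1))
  )
}

#' Fit, match and assess balance in one call
#'
#' Convenience wrapper: [fit_propensity()] on the cohort, [match_1to1()] on
#' the fitted scores (ids are `tx_id`), and [balance_table()].
#'
#' @inheritParams fit_propensity
#' @inheritParams match_1to1
#' @return List with `model`, `match`, `balance`.
#' @export
match_cohort <- function(cohort, covariates = psm_covariates(),
                         caliper = 0.1,
                         caliper_scale = c("score", "logit_sd"),
                         seed = 1L, ridge = FALSE) {
  caliper_scale <- match.arg(caliper_scale)
  model <- fit_propensity(cohort, covariates, ridge = ridge)
  match <- match_1to1(model$scores, model$exposure, caliper = caliper,
                      caliper_scale = caliper_scale, seed = seed,
                      ids = model$row_id)
  used <- cohort[cohort$tx_id %in% model$row_id, ]
  balance <- balance_table(used, match, covariates = model$covariate_names)
  list(model = model, match = match, balance = balance)
}
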