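# Kaplan-Meier, log-rank, Cox and landmark restriction.

# independent product-limit oracle: direct evaluation of the definition
km_oracle <- function(time, event, t) {
  event <- as.logical(event)
  ut <- sort(unique(time[event]))
  s <- 1
  for (u in ut[ut <= t]) {
    d <- sum(time == u & event)
    n <- sum(time >= u)           # events at a tied time count before censorings
    s <- s * (1 - d / n)
  }
  s
}

# independent two-group log-rank oracle from the O-E definition
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1
  event <- as.logical(event)
  ut <- sort(unique(time[event]))
  o <- e <- v <- 0
  for (u in ut) {
    n <- sum(time >= u); n1 <- sum(time >= u & g)
    d <- sum(time == u & event); d1 <- sum(time == u & event & g)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

test_that("Kaplan-Meier matches hand product-limit values", {
  # no events: flat at 1
  km0 <- km_estimate(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_equal(survival_at(km0, c(0.5, 2, 10)), c(1, 1, 1))
  # {1 event, 2 censored, 3 event}: S(1)=2/3, S(3)=0
  km <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(survival_at(km, 1), 2 / 3)
  expect_equal(survival_at(km, 3), 0)
  expect_equal(survival_at(km, 0.99), 1)
  expect_equal(survival_at(km, 2.5), 2 / 3)
  # curve is right-continuous, non-increasing, starts at 1
  expect_true(all(diff(km$curve$surv) <= 0))
  expect_error(km_estimate(numeric(0), logical(0)),
               class = "adolgraft_domain_error")
})

test_that("Kaplan-Meier agrees with the independent oracle under censoring", {
  withr::with_seed(31, {
    time <- round(rexp(60, 0.3), 2)
    event <- runif(60) < 0.7
  })
  km <- km_estimate(time, event)
  for (t in c(0.5, 1, 2, 4, 8)) {
    expect_equal(survival_at(km, t), km_oracle(time, event, t))
  }
})

test_that("Kaplan-Meier equals the empirical survival without censoring", {
  withr::with_seed(32, time <- rexp(500, 0.2))
  km <- km_estimate(time, rep(TRUE, 500))
  for (t in c(1, 3, 5, 10)) {
    expect_equal(survival_at(km, t), mean(time > t))
  }
})

test_that("KM at 5 years is within 3 Greenwood SE of the exponential law", {
  withr::with_seed(33, {
    t_ev <- rexp(20000, 0.1)
    cens <- runif(20000, 0, 30)
  })
  time <- pmin(t_ev, cens)
  event <- t_ev <= cens
  km <- km_estimate(time, event)
  s5 <- survival_at(km, 5)
  se5 <- km$curve$std_err[max(which(km$curve$time <= 5))]
  expect_lt(abs(s5 - exp(-0.5)), 3 * se5)
})

test_that("log-rank matches hand computation and degenerate rules", {
  # identical groups: statistic exactly zero
  lr0 <- log_rank(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                  rep(c("a", "b"), each = 3))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  # hand toy: A {1 event, 4 event}, B {2 event, 5 censored}
  # O_A = 2, E_A = 1/2 + 1/3 + 1/2 = 4/3, V = 1/4 + 2/9 + 1/4 = 13/18
  time <- c(1, 4, 2, 5); event <- c(1, 1, 1, 0); grp <- c("A", "A", "B", "B")
  lr <- log_rank(time, event, grp)
  expect_equal(lr$chi2, (2 - 4 / 3)^2 / (13 / 18))
  expect_equal(round(lr$chi2, 4), 0.6154)
  expect_equal(lr$chi2, logrank_oracle(time, event, grp))
  # random instances agree with the oracle
  for (s in 1:3) {
    withr::with_seed(s, {
      tt <- round(rexp(40, 0.5), 2)
      ee <- runif(40) < 0.8
      gg <- rep(c("a", "b"), 20)
    })
    expect_equal(log_rank(tt, ee, gg)$chi2, logrank_oracle(tt, ee, gg),
                 tolerance = 1e-8)
  }
  # no events at all: chi2 0, p 1
  lrn <- log_rank(c(1, 2), c(0, 0), c("a", "b"))
  expect_equal(lrn$chi2, 0)
  expect_equal(lrn$p, 1)
  expect_error(log_rank(1, 1, "a"), class = "adolgraft_domain_error")
})

test_that("log-rank type-I error is near nominal under the null", {
  reps <- 1000
  rej <- withr::with_seed(34, {
    vapply(seq_len(reps), function(i) {
      time <- rexp(100, 0.3)
      log_rank(time, rep(TRUE, 100), rep(c("a", "b"), 50))$p < 0.05
    }, logical(1))
  })
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("Cox fit recovers a known hazard ratio and nulls", {
  # covariate independent of the hazard: CI covers 1
  withr::with_seed(35, {
    d0 <- tibble::tibble(time = rexp(2000, 0.2),
                         event = TRUE, x = rbinom(2000, 1, 0.5))
  })
  t0 <- cox_fit(d0, "x")$table
  expect_true(t0$ci_lo <= 1 && 1 <= t0$ci_hi)
  # two-group exponential with rate ratio 1.5
  withr::with_seed(36, {
    x <- rbinom(20000, 1, 0.5)
    d1 <- tibble::tibble(time = rexp(20000, 0.1 * 1.5^x), event = TRUE, x = x)
  })
  t1 <- cox_fit(d1, "x")$table
  expect_lt(abs(log(t1$hr) - log(1.5)), 3 * t1$se_log_hr)
  expect_true(t1$ci_lo <= t1$hr & t1$hr <= t1$ci_hi)
  expect_true(all(t1$hr > 0))
})

test_that("Cox score test equals the log-rank statistic without ties", {
  withr::with_seed(37, {
    time <- rexp(200, 0.3)          # continuous: ties a.s. absent
    x <- rbinom(200, 1, 0.5)
    event <- runif(200) < 0.8
  })
  d <- tibble::tibble(time = time, event = event, x = x)
  cf <- cox_fit(d, "x")
  lr <- log_rank(time, event, x)
  expect_equal(cf$score_chi2, lr$chi2, tolerance = 1e-6)
})

test_that("Cox fit rejects degenerate inputs", {
  d <- tibble::tibble(time = c(1, 2, 3), event = c(0, 0, 0), x = c(0, 1, 0))
  expect_error(cox_fit(d, "x"), class = "adolgraft_domain_error")
  d2 <- tibble::tibble(time = c(1, 2, 3), event = c(1, 1, 0), x = c(1, 1, 1))
  expect_error(cox_fit(d2, "x"), "constant",
               class = "adolgraft_domain_error")
})

test_that("landmark restriction drops, shifts and truncates correctly", {
  d <- tibble::tibble(time = c(0.5, 1.0, 2.0, 7.0, 12.0),
                      event = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  # landmark 0: unchanged apart from the horizon cap
  expect_equal(apply_landmark(d, 0, horizon = 20), d)
  lm <- apply_landmark(d, 1, horizon = 10)
  # event at 0.5 and censoring exactly at the landmark are both excluded
  expect_equal(nrow(lm), 3)
  expect_equal(lm$time, c(1, 6, 9))        # shifted by -1, capped at 10-1
  expect_equal(lm$event, c(TRUE, TRUE, FALSE))
  # 5-year landmark with 10-year horizon analyzes 5 post-landmark years
  lm5 <- apply_landmark(d, 5, horizon = 10)
  expect_equal(lm5$time, c(2, 5))
  expect_equal(lm5$event, c(TRUE, FALSE))  # event at 12 y falls past horizon
  expect_error(apply_landmark(d, 15, horizon = 10),
               class = "adolgraft_domain_error")
  expect_error(apply_landmark(d[1, ], 1, horizon = 10),
               class = "adolgraft_domain_error")
})

test_that("matching moves the exposure effect toward the truth", {
  # acuity confounds exposure and hazard; true first-year HR is 1.5
  cfg <- registry_config(n_adolescent_tx = 6000L, n_adult_tx = 10L,
                         confounding_strength = 1.2,
                         acuity_log_hr = log(1.7),
                         exposure_log_hr_early = log(1.5),
                         exposure_log_hr_late = 0,
                         baseline_hazard = c(0.15, rep(0.025, 9)),
                         seed = 38L)
  cohort <- apply_inclusion(generate_registry(cfg)$adolescent_tx)
  d <- tibble::tibble(time = cohort$graft_survival_time,
                      event = cohort$graft_event,
                      x = cohort$age_mismatched, tx_id = cohort$tx_id)
  d1 <- apply_landmark(d, 0, horizon = 1)
  hr_unmatched <- cox_fit(d1, "x")$table$hr
  m <- match_cohort(cohort, seed = 38L)
  ids <- c(m$match$pairs$exposed_id, m$match$pairs$control_id)
  hr_matched <- cox_fit(d1[d1$tx_id %in% ids, ], "x")$table$hr
  expect_lt(abs(log(hr_matched) - log(1.5)),
            abs(log(hr_unmatched) - log(1.5)))
})
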