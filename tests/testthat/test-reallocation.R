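# Great-circle distance, candidate identification, scenario simulation.

# brute-force candidate oracle: re-applies every rule independently
candidate_oracle <- function(index, stream, hospitals, ceiling, window = 90,
                             tol = 20) {
  hits <- character(0)
  for (i in seq_len(nrow(stream))) {
    r <- stream[i, ]
    day <- as.integer(r$tx_date - index$tx_date)
    if (!(r$donor_age >= 12 && r$donor_age <= 17)) next
    if (r$donor_type != "DBD") next
    if (r$graft_type != "whole") next
    if (day < 1 || day > window) next
    if (abs(r$donor_weight - index$recipient_weight) > tol) next
    dh <- hospitals[hospitals$hospital_id == r$donor_hospital, ]
    rh <- hospitals[hospitals$hospital_id == index$recipient_hospital, ]
    if (nrow(dh) == 0 || nrow(rh) == 0) next
    d <- great_circle_nm(rh$latitude, rh$longitude, dh$latitude, dh$longitude)
    if (d > ceiling) next
    hits <- c(hits, r$tx_id)
  }
  hits
}

test_that("great-circle distances match closed-form values", {
  expect_equal(great_circle_nm(40, -100, 40, -100), 0)
  # antipodal along the equator: pi * R / 1.852 km per NM
  expect_equal(great_circle_nm(0, 0, 0, 180), pi * 6371.0088 * 1000 / 1852,
               tolerance = 1e-9)
  expect_lt(abs(great_circle_nm(0, 0, 0, 180) - 10807.28), 0.5)
  # one degree of longitude on the equator: 111.195 km
  expect_lt(abs(great_circle_nm(0, 0, 0, 1) - 60.04), 0.01)
  # symmetry and vectorization
  expect_equal(great_circle_nm(33, -112, 47, -71),
               great_circle_nm(47, -71, 33, -112))
  expect_length(great_circle_nm(c(0, 10), c(0, 20), 30, 40), 2)
  expect_error(great_circle_nm(91, 0, 0, 0), class = "adolgraft_domain_error")
  expect_error(great_circle_nm(0, -200, 0, 0), class = "adolgraft_domain_error")
})

test_that("scenario parameters are validated", {
  s <- reallocation_scenario()
  expect_equal(s$window_days, 90L)
  expect_equal(s$weight_tolerance_kg, 20)
  expect_error(reallocation_scenario(ceiling_nm = -5),
               class = "adolgraft_config_error")
  expect_error(reallocation_scenario(window_days = 0),
               class = "adolgraft_config_error")
  expect_error(reallocation_scenario(weight_tolerance_kg = -1),
               class = "adolgraft_config_error")
})

make_index <- function(weight = 57.4, date = "2021-01-01", hospital = "H001") {
  tibble::tibble(tx_id = "IDX1", tx_date = as.Date(date),
                 age_mismatched = TRUE, recipient_weight = weight,
                 recipient_hospital = hospital)
}

test_that("candidate grafts obey every rule; toy matches the brute force", {
  hosp <- toy_hospitals()
  idx <- make_index()
  base <- as.Date("2021-01-01")
  stream <- toy_transplants(
    8,
    tx_date = base + c(1, 5, 0, 10, 20, 30, 91, 40),
    donor_age = c(15L, 16L, 15L, 30L, 14L, 17L, 15L, 13L),
    donor_type = c("DBD", "DBD", "DBD", "DBD", "DBD", "DCD", "DBD", "DBD"),
    graft_type = c("whole", "whole", "whole", "whole", "whole", "whole",
                   "whole", "whole"),
    donor_weight = c(75, 60, 55, 58, 90, 57, 55, 50),
    donor_hospital = rep(c("H001", "H002"), 4),
    recipient_category = "adult"
  )
  # violations: row 3 day 0, row 4 adult donor, row 5 weight off by 32.6,
  # row 6 DCD, row 7 day 91 -> rows 1, 2, 8 remain under no distance limit
  sc <- reallocation_scenario(Inf)
  cand <- find_candidate_grafts(idx, stream, hosp, sc)
  oracle <- candidate_oracle(idx, stream, hosp, Inf)
  expect_setequal(cand$graft_id, oracle)
  expect_equal(cand$graft_id, c("T000001", "T000002", "T000008"))
  # ordered by day then distance
  expect_true(all(diff(cand$day) >= 0))
  # donor weight 75 vs index 57.4: |17.6| <= 20 -> eligible
  expect_true("T000001" %in% cand$graft_id)
  # day-boundary: a day-1 graft is in, a day-0 graft is out
  expect_false("T000003" %in% cand$graft_id)
  # split grafts are excluded
  stream2 <- stream
  stream2$graft_type[1] <- "split_or_reduced"
  cand2 <- find_candidate_grafts(idx, stream2, hosp, sc)
  expect_false("T000001" %in% cand2$graft_id)
})

test_that("hand count: toy stream with three rule violations leaves five", {
  hosp <- toy_hospitals()
  idx <- make_index(weight = 60)
  base <- as.Date("2021-01-01")
  stream <- toy_transplants(
    8,
    tx_date = base + c(1, 2, 3, 4, 5, 0, 6, 7),
    donor_age = c(rep(15L, 5), 15L, 40L, 15L),
    donor_type = "DBD",
    donor_weight = c(rep(62, 5), 62, 62, 95),
    donor_hospital = "H002",
    recipient_category = "adult"
  )
  sc <- reallocation_scenario(Inf)
  cand <- find_candidate_grafts(idx, stream, hosp, sc)
  expect_equal(nrow(cand), 5)
  expect_setequal(cand$graft_id, candidate_oracle(idx, stream, hosp, Inf))
})

test_that("records with unknown hospital coordinates are skipped and logged", {
  hosp <- toy_hospitals()
  idx <- make_index()
  stream <- toy_transplants(2, tx_date = as.Date("2021-01-03"),
                            donor_age = 15L, donor_weight = 60,
                            donor_hospital = c("H002", "H999"),
                            recipient_category = "adult")
  cand <- find_candidate_grafts(idx, stream, hosp, reallocation_scenario(Inf))
  expect_equal(cand$graft_id, "T000001")
  expect_equal(attr(cand, "skipped"), "T000002")
})

test_that("preconditions on the index case are enforced", {
  hosp <- toy_hospitals()
  sc <- reallocation_scenario(Inf)
  idx_bad <- make_index(date = "2019-01-01")
  expect_error(find_candidate_grafts(idx_bad, toy_transplants(1), hosp, sc),
               class = "adolgraft_domain_error")
  idx_bad2 <- make_index(); idx_bad2$age_mismatched <- FALSE
  expect_error(find_candidate_grafts(idx_bad2, toy_transplants(1), hosp, sc),
               class = "adolgraft_domain_error")
})

test_that("p90 wait matches its empirical-percentile definition", {
  hosp <- toy_hospitals(lat = c(40, 40), lon = c(-100, -100))
  base <- as.Date("2021-06-01")
  # index case i has its first candidate exactly on day i, i = 1..10
  idx <- tibble::tibble(tx_id = sprintf("I%02d", 1:10),
                        tx_date = base - (1:10 - 1),
                        age_mismatched = TRUE,
                        recipient_weight = 60,
                        recipient_hospital = "H001")
  stream <- toy_transplants(1, tx_date = base + 1, donor_age = 15L,
                            donor_weight = 60, donor_hospital = "H002",
                            recipient_category = "adult")
  res <- simulate_scenarios(idx, stream, hosp, ceilings = Inf)
  fa <- res[[1]]$first_arrivals
  expect_setequal(fa$first_day, 1:10)
  expect_equal(res[[1]]$p90_wait, 9L)   # smallest day with >= 9/10 matched
  expect_equal(res[[1]]$cumulative$fraction[9], 0.9)
  expect_true(all(diff(res[[1]]$cumulative$fraction) >= 0))
  # every index case with a day-1 candidate: p90 = 1
  idx1 <- idx; idx1$tx_date <- base
  res1 <- simulate_scenarios(idx1, stream, hosp, ceilings = Inf)
  expect_equal(res1[[1]]$p90_wait, 1L)
  # empty stream: everything undefined
  res0 <- simulate_scenarios(idx, stream[0, ], hosp, ceilings = Inf)
  expect_true(all(is.na(res0[[1]]$first_arrivals$first_day)))
  expect_true(is.na(res0[[1]]$p90_wait))
})

test_that("ceilings are nested: candidate subsets and monotone p90", {
  reg <- generate_registry(small_config(n_adolescent_tx = 1500L,
                                        n_adult_tx = 1200L, seed = 51L))
  cohort <- apply_inclusion(reg$adolescent_tx)
  idx <- cohort[cohort$age_mismatched &
                  cohort$tx_date >= as.Date("2020-02-04"), ]
  ceilings <- c(500, 1000, 1500, Inf)
  res <- simulate_scenarios(idx, reg$adult_tx, reg$hospitals,
                            ceilings = ceilings)
  # candidate list at ceiling c equals the unlimited list filtered by c,
  # and equals the brute-force oracle for a handful of index cases
  unl <- res[[4]]$candidates
  for (k in 1:3) {
    for (id in names(unl)[seq_len(min(5, length(unl)))]) {
      expect_equal(res[[k]]$candidates[[id]]$graft_id,
                   unl[[id]]$graft_id[unl[[id]]$distance_nm <= ceilings[k]])
    }
  }
  for (id in names(unl)[seq_len(min(3, length(unl)))]) {
    expect_setequal(
      res[[1]]$candidates[[id]]$graft_id,
      candidate_oracle(idx[idx$tx_id == id, ], reg$adult_tx,
                       reg$hospitals, 500))
  }
  # p90 never increases as the ceiling is relaxed (NA = beyond the window)
  p90 <- vapply(res, function(r) {
    if (is.na(r$p90_wait)) r$window_days + 1L else r$p90_wait
  }, integer(1))
  expect_true(all(diff(p90) <= 0))
  # unlimited result dominates every finite ceiling, case by case
  for (k in 1:3) {
    f_c <- res[[k]]$first_arrivals$first_day
    f_u <- res[[4]]$first_arrivals$first_day
    expect_true(all(is.na(f_c) | (!is.na(f_u) & f_u <= f_c)))
  }
})

test_that("results are invariant to input row order", {
  reg <- generate_registry(small_config(n_adolescent_tx = 800L,
                                        n_adult_tx = 600L, seed = 52L))
  cohort <- apply_inclusion(reg$adolescent_tx)
  idx <- cohort[cohort$age_mismatched &
                  cohort$tx_date >= as.Date("2020-02-04"), ]
  r1 <- simulate_scenarios(idx, reg$adult_tx, reg$hospitals, ceilings = 1000)
  set.seed(2)
  r2 <- simulate_scenarios(idx[sample(nrow(idx)), ],
                           reg$adult_tx[sample(nrow(reg$adult_tx)), ],
                           reg$hospitals, ceilings = 1000)
  a1 <- dplyr::arrange(r1[[1]]$first_arrivals, index_tx_id)
  a2 <- dplyr::arrange(r2[[1]]$first_arrivals, index_tx_id)
  expect_equal(a1, a2)
  expect_equal(r1[[1]]$p90_wait, r2[[1]]$p90_wait)
})

test_that("consume mode removes assigned grafts from the pool", {
  hosp <- toy_hospitals(lat = c(40, 40), lon = c(-100, -100))
  base <- as.Date("2021-06-01")
  idx <- tibble::tibble(tx_id = c("I1", "I2"),
                        tx_date = c(base, base + 1),
                        age_mismatched = TRUE, recipient_weight = 60,
                        recipient_hospital = "H001")
  stream <- toy_transplants(1, tx_date = base + 2, donor_age = 15L,
                            donor_weight = 60, donor_hospital = "H002",
                            recipient_category = "adult")
  shared <- simulate_scenarios(idx, stream, hosp, ceilings = Inf)
  expect_equal(sum(!is.na(shared[[1]]$first_arrivals$first_day)), 2)
  consumed <- simulate_scenarios(idx, stream, hosp, ceilings = Inf,
                                 consume = TRUE)
  fa <- consumed[[1]]$first_arrivals
  expect_equal(sum(!is.na(fa$first_day)), 1)
  expect_false(is.na(fa$first_day[fa$index_tx_id == "I1"]))  # earliest first
})
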