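# shared fixtures: a one-row transplant-record factory and small configs

toy_transplant <- function(...) {
  row <- tibble::tibble(
    tx_id = "T000001",
    tx_date = as.Date("2021-06-01"),
    donor_id = "D1", recipient_id = "R1",
    donor_age = 16L, donor_sex = "M",
    donor_height = 170, donor_weight = 65,
    donor_type = "DBD", donor_hospital = "H001",
    recipient_age = 15L, recipient_sex = "F",
    recipient_height = 160, recipient_weight = 55,
    recipient_category = "adolescent",
    diagnosis = "biliary_atresia", meld = 20L, status1 = FALSE,
    admission = "home", prior_transplant = FALSE, multiorgan = FALSE,
    graft_type = "whole", cit_hours = 6.5, center_id = "H001",
    recipient_hospital = "H001", waiting_days = 30L,
    graft_loss_date = as.Date(NA), death_date = as.Date(NA),
    last_followup_date = as.Date("2024-06-01")
  )
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

toy_transplants <- function(n, ...) {
  args <- list(...)
  rows <- lapply(seq_len(n), function(i) {
    r <- toy_transplant(tx_id = sprintf("T%06d", i))
    for (nm in names(args)) {
      v <- args[[nm]]
      r[[nm]] <- if (length(v) == n) v[i] else v
    }
    r
  })
  dplyr::bind_rows(rows)
}

toy_hospitals <- function(lat = c(40, 40, 40), lon = c(-100, -90, -75)) {
  tibble::tibble(hospital_id = sprintf("H%03d", seq_along(lat)),
                 latitude = lat, longitude = lon)
}

small_config <- function(...) {
  args <- modifyList(list(n_adolescent_tx = 400L, n_adult_tx = 200L,
                          seed = 1L), list(...))
  do.call(registry_config, args)
}
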