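# internal helpers shared across modules

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# configuration error that names the offending field
config_abort <- function(field, msg) {
  abort(sprintf("invalid configuration field `%s`: %s", field, msg),
        class = "adolgraft_config_error", field = field)
}

stopifnot_scalar_date <- function(x, field) {
  if (!inherits(x, "Date") || length(x) != 1L || is.na(x)) {
    config_abort(field, "must be a single non-missing Date")
  }
}

# deterministic sub-seed derivation so stages draw from independent streams
# while everything is reproducible from one user-facing seed (kept < 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1009) %% 2147483647)
}

#' Format a count as a printed percentage
#'
#' Report-table helper: the percentage of `num` out of `den`, rounded to a
#' fixed number of decimal places the way registry reports print them
#' (for example 152 of 290 prints as 52.4).
#'
#' @param num Numerator count(s).
#' @param den Denominator count(s).
#' @param digits Decimal places (default 1).
#' @return Numeric vector of rounded percentages.
#' @examples
#' format_pct(152, 290)
#' @export
format_pct <- function(num, den, digits = 1) {
  round(100 * num / den, digits)
}
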