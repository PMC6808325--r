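#' Health states of the cohort model
#'
#' The model tracks three mutually exclusive states: hemodialysis (HD),
#' continuous ambulatory peritoneal dialysis (CAPD), and Death (absorbing).
#'
#' @format Character vector of state names, in matrix order.
#' @export
health_states <- c("HD", "CAPD", "Death")

#' Round a value the way the result tables print it
#'
#' Decimal rounding with ties resolved half-to-even on the decimal value,
#' not on its binary double representation. `round()` alone reports
#' 3.70 * 0.905 as 3.349 because the product's double sits fractionally
#' above the 3.3485 tie; snapping to 12 significant decimal digits first
#' restores the decimal tie so half-to-even gives 3.348, the convention
#' used for all reported quality-adjusted life years, life years and
#' Ringgit amounts.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return numeric vector rounded for reporting.
#' @examples
#' report_round(3.70 * 0.905, 3) # 3.348
#' @export
report_round <- function(x, digits = 0) {
  snapped <- vapply(x, function(v) {
    if (!is.finite(v)) return(v)
    as.numeric(sprintf("%.12g", v))
  }, numeric(1))
  round(snapped, digits)
}

# internal: stop with a classed validation error naming field and rule
abort_invalid <- function(field, rule) {
  rlang::abort(
    sprintf("validation error: `%s` %s", field, rule),
    class = "dialcea_validation_error"
  )
}

abort_config <- function(key) {
  rlang::abort(
    sprintf("configuration error: missing key `%s`", key),
    class = "dialcea_config_error"
  )
}

DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 365.25 / 12
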