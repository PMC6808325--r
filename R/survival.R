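#' Kaplan-Meier survivor function from registry records
#'
#' Product-limit estimate of survival on dialysis from patient-level
#' records under intention-to-treat attribution: every record carries its
#' first modality, and a death occurring after a modality switch still
#' counts as an event for the first modality. Transplant, recovery of
#' kidney function, loss to follow-up and administrative end of follow-up
#' are censoring events. Ties between an event and a censoring at the same
#' time are resolved events-first, the standard convention.
#'
#' @param records tibble of patient records with columns `start_date`,
#'   `terminal_date` (Date) and `terminal_event`; see
#'   [collapse_registry()] for the registry shape.
#' @param event_of_interest character vector of `terminal_event` values
#'   counted as events (default `"death"`).
#' @param censor_events `terminal_event` values treated as censorings; the
#'   two sets must be disjoint and together cover every event code present.
#' @return A tibble of class `km_curve` with one row per distinct follow-up
#'   time (months, including time 0): `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` and the Greenwood standard error `std_err`.
#' @examples
#' reg <- generate_registry(n_patients = 200, seed = 1)
#' km <- km_estimate(collapse_registry(reg))
#' head(km)
#' @export
km_estimate <- function(records,
                        event_of_interest = "death",
                        censor_events = c("switch", "transplant", "recovery",
                                          "lost_to_follow_up",
                                          "administrative_censor")) {
  if (nrow(records) == 0)
    rlang::abort("no records supplied", class = "dialcea_input_error")
  if (length(intersect(event_of_interest, censor_events)) > 0)
    rlang::abort("event and censoring sets must be disjoint",
                 class = "dialcea_input_error")
  seen <- unique(records$terminal_event)
  uncovered <- setdiff(seen, c(event_of_interest, censor_events))
  if (length(uncovered) > 0)
    rlang::abort(paste0("terminal_event value(s) not classified: ",
                        paste(uncovered, collapse = ", ")),
                 class = "dialcea_input_error")
  if (any(records$terminal_date < records$start_date))
    abort_invalid("terminal_date", "must be >= start_date")

  time <- as.numeric(records$terminal_date - records$start_date) /
    DAYS_PER_MONTH
  status <- as.integer(records$terminal_event %in% event_of_interest)
  if (all(status == 0))
    rlang::warn("all records censored; survivor function is flat at 1")

  fit <- survival::survfit(survival::Surv(time, status) ~ 1,
                           conf.type = "log")
  sf <- summary(fit, censored = TRUE)
  out <- tibble::tibble(
    time = c(0, sf$time),
    n_risk = c(length(time), sf$n.risk),
    n_event = c(0, sf$n.event),
    n_censor = c(0, sf$n.censor),
    survival = c(1, sf$surv),
    std_err = c(0, sf$std.err)
  )
  class(out) <- c("km_curve", class(out))
  attr(out, "time_unit") <- "months"
  out
}

#' Restricted mean survival time (life years)
#'
#' Area under the Kaplan-Meier step function from 0 to a horizon,
#' returned in years. This is the "life years" summary used for the
#' cost-utility comparison. If the horizon extends past the last observed
#' follow-up time the survivor function is held at its last value, with a
#' warning.
#'
#' @param curve a `km_curve` from [km_estimate()] (times in months).
#' @param horizon restriction horizon in years.
#' @return Restricted mean survival in years.
#' @export
restricted_mean_survival <- function(curve, horizon) {
  if (horizon <= 0) abort_invalid("horizon", "must be > 0")
  h <- horizon * 12  # curve carries months
  times <- curve$time
  surv <- curve$survival
  if (h > max(times) && surv[length(surv)] > 0)
    rlang::warn(sprintf(
      "horizon (%.1f months) beyond last follow-up (%.1f months); survivor function held at %.4f",
      h, max(times), surv[length(surv)]))
  # S is right-continuous and constant between event times
  knots <- c(times[times < h], h)
  widths <- diff(knots)
  heights <- surv[findInterval(knots[-length(knots)], times)]
  sum(widths * heights) / 12
}

#' Annual event rate from counts and mid-year population
#'
#' The registry convention: events occurring in a calendar year divided by
#' the estimated mid-year population at risk. Vector inputs are treated as
#' one entry per year and the yearly rates averaged with equal weight.
#'
#' @param events number of events per year (scalar or vector).
#' @param midyear_population population at risk at mid-year, same length.
#' @return A one-row tibble: `rate` (events per patient-year), `events`
#'   (total), `n_years`, with the per-year breakdown in attribute
#'   `"per_year"`.
#' @examples
#' annual_event_rate(100, 800) # rate 0.125
#' @export
annual_event_rate <- function(events, midyear_population) {
  if (length(events) != length(midyear_population))
    abort_invalid("events", "must match midyear_population in length")
  if (any(midyear_population <= 0))
    abort_invalid("midyear_population", "must be > 0")
  if (any(events < 0)) abort_invalid("events", "must be >= 0")
  yearly <- events / midyear_population
  n_years <- length(events)
  out <- tibble::tibble(
    rate = mean(yearly),
    events = sum(events),
    n_years = n_years
  )
  attr(out, "per_year") <- tibble::tibble(
    year_index = seq_along(events), events = events,
    midyear_population = midyear_population, rate = yearly
  )
  out
}

#' Convert an annual rate to a per-cycle transition probability
#'
#' `p = 1 - exp(-r t)`, the constant-hazard conversion between an
#' event rate per patient-year and the probability of at least one event
#' over a cycle of length `t` years.
#'
#' @param rate events per patient-year (vectorized, must be >= 0).
#' @param t cycle length in years (default 1).
#' @return per-cycle probability in `[0, 1)`.
#' @examples
#' rate_to_probability(0.134) # 0.12541
#' @export
rate_to_probability <- function(rate, t = 1) {
  if (any(rate < 0)) abort_invalid("rate", "must be >= 0")
  if (any(t <= 0)) abort_invalid("t", "must be > 0")
  1 - exp(-rate * t)
}

#' Annual transition rates from a registry episode table
#'
#' Computes, for each calendar year of follow-up, events (deaths and
#' modality switches by direction) divided by the mid-year population at
#' risk in the originating modality, then averages the yearly rates with
#' equal weight. The mid-year population is the head count at the
#' midpoint date (1 July) of the year by default; the average of the
#' start-of-year and end-of-year counts is available as
#' `midyear = "boundary_average"` (it slightly overstates rates in a
#' shrinking pool).
#'
#' Two attribution conventions are supported: `"current"` attributes each
#' event and all person-time to the modality occupied when it happened
#' (the convention behind per-modality annual death rates), `"first"`
#' attributes the whole of every patient's follow-up — and any death — to
#' the first modality (the intention-to-treat convention used for life
#' years). Under `"first"`, switch events retain their observed direction.
#'
#' @param episodes episode-level registry tibble from
#'   [generate_registry()] (columns `patient_id`, `modality`,
#'   `episode_start`, `episode_end`, `end_reason`).
#' @param attribution `"current"` (default) or `"first"`.
#' @param midyear mid-year population convention: `"midpoint"` (default)
#'   or `"boundary_average"`.
#' @return tibble with one row per transition (`from`, `to`): averaged
#'   `rate`, total `events`, `n_years`.
#' @export
estimate_annual_rates <- function(episodes,
                                  attribution = c("current", "first"),
                                  midyear = c("midpoint",
                                              "boundary_average")) {
  attribution <- match.arg(attribution)
  midyear <- match.arg(midyear)
  ep <- episodes
  if (attribution == "first") {
    first_mod <- ep |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        first_modality = .data$modality[which.min(.data$episode_start)],
        .groups = "drop"
      )
    ep <- ep |>
      dplyr::left_join(first_mod, by = "patient_id") |>
      dplyr::mutate(modality = .data$first_modality) |>
      dplyr::select(-"first_modality")
  }

  years <- seq(min(as.integer(format(ep$episode_start, "%Y"))),
               max(as.integer(format(ep$episode_end, "%Y"))))

  transitions <- tibble::tribble(
    ~from,  ~to,     ~reason,
    "HD",   "CAPD",  "switch",
    "HD",   "Death", "death",
    "CAPD", "HD",    "switch",
    "CAPD", "Death", "death"
  )

  purrr::pmap_dfr(transitions, function(from, to, reason) {
    # a switch keeps its observed direction (episode modality -> other)
    # under either attribution; deaths follow the attribution convention
    keep <- if (reason == "switch") {
      episodes$end_reason == "switch" & episodes$modality == from
    } else {
      ep$end_reason == "death" & ep$modality == from
    }
    ev_dates <- if (reason == "switch") episodes$episode_end[keep]
                else ep$episode_end[keep]
    at_risk <- ep[ep$modality == from, ]

    # at risk on date d: episode covers d (inclusive at both ends, so a
    # patient administratively censored on 31 Dec still counts that day)
    n_at <- function(d) sum(at_risk$episode_start <= d &
                              at_risk$episode_end >= d)
    per_year <- purrr::map_dfr(years, function(y) {
      y0 <- as.Date(sprintf("%d-01-01", y))
      y1 <- as.Date(sprintf("%d-12-31", y))
      pop <- if (midyear == "midpoint") {
        n_at(as.Date(sprintf("%d-07-01", y)))
      } else {
        (n_at(y0) + n_at(y1)) / 2
      }
      tibble::tibble(
        year = y,
        events = sum(ev_dates >= y0 & ev_dates <= y1),
        midyear = pop
      )
    }) |>
      dplyr::filter(.data$midyear > 0)

    est <- annual_event_rate(per_year$events, per_year$midyear)
    tibble::tibble(from = from, to = to, rate = est$rate,
                   events = est$events, n_years = est$n_years)
  })
}
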