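#' Generate a synthetic dialysis registry
#'
#' Simulates registry-style follow-up with the statistical structure the
#' survival-estimation stage assumes: patients enrol uniformly over an
#' enrolment window, start on HD or CAPD per the modality split, and are
#' then exposed to competing constant-hazard (exponential) clocks for
#' death, switching to the other modality, kidney transplant, recovery of
#' kidney function and loss to follow-up. A switch changes the modality
#' and restarts all clocks with the new modality's hazards
#' (memorylessness); any other event — or the administrative end of
#' follow-up — terminates the record. Default hazards are the published
#' registry-derived annual rates; the censoring hazards have no published
#' values and default to small rates reflecting the rarity of
#' deceased-donor transplantation and recovery in this population.
#'
#' @param n_patients cohort size.
#' @param modality_split named proportions `c(HD = , CAPD = )`, sum 1.
#' @param death_hazard annual death rates `c(HD = , CAPD = )`.
#' @param switch_hazard annual switch rates `c(HD_CAPD = , CAPD_HD = )`.
#' @param censor_hazards annual rates `c(transplant = , recovery = ,
#'   lost_to_follow_up = )`, applied in either modality.
#' @param enrolment_start,enrolment_end enrolment window (dates).
#' @param admin_censor_date administrative end of follow-up.
#' @param seed integer seed (optional; fixed seed gives identical output).
#' @return Episode-level tibble of class `dialysis_registry`: one row per
#'   modality spell with `patient_id`, `episode`, `modality`,
#'   `episode_start`, `episode_end`, `end_reason` (one of `death`,
#'   `switch`, `transplant`, `recovery`, `lost_to_follow_up`,
#'   `administrative_censor`). Collapse to one-row-per-patient records
#'   with [collapse_registry()].
#' @examples
#' reg <- generate_registry(100, seed = 42)
#' table(reg$end_reason)
#' @export
generate_registry <- function(n_patients,
                              modality_split = c(HD = 0.6, CAPD = 0.4),
                              death_hazard = c(HD = 0.125, CAPD = 0.134),
                              switch_hazard = c(HD_CAPD = 0.007,
                                                CAPD_HD = 0.067),
                              censor_hazards = c(transplant = 0.005,
                                                 recovery = 0.002,
                                                 lost_to_follow_up = 0.01),
                              enrolment_start = as.Date("2011-01-01"),
                              enrolment_end = as.Date("2015-12-31"),
                              admin_censor_date = as.Date("2016-12-31"),
                              seed = NULL) {
  if (n_patients < 1) abort_invalid("n_patients", "must be >= 1")
  if (abs(sum(modality_split) - 1) > 1e-9)
    abort_invalid("modality_split", "must sum to 1")
  if (any(c(death_hazard, switch_hazard, censor_hazards) < 0))
    abort_invalid("hazards", "must be >= 0")
  enrolment_start <- as.Date(enrolment_start)
  enrolment_end <- as.Date(enrolment_end)
  admin_censor_date <- as.Date(admin_censor_date)
  if (enrolment_end > admin_censor_date)
    abort_invalid("enrolment_window", "must end before admin_censor_date")
  if (!is.null(seed)) set.seed(seed)

  first_mod <- sample(names(modality_split), n_patients, replace = TRUE,
                      prob = modality_split)
  enrol <- as.numeric(enrolment_start) +
    floor(stats::runif(n_patients) *
            (as.numeric(enrolment_end - enrolment_start) + 1))
  admin_num <- as.numeric(admin_censor_date)
  causes <- c("death", "switch", "transplant", "recovery",
              "lost_to_follow_up")

  # competing exponential clocks, vectorized over the still-active cohort;
  # a switch flips the modality, restarts the clocks (memorylessness) and
  # sends the patient into the next round
  active <- seq_len(n_patients)
  mod <- first_mod
  t0 <- enrol
  episode_no <- rep(1L, n_patients)
  chunks <- list()
  while (length(active) > 0) {
    m <- mod[active]
    hz <- cbind(
      death = unname(death_hazard[m]),
      switch = unname(switch_hazard[ifelse(m == "HD",
                                           "HD_CAPD", "CAPD_HD")]),
      transplant = censor_hazards[["transplant"]],
      recovery = censor_hazards[["recovery"]],
      lost_to_follow_up = censor_hazards[["lost_to_follow_up"]]
    )
    total <- rowSums(hz)
    tt <- stats::rexp(length(active)) / total  # Inf where total == 0
    u <- stats::runif(length(active)) * total
    cum <- hz
    for (j in 2:ncol(cum)) cum[, j] <- cum[, j] + cum[, j - 1]
    cause <- causes[rowSums(cum < u) + 1]
    t_end <- round(t0[active] + tt * DAYS_PER_YEAR)
    admin <- t_end >= admin_num | !is.finite(t_end)
    t_end[admin] <- admin_num
    cause[admin] <- "administrative_censor"

    chunks[[length(chunks) + 1]] <- tibble::tibble(
      patient_id = sprintf("P%05d", active),
      episode = episode_no[active],
      modality = m,
      episode_start = as.Date(t0[active], origin = "1970-01-01"),
      episode_end = as.Date(t_end, origin = "1970-01-01"),
      end_reason = cause
    )
    switching <- active[cause == "switch"]
    t0[switching] <- t_end[cause == "switch"]
    mod[switching] <- ifelse(mod[switching] == "HD", "CAPD", "HD")
    episode_no[switching] <- episode_no[switching] + 1L
    active <- switching
  }
  out <- dplyr::bind_rows(chunks) |>
    dplyr::arrange(.data$patient_id, .data$episode)
  class(out) <- c("dialysis_registry", class(out))
  out
}

#' Collapse an episode registry to one record per patient
#'
#' The patient-record shape consumed by [km_estimate()]: first modality
#' (retained regardless of later switches, the intention-to-treat
#' convention), dialysis start date, and the terminal event with its
#' date. Interior switch episodes disappear into the record; their count
#' is kept in `n_switches`.
#'
#' @param episodes a `dialysis_registry` tibble from
#'   [generate_registry()] (or any table with its columns).
#' @return tibble with one row per patient: `patient_id`,
#'   `first_modality`, `start_date`, `terminal_event`, `terminal_date`,
#'   `n_switches`.
#' @export
collapse_registry <- function(episodes) {
  episodes |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$episode, .by_group = TRUE) |>
    dplyr::summarise(
      first_modality = dplyr::first(.data$modality),
      start_date = dplyr::first(.data$episode_start),
      terminal_event = dplyr::last(.data$end_reason),
      terminal_date = dplyr::last(.data$episode_end),
      n_switches = sum(.data$end_reason == "switch"),
      .groups = "drop"
    )
}

#' Run the full pipeline on a synthetic registry
#'
#' Chains the stages end to end: generate a registry, estimate annual
#' transition rates by the mid-year-population convention, convert them
#' to per-cycle probabilities, build the transition matrix, and run the
#' Markov cohort model — returning every intermediate for pipeline-level
#' testing.
#'
#' @param n_patients,seed,... passed to [generate_registry()].
#' @param params parameter bundle supplying costs, utilities, horizon and
#'   scenario mix (default [default_parameters()]).
#' @param scenario scenario label selecting the initial mix.
#' @param attribution rate-attribution convention, see
#'   [estimate_annual_rates()].
#' @return list with `episodes`, `records`, `rates` (estimated),
#'   `probabilities`, `tpm`, and `result` (a `markov_result`).
#' @export
end_to_end_fixture <- function(n_patients, seed = NULL, params = NULL,
                               scenario = "base_case",
                               attribution = "current", ...) {
  params <- params %||% default_parameters()
  episodes <- generate_registry(n_patients, seed = seed, ...)
  records <- collapse_registry(episodes)
  rates <- estimate_annual_rates(episodes, attribution = attribution)
  cl <- params$settings$cycle_length
  probabilities <- rates |>
    dplyr::mutate(probability = rate_to_probability(.data$rate, cl))
  tpm <- build_transition_matrix(
    dplyr::select(rates, "from", "to", "rate"), cycle_length = cl)
  init <- params$scenarios[params$scenarios$scenario == scenario, ]
  result <- run_cohort(init, tpm, params = params,
                       discount_rate = params$settings$discount_rate)
  list(episodes = episodes, records = records, rates = rates,
       probabilities = probabilities, tpm = tpm, result = result)
}
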