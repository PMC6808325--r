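#' Load model parameters from a YAML configuration file
#'
#' Reads the full set of model inputs — per-patient annual cost components
#' with plausible ranges for HD and CAPD, EQ-5D utility indices, annual
#' transition rates, scenario initial-mix definitions, and economic
#' settings (discount rate, horizon, willingness-to-pay thresholds, life
#' years) — and validates every structural invariant before returning.
#'
#' @param path path to a YAML parameter file; see
#'   `system.file("extdata", "moh_dialysis_2017.yaml", package = "dialcea")`
#'   for the bundled default layout.
#' @return An object of class `dialysis_params`: a list of tibbles
#'   (`costs`, `cost_totals`, `utilities`, `rates`, `scenarios`) plus a
#'   `settings` list.
#' @seealso [default_parameters()], [write_parameters()],
#'   [validate_cost_totals()]
#' @export
load_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- function(x, key, where) {
    if (is.null(x[[key]])) abort_config(paste0(where, key))
    x[[key]]
  }
  costs_raw <- need(raw, "costs", "")

  cost_components <- c(
    "outpatient", "access_surgeries", "building_land", "equipment",
    "staff", "overheads", "dialysis_consumables", "hospitalization"
  )
  costs <- purrr::map_dfr(c("HD", "CAPD"), function(mod) {
    modc <- need(costs_raw, mod, "costs/")
    comp <- need(modc, "components", paste0("costs/", mod, "/"))
    purrr::map_dfr(cost_components, function(cmp) {
      entry <- need(comp, cmp, paste0("costs/", mod, "/components/"))
      tibble::tibble(
        modality = mod, component = cmp,
        mean = entry$mean, low = entry$low, high = entry$high
      )
    })
  })
  cost_totals <- purrr::map_dfr(c("HD", "CAPD"), function(mod) {
    tot <- need(need(costs_raw, mod, "costs/"), "total",
                paste0("costs/", mod, "/"))
    tibble::tibble(modality = mod, mean = tot$mean,
                   low = tot$low, high = tot$high)
  })

  util_raw <- need(raw, "utilities", "")
  utilities <- purrr::map_dfr(c("HD", "CAPD"), function(mod) {
    u <- need(util_raw, mod, "utilities/")
    tibble::tibble(modality = mod, mean = u$mean, low = u$low, high = u$high)
  })

  rate_raw <- need(raw, "transition_rates", "")
  rate_keys <- tibble::tribble(
    ~key,         ~from,  ~to,
    "HD_CAPD",    "HD",   "CAPD",
    "HD_death",   "HD",   "Death",
    "CAPD_HD",    "CAPD", "HD",
    "CAPD_death", "CAPD", "Death"
  )
  rates <- purrr::pmap_dfr(rate_keys, function(key, from, to) {
    r <- need(rate_raw, key, "transition_rates/")
    tibble::tibble(from = from, to = to, label = key,
                   mean = r$mean, low = r$low, high = r$high)
  })

  scen_raw <- need(raw, "scenarios", "")
  scenarios <- purrr::imap_dfr(scen_raw, function(s, nm) {
    tibble::tibble(
      scenario = nm,
      init_HD = need(s, "init_HD", paste0("scenarios/", nm, "/")),
      init_CAPD = need(s, "init_CAPD", paste0("scenarios/", nm, "/"))
    )
  })

  set_raw <- need(raw, "settings", "")
  wtp <- need(set_raw, "wtp_thresholds", "settings/")
  ly <- need(set_raw, "life_years", "settings/")
  settings <- list(
    discount_rate = need(set_raw, "discount_rate", "settings/"),
    n_cycles = need(set_raw, "n_cycles", "settings/"),
    cycle_length = need(set_raw, "cycle_length", "settings/"),
    wtp_very_cost_effective = need(wtp, "very_cost_effective",
                                   "settings/wtp_thresholds/"),
    wtp_cost_effective = need(wtp, "cost_effective",
                              "settings/wtp_thresholds/"),
    life_years = c(HD = need(ly, "HD", "settings/life_years/"),
                   CAPD = need(ly, "CAPD", "settings/life_years/"))
  )

  params <- structure(
    list(costs = costs, cost_totals = cost_totals, utilities = utilities,
         rates = rates, scenarios = scenarios, settings = settings),
    class = "dialysis_params"
  )
  validate_parameters(params)
  params
}

#' Bundled default parameter set
#'
#' The published Malaysian Ministry of Health inputs: 2017 Ringgit cost
#' components, EQ-5D-3L utilities (HD 0.854, CAPD 0.905), registry-derived
#' annual transition rates, the four provision scenarios (60:40 base case,
#' 55:45, 50:50, 70:30 HD:CAPD) and economic settings (3% discounting,
#' five 1-year cycles, RM40,000 / RM120,000 willingness-to-pay thresholds).
#'
#' @return A `dialysis_params` object; see [load_parameters()].
#' @examples
#' p <- default_parameters()
#' p$cost_totals
#' @export
default_parameters <- function() {
  load_parameters(system.file("extdata", "moh_dialysis_2017.yaml",
                              package = "dialcea", mustWork = TRUE))
}

#' Serialize parameters back to YAML
#'
#' Inverse of [load_parameters()]: writing and re-loading reproduces every
#' numeric field bit-identically (values are emitted at 15 significant
#' digits).
#'
#' @param params a `dialysis_params` object.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "dialysis_params"))
  rng <- function(row) list(mean = row$mean, low = row$low, high = row$high)
  costs <- lapply(c("HD", "CAPD"), function(mod) {
    comp <- dplyr::filter(params$costs, .data$modality == mod)
    tot <- dplyr::filter(params$cost_totals, .data$modality == mod)
    list(
      components = stats::setNames(
        lapply(seq_len(nrow(comp)), function(i) rng(comp[i, ])),
        comp$component
      ),
      total = rng(tot)
    )
  })
  names(costs) <- c("HD", "CAPD")
  utilities <- lapply(c("HD", "CAPD"), function(mod) {
    rng(dplyr::filter(params$utilities, .data$modality == mod))
  })
  names(utilities) <- c("HD", "CAPD")
  rates <- stats::setNames(
    lapply(seq_len(nrow(params$rates)), function(i) rng(params$rates[i, ])),
    params$rates$label
  )
  scenarios <- stats::setNames(
    lapply(seq_len(nrow(params$scenarios)), function(i) {
      list(init_HD = params$scenarios$init_HD[i],
           init_CAPD = params$scenarios$init_CAPD[i])
    }),
    params$scenarios$scenario
  )
  s <- params$settings
  out <- list(
    costs = costs, utilities = utilities, transition_rates = rates,
    scenarios = scenarios,
    settings = list(
      discount_rate = s$discount_rate, n_cycles = s$n_cycles,
      cycle_length = s$cycle_length,
      wtp_thresholds = list(
        very_cost_effective = s$wtp_very_cost_effective,
        cost_effective = s$wtp_cost_effective
      ),
      life_years = list(HD = unname(s$life_years["HD"]),
                        CAPD = unname(s$life_years["CAPD"]))
    )
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Validate a parameter bundle
#'
#' Checks every structural invariant: component means within their ranges
#' and non-negative lows, utilities in `[0, 1]` with ordered ranges,
#' transition rates positive with per-modality exit-rate sums below 3
#' (so stay-probabilities remain positive after rate-to-probability
#' conversion), scenario initial mixes on the unit simplex, discount rate
#' in `[0, 1)`, and ordered positive willingness-to-pay thresholds.
#' Component sums are checked against printed totals to 0.5 RM.
#'
#' @param params a `dialysis_params` object.
#' @return `params`, invisibly, if valid; otherwise an error of class
#'   `dialcea_validation_error` naming the offending field and rule.
#' @export
validate_parameters <- function(params) {
  co <- params$costs
  for (i in seq_len(nrow(co))) {
    f <- paste0("costs$", co$modality[i], "$", co$component[i])
    if (co$low[i] < 0) abort_invalid(f, "must have low >= 0")
    if (co$mean[i] < co$low[i] || co$mean[i] > co$high[i])
      abort_invalid(f, "must have mean within [low, high]")
  }
  tot_check <- validate_cost_totals(params)
  if (!all(tot_check$pass)) {
    bad <- tot_check$modality[!tot_check$pass][1]
    abort_invalid(paste0("cost_totals$", bad),
                  "component sum must match printed total within 0.5 RM")
  }

  ut <- params$utilities
  for (i in seq_len(nrow(ut))) {
    f <- paste0("utilities$", ut$modality[i])
    ok <- ut$low[i] >= 0 && ut$low[i] <= ut$mean[i] &&
      ut$mean[i] <= ut$high[i] && ut$high[i] <= 1
    if (!ok) abort_invalid(f, "must satisfy 0 <= low <= mean <= high <= 1")
  }

  ra <- params$rates
  for (i in seq_len(nrow(ra))) {
    f <- paste0("rates$", ra$label[i])
    if (ra$mean[i] <= 0) abort_invalid(f, "must be > 0")
    if (ra$low[i] > ra$mean[i] || ra$mean[i] > ra$high[i])
      abort_invalid(f, "must satisfy low <= mean <= high")
  }
  exit_sums <- ra |>
    dplyr::group_by(.data$from) |>
    dplyr::summarise(total = sum(.data$mean), .groups = "drop")
  for (i in seq_len(nrow(exit_sums))) {
    if (exit_sums$total[i] >= 3)
      abort_invalid(paste0("rates (exits from ", exit_sums$from[i], ")"),
                    "exit-rate sum must be < 3")
  }

  sc <- params$scenarios
  for (i in seq_len(nrow(sc))) {
    f <- paste0("scenarios$", sc$scenario[i])
    if (sc$init_HD[i] < 0 || sc$init_HD[i] > 1 ||
        sc$init_CAPD[i] < 0 || sc$init_CAPD[i] > 1)
      abort_invalid(f, "initial proportions must lie in [0, 1]")
    if (abs(sc$init_HD[i] + sc$init_CAPD[i] - 1) > 1e-9)
      abort_invalid(f, "initial proportions must sum to 1")
  }

  s <- params$settings
  if (s$discount_rate < 0 || s$discount_rate >= 1)
    abort_invalid("settings$discount_rate", "must lie in [0, 1)")
  if (s$n_cycles < 1) abort_invalid("settings$n_cycles", "must be >= 1")
  if (s$cycle_length <= 0)
    abort_invalid("settings$cycle_length", "must be > 0")
  if (s$wtp_very_cost_effective <= 0 ||
      s$wtp_cost_effective <= s$wtp_very_cost_effective)
    abort_invalid("settings$wtp_thresholds",
                  "must be positive and ordered (very < cost_effective)")
  invisible(params)
}

#' Check cost component sums against printed totals
#'
#' The eight annual cost components per modality should reproduce the
#' printed per-patient total to within 0.5 RM (the slack left by rounding
#' each component to whole sen).
#'
#' @param params a `dialysis_params` object.
#' @param tolerance allowed absolute discrepancy in RM (default 0.5).
#' @return A tibble with one row per modality: `component_sum`,
#'   `printed_total`, `discrepancy`, and logical `pass`.
#' @examples
#' validate_cost_totals(default_parameters())
#' @export
validate_cost_totals <- function(params, tolerance = 0.5) {
  sums <- params$costs |>
    dplyr::group_by(.data$modality) |>
    dplyr::summarise(component_sum = sum(.data$mean), .groups = "drop")
  dplyr::left_join(sums,
                   dplyr::select(params$cost_totals, "modality",
                                 printed_total = "mean"),
                   by = "modality") |>
    dplyr::mutate(
      discrepancy = abs(.data$component_sum - .data$printed_total),
      pass = .data$discrepancy <= tolerance
    )
}

#' @export
print.dialysis_params <- function(x, ...) {
  cat("<dialysis_params>\n")
  cat("  cost components:", nrow(x$costs), "over",
      length(unique(x$costs$modality)), "modalities\n")
  tot <- x$cost_totals
  cat(sprintf("  annual cost (RM/patient/yr): HD %.2f, CAPD %.2f\n",
              tot$mean[tot$modality == "HD"],
              tot$mean[tot$modality == "CAPD"]))
  u <- x$utilities
  cat(sprintf("  utilities: HD %.3f, CAPD %.3f\n",
              u$mean[u$modality == "HD"], u$mean[u$modality == "CAPD"]))
  cat("  scenarios:", paste(x$scenarios$scenario, collapse = ", "), "\n")
  cat(sprintf("  horizon: %d cycles of %g yr, discount %.1f%%\n",
              x$settings$n_cycles, x$settings$cycle_length,
              100 * x$settings$discount_rate))
  invisible(x)
}

# internal: named vectors used across modules
cost_vector <- function(params) {
  stats::setNames(params$cost_totals$mean, params$cost_totals$modality)
}

utility_vector <- function(params) {
  stats::setNames(params$utilities$mean, params$utilities$modality)
}
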