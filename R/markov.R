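#' Build the per-cycle transition probability matrix
#'
#' Converts annual transition rates to per-cycle probabilities with
#' `p = 1 - exp(-r t)` and assembles the 3-state (HD, CAPD, Death)
#' row-stochastic matrix. Each off-diagonal exit probability is converted
#' independently; the stay probability is one minus the exits; the Death
#' row is absorbing. One movement per cycle is implied by the single-step
#' matrix.
#'
#' @param rates either a `dialysis_params` object (mean rates are used) or
#'   a tibble with columns `from`, `to`, `rate` giving annual rates for
#'   the four live transitions.
#' @param cycle_length cycle length in years (default 1).
#' @return 3x3 matrix with dimnames `health_states`, rows summing to 1.
#' @examples
#' build_transition_matrix(default_parameters())
#' @export
build_transition_matrix <- function(rates, cycle_length = 1) {
  if (inherits(rates, "dialysis_params"))
    rates <- dplyr::select(rates$rates, "from", "to", rate = "mean")
  if (any(rates$rate < 0)) abort_invalid("rate", "must be >= 0")
  m <- matrix(0, 3, 3, dimnames = list(health_states, health_states))
  m["Death", "Death"] <- 1
  for (i in seq_len(nrow(rates))) {
    m[rates$from[i], rates$to[i]] <-
      rate_to_probability(rates$rate[i], cycle_length)
  }
  for (s in c("HD", "CAPD")) {
    exits <- sum(m[s, setdiff(health_states, s)])
    if (exits >= 1)
      rlang::abort(
        sprintf("exit probabilities from state %s sum to %.4f (>= 1)",
                s, exits),
        class = "dialcea_validation_error")
    m[s, s] <- 1 - exits
  }
  m
}

# internal: row-stochasticity check
assert_stochastic <- function(tpm, tol = 1e-12) {
  if (!all(dim(tpm) == c(3, 3)) ||
      any(tpm < -tol) || any(tpm > 1 + tol) ||
      any(abs(rowSums(tpm) - 1) > tol))
    rlang::abort("transition matrix is not row-stochastic over 3 states",
                 class = "dialcea_validation_error")
  invisible(tpm)
}

#' Run the Markov cohort simulation
#'
#' Propagates the state-occupancy vector through `n_cycles` applications
#' of the transition matrix and accumulates per-cycle cost, life years and
#' QALYs with a half-cycle correction: each cycle's contribution weights
#' state occupancy by the average of its start-of-cycle and end-of-cycle
#' values (equivalently, trapezoidal weights 1/2, 1, ..., 1, 1/2 on the
#' cycle boundaries). The Death state accrues nothing. Cycle-k
#' contributions are discounted by `(1 + discount_rate)^-k`
#' (`discount_timing = "end"`, the default) or `^-(k - 1/2)`
#' (`"half"`, aligning the discount point with the half-cycle assumption).
#'
#' @param init initial occupancy: named numeric `c(HD = , CAPD = )`
#'   summing to 1, or a one-row scenario tibble with `init_HD`/`init_CAPD`.
#' @param tpm 3x3 transition matrix from [build_transition_matrix()].
#' @param costs named annual per-patient cost `c(HD = , CAPD = )` in RM.
#' @param utilities named utility indices `c(HD = , CAPD = )`.
#' @param n_cycles number of cycles (default 5).
#' @param cycle_length cycle length in years (default 1).
#' @param discount_rate annual discount rate (default 0.03).
#' @param discount_timing `"end"` or `"half"`.
#' @param scenario optional label stored on the result.
#' @return An object of class `markov_result`: list with `scenario`,
#'   `totals` (named list: `cost`, `ly`, `qaly` and discounted
#'   `disc_cost`, `disc_ly`, `disc_qaly`), the per-cycle `trace` tibble
#'   (occupancy plus per-cycle and discounted contributions) and the run
#'   `settings`. Use [tidy()] for the trace and [glance()] for totals.
#' @param params optional `dialysis_params`; supplies costs, utilities,
#'   horizon and cycle length when the explicit arguments are left NULL.
#' @examples
#' p <- default_parameters()
#' run_cohort(c(HD = 0.6, CAPD = 0.4), build_transition_matrix(p), params = p)
#' @export
run_cohort <- function(init, tpm, costs = NULL, utilities = NULL,
                       n_cycles = 5, cycle_length = 1,
                       discount_rate = 0.03,
                       discount_timing = c("end", "half"),
                       scenario = NULL, params = NULL) {
  discount_timing <- match.arg(discount_timing)
  if (!is.null(params)) {
    if (is.null(costs)) costs <- cost_vector(params)
    if (is.null(utilities)) utilities <- utility_vector(params)
    n_cycles <- params$settings$n_cycles
    cycle_length <- params$settings$cycle_length
  }
  if (is.data.frame(init)) {
    scenario <- scenario %||% init$scenario[1]
    init <- c(HD = init$init_HD[1], CAPD = init$init_CAPD[1])
  }
  if (is.null(names(init))) names(init) <- c("HD", "CAPD")
  if (any(init < 0) || abs(sum(init) - 1) > 1e-9)
    abort_invalid("init", "must be non-negative and sum to 1")
  assert_stochastic(tpm)
  if (n_cycles < 1) abort_invalid("n_cycles", "must be >= 1")
  stopifnot(all(c("HD", "CAPD") %in% names(costs)),
            all(c("HD", "CAPD") %in% names(utilities)))

  occ <- matrix(0, n_cycles + 1, 3,
                dimnames = list(NULL, health_states))
  occ[1, ] <- c(init[["HD"]], init[["CAPD"]], 0)
  for (k in seq_len(n_cycles)) occ[k + 1, ] <- occ[k, ] %*% tpm

  cvec <- c(costs[["HD"]], costs[["CAPD"]])
  uvec <- c(utilities[["HD"]], utilities[["CAPD"]])
  k <- seq_len(n_cycles)
  alive_mid <- (occ[k, 1:2, drop = FALSE] + occ[k + 1, 1:2, drop = FALSE]) / 2
  cycle_ly <- cycle_length * rowSums(alive_mid)
  cycle_qaly <- cycle_length * as.numeric(alive_mid %*% uvec)
  cycle_cost <- cycle_length * as.numeric(alive_mid %*% cvec)
  disc_exp <- if (discount_timing == "end") k else k - 0.5
  df <- (1 + discount_rate)^(-disc_exp * cycle_length)

  disc_ly <- cycle_ly * df
  disc_qaly <- cycle_qaly * df
  disc_cost <- cycle_cost * df
  trace <- tibble::tibble(
    cycle = 0:n_cycles,
    HD = occ[, 1], CAPD = occ[, 2], Death = occ[, 3],
    cycle_ly = c(0, cycle_ly),
    cycle_qaly = c(0, cycle_qaly),
    cycle_cost = c(0, cycle_cost),
    disc_ly = c(0, disc_ly),
    disc_qaly = c(0, disc_qaly),
    disc_cost = c(0, disc_cost)
  )
  totals <- list(
    cost = sum(cycle_cost), ly = sum(cycle_ly), qaly = sum(cycle_qaly),
    disc_cost = sum(cycle_cost * df), disc_ly = sum(cycle_ly * df),
    disc_qaly = sum(cycle_qaly * df)
  )
  structure(
    list(scenario = scenario %||% "cohort", totals = totals, trace = trace,
         settings = list(n_cycles = n_cycles, cycle_length = cycle_length,
                         discount_rate = discount_rate,
                         discount_timing = discount_timing,
                         tpm = tpm, costs = cvec, utilities = uvec)),
    class = "markov_result"
  )
}

#' Mix pure-start cohort results into a scenario result
#'
#' A scenario that starts `init_HD` of the cohort on HD and `init_CAPD` on
#' CAPD equals the same mixture of the two pure-start runs, because the
#' cohort recursion, the half-cycle weighting and discounting are all
#' linear in the initial vector. Both runs must share identical settings
#' (matrix, horizon, discounting).
#'
#' @param result_hd `markov_result` from an all-HD start.
#' @param result_capd `markov_result` from an all-CAPD start.
#' @param init scenario mix: named vector or scenario tibble row.
#' @param scenario optional label.
#' @return A `markov_result` for the mixed cohort.
#' @export
weighted_strategy_result <- function(result_hd, result_capd, init,
                                     scenario = NULL) {
  s1 <- result_hd$settings
  s2 <- result_capd$settings
  same <- isTRUE(all.equal(s1[c("n_cycles", "cycle_length", "discount_rate",
                                "discount_timing")],
                           s2[c("n_cycles", "cycle_length", "discount_rate",
                                "discount_timing")])) &&
    isTRUE(all.equal(s1$tpm, s2$tpm)) &&
    isTRUE(all.equal(s1$costs, s2$costs)) &&
    isTRUE(all.equal(s1$utilities, s2$utilities))
  if (!same)
    rlang::abort("results were computed under different settings",
                 class = "dialcea_input_error")
  if (is.data.frame(init)) {
    scenario <- scenario %||% init$scenario[1]
    init <- c(HD = init$init_HD[1], CAPD = init$init_CAPD[1])
  }
  w <- c(init[["HD"]], init[["CAPD"]])
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    abort_invalid("init", "must be non-negative and sum to 1")

  totals <- purrr::map2(result_hd$totals, result_capd$totals,
                        ~ w[1] * .x + w[2] * .y)
  num <- setdiff(names(result_hd$trace), "cycle")
  trace <- result_hd$trace
  for (col in num)
    trace[[col]] <- w[1] * result_hd$trace[[col]] +
      w[2] * result_capd$trace[[col]]
  structure(
    list(scenario = scenario %||% "weighted", totals = totals,
         trace = trace, settings = s1),
    class = "markov_result"
  )
}

#' Run every provision scenario
#'
#' Runs the two pure-start cohorts once and mixes them into each
#' scenario's initial HD:CAPD distribution, returning the scenario table
#' that feeds the incremental cost-effectiveness analysis.
#'
#' @param params a `dialysis_params` object.
#' @param discount_timing passed to [run_cohort()].
#' @return tibble with one row per scenario: undiscounted `cost`, `ly`,
#'   `qaly` and discounted `disc_cost`, `disc_ly`, `disc_qaly`
#'   (per patient, over the model horizon).
#' @examples
#' run_scenarios(default_parameters())
#' @export
run_scenarios <- function(params, discount_timing = "end") {
  tpm <- build_transition_matrix(params, params$settings$cycle_length)
  base_args <- list(
    tpm = tpm, costs = cost_vector(params),
    utilities = utility_vector(params),
    n_cycles = params$settings$n_cycles,
    cycle_length = params$settings$cycle_length,
    discount_rate = params$settings$discount_rate,
    discount_timing = discount_timing
  )
  hd <- do.call(run_cohort, c(list(init = c(HD = 1, CAPD = 0)), base_args))
  capd <- do.call(run_cohort, c(list(init = c(HD = 0, CAPD = 1)), base_args))
  purrr::pmap_dfr(params$scenarios, function(scenario, init_HD, init_CAPD) {
    res <- weighted_strategy_result(
      hd, capd, c(HD = init_HD, CAPD = init_CAPD), scenario = scenario)
    tibble::tibble(scenario = scenario, !!!res$totals)
  })
}

#' @export
print.markov_result <- function(x, ...) {
  t <- x$totals
  cat(sprintf("<markov_result: %s> %d cycles, discount %.1f%%\n",
              x$scenario, x$settings$n_cycles,
              100 * x$settings$discount_rate))
  cat(sprintf("  undiscounted: cost RM%.0f, LY %.3f, QALY %.3f\n",
              t$cost, t$ly, t$qaly))
  cat(sprintf("  discounted:   cost RM%.0f, LY %.3f, QALY %.3f\n",
              t$disc_cost, t$disc_ly, t$disc_qaly))
  invisible(x)
}
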