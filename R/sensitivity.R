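#' Fit a sampling distribution to a mean and plausible range
#'
#' Method-of-moments fit treating the printed (low, high) range as a
#' central 95% interval, so `SD = (high - low) / 3.92` (an alternative
#' `(high - low) / 4` convention is available via `range_sd`). Gamma
#' (costs): `shape = mean^2 / var`, `rate = mean / var`. Beta (utilities,
#' transition rates): `alpha = mean * nu`, `beta = (1 - mean) * nu` with
#' `nu = mean (1 - mean) / var - 1`. The fitted distribution's mean equals
#' the input mean by construction. A zero-width range (or zero mean for a
#' gamma) yields a degenerate point mass.
#'
#' @param family `"gamma"` or `"beta"`.
#' @param mean,low,high the printed mean and range (low <= mean <= high).
#' @param range_sd `"ci95"` (divide range by 3.92, default) or
#'   `"quarter"` (divide by 4).
#' @return A list of class `distribution_spec`: `family` (possibly
#'   `"degenerate"`), `mean`, `low`, `high`, `sd`, and the fitted
#'   parameters (`shape`/`rate` for gamma, `shape1`/`shape2` for beta).
#' @examples
#' fit_distribution("beta", 0.5, 0.25, 0.75) # alpha = beta ~ 7.18
#' @export
fit_distribution <- function(family = c("gamma", "beta"), mean, low, high,
                             range_sd = c("ci95", "quarter")) {
  family <- match.arg(family)
  range_sd <- match.arg(range_sd)
  if (low > mean || mean > high)
    abort_invalid("mean", "must satisfy low <= mean <= high")
  sd <- (high - low) / if (range_sd == "ci95") 3.92 else 4
  v <- sd^2

  if (family == "gamma") {
    if (mean < 0) abort_invalid("mean", "must be >= 0 for a gamma")
    if (mean == 0 && v > 0) {
      rlang::warn("gamma with zero mean: using a degenerate point mass")
      v <- 0
    }
    if (v == 0)
      return(structure(list(family = "degenerate", mean = mean, low = low,
                            high = high, sd = 0),
                       class = "distribution_spec"))
    spec <- list(family = "gamma", mean = mean, low = low, high = high,
                 sd = sd, shape = mean^2 / v, rate = mean / v)
  } else {
    if (mean < 0 || mean > 1)
      abort_invalid("mean", "must lie in [0, 1] for a beta")
    if (v == 0)
      return(structure(list(family = "degenerate", mean = mean, low = low,
                            high = high, sd = 0),
                       class = "distribution_spec"))
    if (v >= mean * (1 - mean))
      rlang::abort(
        sprintf("beta fit infeasible: variance %.4g >= mean(1-mean) %.4g",
                v, mean * (1 - mean)),
        class = "dialcea_validation_error")
    nu <- mean * (1 - mean) / v - 1
    spec <- list(family = "beta", mean = mean, low = low, high = high,
                 sd = sd, shape1 = mean * nu, shape2 = (1 - mean) * nu)
  }
  structure(spec, class = "distribution_spec")
}

#' Draw from a fitted distribution spec
#'
#' @param spec a `distribution_spec` from [fit_distribution()].
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
sample_distribution <- function(spec, n) {
  switch(spec$family,
    degenerate = rep(spec$mean, n),
    gamma = stats::rgamma(n, shape = spec$shape, rate = spec$rate),
    beta = stats::rbeta(n, shape1 = spec$shape1, shape2 = spec$shape2)
  )
}

# internal: the full labelled parameter table driving tornado and PSA.
# Labels follow the field convention: c<MOD>_<component>, u<MOD>,
# p<FROM>_<TO or death>.
parameter_table <- function(params) {
  costs <- params$costs |>
    dplyr::transmute(
      label = paste0("c", .data$modality, "_",
                     c(outpatient = "outpatient",
                       access_surgeries = "access",
                       building_land = "building_land",
                       equipment = "equipment",
                       staff = "staffing",
                       overheads = "overheads",
                       dialysis_consumables = "consumables",
                       hospitalization = "hosp")[.data$component]),
      block = "cost", modality = .data$modality,
      component = .data$component,
      mean = .data$mean, low = .data$low, high = .data$high,
      family = "gamma"
    )
  utils_ <- params$utilities |>
    dplyr::transmute(
      label = paste0("u", .data$modality), block = "utility",
      modality = .data$modality, component = NA_character_,
      mean = .data$mean, low = .data$low, high = .data$high,
      family = "beta"
    )
  rates <- params$rates |>
    dplyr::transmute(
      label = paste0("p", .data$from, "_",
                     ifelse(.data$to == "Death", "death", .data$to)),
      block = "rate", modality = .data$from, component = .data$to,
      mean = .data$mean, low = .data$low, high = .data$high,
      family = "beta"
    )
  dplyr::bind_rows(costs, utils_, rates)
}

# internal: set one labelled parameter to a value, returning new params
set_parameter <- function(params, row, value) {
  p <- params
  if (row$block == "cost") {
    sel <- p$costs$modality == row$modality &
      p$costs$component == row$component
    p$costs$mean[sel] <- value
    # keep the modality total consistent with its components
    p$cost_totals$mean[p$cost_totals$modality == row$modality] <-
      sum(p$costs$mean[p$costs$modality == row$modality])
  } else if (row$block == "utility") {
    p$utilities$mean[p$utilities$modality == row$modality] <- value
  } else {
    sel <- p$rates$from == row$modality & p$rates$to == row$component
    p$rates$mean[sel] <- value
  }
  p
}

# internal: incremental (intervention - comparator) totals between two
# scenarios under a parameter bundle; mixes two pure-start runs.
scenario_pair_totals <- function(params, intervention, comparator,
                                 discount_timing = "end") {
  res <- run_scenarios(params, discount_timing = discount_timing)
  list(
    intervention = res[res$scenario == intervention, ],
    comparator = res[res$scenario == comparator, ]
  )
}

#' One-way sensitivity analysis: NMB tornado
#'
#' For each model input (the 16 cost components, 2 utilities and 4
#' transition rates) in turn, sets it to its low then its high range
#' bound with every other input at its mean, reruns the Markov model for
#' both scenarios of the comparison, and records the incremental net
#' monetary benefit (intervention minus comparator) at the
#' willingness-to-pay threshold. Entries are sorted by descending bar
#' width, the tornado order. Each endpoint also carries the compared
#' strategies' own cost per QALY and its threshold classification
#' (`worst_class` is the weaker of the two strategies' classes at that
#' endpoint), the sense in which every imputed value can remain
#' cost-effective even where the incremental ranking flips.
#'
#' @param params a `dialysis_params` object.
#' @param intervention,comparator scenario labels (defaults: the 50:50
#'   strategy against the 60:40 base case, i.e. the policy alternative
#'   against current practice).
#' @param threshold willingness-to-pay per QALY (RM).
#' @param discounted use discounted totals (default TRUE).
#' @param discount_timing passed to [run_cohort()].
#' @return tibble of class `tornado_result`, one row per parameter:
#'   `parameter`, `low`, `high`, `nmb_at_low`, `nmb_at_high`,
#'   `bar_width`, `cpq_max` (largest strategy cost/QALY across both
#'   endpoints), `worst_class`. Attributes: `baseline_nmb`, `threshold`.
#' @export
one_way_tornado <- function(params, intervention = "scenario2",
                            comparator = "base_case", threshold = 120000,
                            discounted = TRUE, discount_timing = "end") {
  stopifnot(all(c(intervention, comparator) %in% params$scenarios$scenario))
  tab <- parameter_table(params)
  cost_col <- if (discounted) "disc_cost" else "cost"
  qaly_col <- if (discounted) "disc_qaly" else "qaly"

  eval_pair <- function(p) {
    pr <- scenario_pair_totals(p, intervention, comparator, discount_timing)
    nmb <- net_monetary_benefit(
      pr$intervention[[qaly_col]] - pr$comparator[[qaly_col]],
      pr$intervention[[cost_col]] - pr$comparator[[cost_col]],
      threshold)
    cpq <- c(pr$intervention[[cost_col]] / pr$intervention[[qaly_col]],
             pr$comparator[[cost_col]] / pr$comparator[[qaly_col]])
    list(nmb = nmb, cpq_max = max(cpq))
  }
  baseline <- eval_pair(params)

  rows <- purrr::map_dfr(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    ends <- c(low = row$low, high = row$high)
    if (row$block == "utility" && ends["high"] > 1) {
      rlang::warn(sprintf("clipping %s high range to 1", row$label))
      ends["high"] <- 1
    }
    at <- lapply(ends, function(v) eval_pair(set_parameter(params, row, v)))
    tibble::tibble(
      parameter = row$label, low = ends[["low"]], high = ends[["high"]],
      nmb_at_low = at$low$nmb, nmb_at_high = at$high$nmb,
      bar_width = abs(at$high$nmb - at$low$nmb),
      cpq_max = max(at$low$cpq_max, at$high$cpq_max),
      worst_class = classify_threshold(
        max(at$low$cpq_max, at$high$cpq_max),
        very_threshold = min(40000, threshold), threshold = threshold)
    )
  }) |>
    dplyr::arrange(dplyr::desc(.data$bar_width), .data$parameter)
  class(rows) <- c("tornado_result", class(rows))
  attr(rows, "baseline_nmb") <- baseline$nmb
  attr(rows, "threshold") <- threshold
  attr(rows, "comparison") <- c(intervention = intervention,
                                comparator = comparator)
  rows
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Each iteration draws every cost component from its fitted gamma
#' distribution, each utility and each annual transition rate from its
#' fitted beta, rebuilds the transition matrix, and runs the cohort model
#' for every scenario on the common draw (common random numbers, so
#' between-scenario differences are not masked by sampling noise).
#' Iterations whose drawn exit probabilities would sum to 1 or more for
#' some state are redrawn; the count is recorded in attribute
#' `"n_redraws"`.
#'
#' @param params a `dialysis_params` object.
#' @param n_iterations Monte Carlo iterations (default 1000).
#' @param seed integer seed for reproducibility (optional).
#' @param discount_timing passed to [run_cohort()].
#' @param range_sd range-to-SD convention for [fit_distribution()].
#' @return tibble of class `psa_result`: one row per iteration x
#'   scenario, with undiscounted `cost`, `ly`, `qaly` and discounted
#'   `disc_cost`, `disc_ly`, `disc_qaly`.
#' @export
run_psa <- function(params, n_iterations = 1000, seed = NULL,
                    discount_timing = "end", range_sd = "ci95") {
  if (n_iterations < 1) abort_invalid("n_iterations", "must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  tab <- parameter_table(params)
  specs <- purrr::map(seq_len(nrow(tab)), function(i) {
    fit_distribution(tab$family[i], tab$mean[i], tab$low[i], tab$high[i],
                     range_sd = range_sd)
  })
  s <- params$settings
  n_redraws <- 0L

  draw_params <- function() {
    repeat {
      vals <- vapply(specs, sample_distribution, numeric(1), n = 1)
      p <- params
      for (i in seq_len(nrow(tab))) p <- set_parameter(p, tab[i, ], vals[i])
      exit_ok <- p$rates |>
        dplyr::group_by(.data$from) |>
        dplyr::summarise(
          ok = sum(rate_to_probability(.data$mean, s$cycle_length)) < 1,
          .groups = "drop")
      if (all(exit_ok$ok)) return(p)
      n_redraws <<- n_redraws + 1L
    }
  }

  out <- purrr::map_dfr(seq_len(n_iterations), function(it) {
    p <- draw_params()
    run_scenarios(p, discount_timing = discount_timing) |>
      dplyr::mutate(iteration = it, .before = 1)
  })
  class(out) <- c("psa_result", class(out))
  attr(out, "n_redraws") <- n_redraws
  attr(out, "seed") <- seed
  out
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay threshold on the grid, the probability
#' that each scenario attains the maximum net monetary benefit
#' (`qaly * threshold - cost`) across the PSA iterations; exact ties
#' share their probability equally.
#'
#' @param samples a `psa_result` from [run_psa()].
#' @param thresholds threshold grid in RM/QALY (default 0 to 200,000 in
#'   steps of 5,000).
#' @param discounted evaluate NMB on discounted cost/QALY (default TRUE).
#' @return tibble of class `ceac_curve`: `threshold`, `scenario`,
#'   `probability`; probabilities sum to 1 at every threshold.
#' @export
ceac <- function(samples, thresholds = seq(0, 200000, by = 5000),
                 discounted = TRUE) {
  if (length(thresholds) == 0)
    rlang::abort("threshold grid is empty", class = "dialcea_input_error")
  if (nrow(samples) == 0)
    rlang::abort("no PSA samples", class = "dialcea_input_error")
  cost_col <- if (discounted) "disc_cost" else "cost"
  qaly_col <- if (discounted) "disc_qaly" else "qaly"
  scen <- unique(samples$scenario)
  wide_c <- matrix(samples[[cost_col]], ncol = length(scen), byrow = TRUE)
  wide_q <- matrix(samples[[qaly_col]], ncol = length(scen), byrow = TRUE)
  # rows are iterations in order, columns scenarios in first-seen order
  colnames(wide_c) <- colnames(wide_q) <- samples$scenario[seq_along(scen)]

  purrr::map_dfr(thresholds, function(lambda) {
    nmb <- wide_q * lambda - wide_c
    best <- nmb == apply(nmb, 1, max)
    weight <- best / rowSums(best)  # ties split equally
    tibble::tibble(
      threshold = lambda,
      scenario = colnames(wide_c),
      probability = unname(colMeans(weight))
    )
  }) |>
    structure(class = c("ceac_curve", class(tibble::tibble())))
}
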