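#' Quality-adjusted life years from life years and a utility index
#'
#' @param life_years life years (>= 0).
#' @param utility EQ-5D-type utility index in `[0, 1]`.
#' @return `life_years * utility`, at full precision; use [report_round()]
#'   with 3 decimals for printed-style reporting.
#' @examples
#' report_round(qaly_from_ly(4.15, 0.854), 3) # 3.544
#' @export
qaly_from_ly <- function(life_years, utility) {
  if (any(utility > 1) || any(utility < 0))
    abort_invalid("utility", "must lie in [0, 1]")
  if (any(life_years < 0)) abort_invalid("life_years", "must be >= 0")
  life_years * utility
}

#' Cost per life year and per QALY
#'
#' The cost per life year of a dialysis modality is its mean annual
#' per-patient treatment cost (one life year sustained on dialysis costs
#' one year of treatment); the cost per QALY scales it by the ratio of
#' life years to QALYs, i.e. `annual_cost * life_years / qaly`.
#'
#' @param annual_cost mean annual per-patient cost (RM/year).
#' @param life_years life years.
#' @param qaly quality-adjusted life years (> 0).
#' @return one-row tibble: `cost_per_ly`, `cost_per_qaly` (full
#'   precision; reporting rounds to whole RM).
#' @examples
#' cost_per_outcome(39791, 4.15, 3.544)
#' @export
cost_per_outcome <- function(annual_cost, life_years, qaly) {
  if (any(qaly <= 0)) abort_invalid("qaly", "must be > 0")
  if (any(life_years <= 0)) abort_invalid("life_years", "must be > 0")
  tibble::tibble(
    cost_per_ly = annual_cost,
    cost_per_qaly = annual_cost * life_years / qaly
  )
}

#' Per-modality cost-effectiveness and cost-utility summary
#'
#' Builds the modality comparison table: life years, QALYs (life years
#' weighted by the EQ-5D utility), annual cost, cost per life year and
#' cost per QALY, for HD and CAPD. With `rounded = TRUE` (default) the
#' printed reporting convention is applied: life years to 2 decimals,
#' QALYs to 3, Ringgit to whole units — and the rounded values feed the
#' downstream divisions, so the table reproduces published figures
#' exactly.
#'
#' @param params a `dialysis_params` object.
#' @param rounded apply the reporting convention (default TRUE).
#' @return tibble with one row per modality: `life_years`, `qaly`,
#'   `annual_cost`, `cost_per_ly`, `cost_per_qaly`.
#' @examples
#' modality_summary(default_parameters())
#' @export
modality_summary <- function(params, rounded = TRUE) {
  out <- purrr::map_dfr(c("HD", "CAPD"), function(mod) {
    ly <- unname(params$settings$life_years[mod])
    u <- params$utilities$mean[params$utilities$modality == mod]
    cost <- params$cost_totals$mean[params$cost_totals$modality == mod]
    if (rounded) {
      ly <- report_round(ly, 2)
      q <- report_round(qaly_from_ly(ly, u), 3)
      cost <- report_round(cost, 0)
    } else {
      q <- qaly_from_ly(ly, u)
    }
    cpo <- cost_per_outcome(cost, ly, q)
    tibble::tibble(
      modality = mod, life_years = ly, qaly = q, annual_cost = cost,
      cost_per_ly = if (rounded) report_round(cpo$cost_per_ly, 0)
                    else cpo$cost_per_ly,
      cost_per_qaly = if (rounded) report_round(cpo$cost_per_qaly, 0)
                      else cpo$cost_per_qaly
    )
  })
  out
}

#' Cost ratios between two modality summaries
#'
#' @param a,b one-row summaries (rows of [modality_summary()] output);
#'   ratios are `a / b`.
#' @return one-row tibble `ratio_per_ly`, `ratio_per_qaly`, rounded to
#'   2 decimals for reporting.
#' @examples
#' ms <- modality_summary(default_parameters())
#' cost_ratio(ms[ms$modality == "HD", ], ms[ms$modality == "CAPD", ])
#' @export
cost_ratio <- function(a, b) {
  if (b$cost_per_ly <= 0 || b$cost_per_qaly <= 0)
    abort_invalid("b", "must have positive costs")
  tibble::tibble(
    ratio_per_ly = report_round(a$cost_per_ly / b$cost_per_ly, 2),
    ratio_per_qaly = report_round(a$cost_per_qaly / b$cost_per_qaly, 2)
  )
}

#' Net monetary benefit
#'
#' `NMB = incremental QALYs x threshold - incremental cost`. A positive
#' NMB means the intervention is cost-effective against its comparator at
#' the given willingness-to-pay threshold.
#'
#' @param incr_qaly incremental QALYs.
#' @param incr_cost incremental cost (RM).
#' @param threshold willingness-to-pay per QALY (RM, >= 0).
#' @return NMB in RM (vectorized).
#' @examples
#' net_monetary_benefit(2, 100000, 120000) # 140000
#' @export
net_monetary_benefit <- function(incr_qaly, incr_cost, threshold) {
  if (any(threshold < 0)) abort_invalid("threshold", "must be >= 0")
  incr_qaly * threshold - incr_cost
}

#' Classify a cost-effectiveness ratio against GDP-based thresholds
#'
#' Below 1x GDP per capita (RM40,000 by default): very cost-effective;
#' below 3x GDP (RM120,000): cost-effective; otherwise not
#' cost-effective.
#'
#' @param value cost per QALY (or per LY), or an ICER (RM).
#' @param very_threshold,threshold the two ordered thresholds.
#' @return character vector of classifications.
#' @export
classify_threshold <- function(value, very_threshold = 40000,
                               threshold = 120000) {
  dplyr::case_when(
    value < very_threshold ~ "very_cost_effective",
    value < threshold ~ "cost_effective",
    .default = "not_cost_effective"
  )
}

#' Incremental cost-effectiveness ladder with dominance analysis
#'
#' Orders strategies by effectiveness, flags strict dominance (higher
#' cost with lower-or-equal effectiveness), removes extended dominance
#' (a strategy whose ICER exceeds that of the next more effective
#' alternative, so a mixture of its neighbours would be more efficient),
#' computes ICERs between surviving frontier neighbours, and classifies
#' each ICER against the willingness-to-pay thresholds. For dominated
#' strategies the dominance flag is reported instead of an ICER.
#'
#' @param scenarios tibble with columns `scenario` (label), `cost` and
#'   `effect` (QALYs, or LYs).
#' @param very_threshold,threshold classification thresholds (RM).
#' @param strict_only if TRUE, skip extended-dominance removal.
#' @return tibble of class `cea_result`, ordered by effectiveness:
#'   `scenario`, `cost`, `effect`, `dominance` (one of `nondominated`,
#'   `strictly_dominated`, `extendedly_dominated`, `equivalent`), `icer`
#'   (vs the previous frontier strategy; NA for dominated strategies and
#'   the least effective frontier strategy), `comparator`,
#'   `threshold_class`.
#' @examples
#' icer_ladder(tibble::tibble(scenario = c("A", "B"),
#'                            cost = c(100, 150), effect = c(1, 2)))
#' @export
icer_ladder <- function(scenarios, very_threshold = 40000,
                        threshold = 120000, strict_only = FALSE) {
  if (nrow(scenarios) < 2)
    rlang::abort("need at least 2 scenarios", class = "dialcea_input_error")
  df <- scenarios |>
    dplyr::select("scenario", "cost", "effect") |>
    dplyr::arrange(.data$effect, .data$cost, .data$scenario) |>
    dplyr::mutate(dominance = "nondominated", icer = NA_real_,
                  comparator = NA_character_)

  # equivalents: identical cost and effectiveness
  for (i in seq_len(nrow(df))) {
    same <- df$cost == df$cost[i] & df$effect == df$effect[i]
    if (sum(same) > 1 && which(same)[1] != i) df$dominance[i] <- "equivalent"
  }

  # strict dominance
  for (i in seq_len(nrow(df))) {
    if (df$dominance[i] != "nondominated") next
    others <- df[-i, ]
    dominated <- any(
      (others$cost <= df$cost[i] & others$effect > df$effect[i]) |
      (others$cost < df$cost[i] & others$effect >= df$effect[i])
    )
    if (dominated) df$dominance[i] <- "strictly_dominated"
  }

  # extended dominance on the remaining frontier
  if (!strict_only) {
    repeat {
      idx <- which(df$dominance == "nondominated")
      if (length(idx) < 3) break
      icers <- diff(df$cost[idx]) / diff(df$effect[idx])
      drop <- which(diff(icers) < 0)  # ICER falls at the next step
      if (length(drop) == 0) break
      df$dominance[idx[drop[1] + 1]] <- "extendedly_dominated"
    }
  }

  idx <- which(df$dominance == "nondominated")
  if (length(idx) >= 2) {
    for (j in 2:length(idx)) {
      i <- idx[j]; prev <- idx[j - 1]
      df$icer[i] <- (df$cost[i] - df$cost[prev]) /
        (df$effect[i] - df$effect[prev])
      df$comparator[i] <- df$scenario[prev]
    }
  }
  df$threshold_class <- ifelse(
    is.na(df$icer), NA_character_,
    classify_threshold(df$icer, very_threshold, threshold))
  class(df) <- c("cea_result", class(df))
  attr(df, "thresholds") <- c(very_cost_effective = very_threshold,
                              cost_effective = threshold)
  df
}
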