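test_that("QALY weighting reproduces the published cost-utility table", {
  expect_equal(report_round(qaly_from_ly(4.15, 0.854), 3), 3.544)
  expect_equal(report_round(qaly_from_ly(3.70, 0.905), 3), 3.348)
  expect_equal(qaly_from_ly(2.7, 1), 2.7)
  expect_error(qaly_from_ly(4, 1.2), "utility")

  ms <- modality_summary(default_parameters())
  expect_equal(ms$qaly[ms$modality == "HD"], 3.544)
  expect_equal(ms$qaly[ms$modality == "CAPD"], 3.348)
  expect_equal(ms$cost_per_qaly[ms$modality == "HD"], 46595)
  expect_equal(ms$cost_per_qaly[ms$modality == "CAPD"], 41527)
})

test_that("cost per outcome is the annual cost scaled by LY/QALY", {
  hd <- cost_per_outcome(39791, 4.15, 3.544)
  expect_equal(hd$cost_per_ly, 39791)
  expect_equal(report_round(hd$cost_per_qaly, 0), 46595)
  capd <- cost_per_outcome(37576, 3.70, 3.348)
  expect_equal(report_round(capd$cost_per_qaly, 0), 41527)
  u1 <- cost_per_outcome(1000, 3, 3)
  expect_equal(u1$cost_per_ly, u1$cost_per_qaly)
  expect_error(cost_per_outcome(1000, 3, 0), "qaly")
})

test_that("modality cost ratios match at 2-decimal reporting", {
  ms <- modality_summary(default_parameters())
  r <- cost_ratio(ms[ms$modality == "HD", ], ms[ms$modality == "CAPD", ])
  expect_equal(r$ratio_per_ly, 1.06)
  expect_equal(r$ratio_per_qaly, 1.12)
  same <- cost_ratio(ms[1, ], ms[1, ])
  expect_equal(unlist(same), c(ratio_per_ly = 1, ratio_per_qaly = 1))
})

test_that("net monetary benefit is incremental benefit minus cost", {
  expect_equal(net_monetary_benefit(2, 100000, 120000), 140000)
  expect_equal(net_monetary_benefit(0, 0, 50000), 0)
  expect_equal(net_monetary_benefit(0.1, 20000, 120000), -8000)
  expect_error(net_monetary_benefit(1, 1, -5), "threshold")
})

test_that("NMB sign agrees with ICER versus threshold", {
  set.seed(21)
  for (i in 1:200) {
    dq <- stats::runif(1, 0.001, 2)
    dc <- stats::runif(1, -50000, 200000)
    lambda <- stats::runif(1, 0, 150000)
    icer <- dc / dq
    nmb <- net_monetary_benefit(dq, dc, lambda)
    if (abs(icer - lambda) > 1e-8) {
      expect_equal(nmb > 0, icer < lambda)
    }
  }
})

test_that("the ICER ladder ranks, flags dominance and classifies", {
  two <- icer_ladder(tibble::tibble(
    scenario = c("A", "B"), cost = c(100, 150), effect = c(1, 2)),
    very_threshold = 40, threshold = 120)
  expect_equal(two$dominance, c("nondominated", "nondominated"))
  expect_equal(two$icer, c(NA, 50))
  expect_equal(two$threshold_class[2], "cost_effective")

  tri <- icer_ladder(tibble::tibble(
    scenario = c("A", "B", "C"),
    cost = c(100, 150, 200), effect = c(1, 2, 1.5)))
  expect_equal(tri$dominance[tri$scenario == "C"], "strictly_dominated")
  expect_true(is.na(tri$icer[tri$scenario == "C"]))

  frontier <- icer_ladder(tibble::tibble(
    scenario = c("A", "B", "C"),
    cost = c(0, 100, 150), effect = c(0, 1, 1.2)))
  expect_equal(frontier$dominance, rep("nondominated", 3))
  expect_equal(frontier$icer, c(NA, 100, 250))
})

test_that("extended dominance removes strategies off the efficient frontier", {
  # B's ICER (100) exceeds C's ICER over B (25): mixture of A and C beats B
  lad <- icer_ladder(tibble::tibble(
    scenario = c("A", "B", "C"),
    cost = c(0, 100, 150), effect = c(0, 1, 3)))
  expect_equal(lad$dominance[lad$scenario == "B"], "extendedly_dominated")
  expect_equal(lad$icer[lad$scenario == "C"], 50)  # C vs A directly

  strict <- icer_ladder(tibble::tibble(
    scenario = c("A", "B", "C"),
    cost = c(0, 100, 150), effect = c(0, 1, 3)), strict_only = TRUE)
  expect_equal(strict$dominance[strict$scenario == "B"], "nondominated")
})

test_that("the ladder is invariant under input ordering", {
  base <- tibble::tibble(
    scenario = c("A", "B", "C", "D"),
    cost = c(0, 100, 150, 120), effect = c(0, 1, 3, 0.5))
  ref <- icer_ladder(base)
  set.seed(33)
  for (i in 1:10) {
    perm <- icer_ladder(base[sample(nrow(base)), ])
    expect_equal(as.data.frame(perm), as.data.frame(ref))
  }
})

test_that("frontier ICERs increase with effectiveness", {
  set.seed(44)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    lad <- icer_ladder(tibble::tibble(
      scenario = paste0("S", 1:n),
      cost = stats::runif(n, 0, 1e5),
      effect = stats::runif(n, 0, 5)))
    icers <- lad$icer[!is.na(lad$icer)]
    if (length(icers) > 1) expect_true(all(diff(icers) > 0))
  }
})

test_that("cost-and-effect ties are flagged equivalent without an ICER", {
  lad <- icer_ladder(tibble::tibble(
    scenario = c("A", "B"), cost = c(100, 100), effect = c(1, 1)))
  expect_true("equivalent" %in% lad$dominance)
  expect_true(all(is.na(lad$icer)))
})

test_that("threshold classification follows the GDP bands", {
  expect_equal(classify_threshold(c(30000, 46595, 150000)),
               c("very_cost_effective", "cost_effective",
                 "not_cost_effective"))
})
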