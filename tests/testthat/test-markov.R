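p_default <- default_parameters()

test_that("transition matrix converts published rates correctly", {
  m <- build_transition_matrix(p_default)
  expect_equal(rowSums(m), c(HD = 1, CAPD = 1, Death = 1), tolerance = 1e-15)
  expect_equal(unname(m["Death", ]), c(0, 0, 1))
  expect_equal(unname(m["HD", ]), c(0.875521, 0.006976, 0.117503),
               tolerance = 1e-6)
  expect_equal(unname(m["CAPD", ]), c(0.064805, 0.809785, 0.125410),
               tolerance = 1e-5)

  zero <- build_transition_matrix(
    tibble::tibble(from = c("HD", "CAPD"), to = c("CAPD", "HD"),
                   rate = c(0, 0)))
  expect_equal(unname(zero), diag(3))

  expect_error(
    build_transition_matrix(
      tibble::tibble(from = c("HD", "HD"), to = c("CAPD", "Death"),
                     rate = c(5, 5))),
    "HD", class = "dialcea_validation_error")
})

test_that("a lossless cohort accrues exactly the horizon", {
  m <- build_transition_matrix(
    tibble::tibble(from = "HD", to = "Death", rate = 0))
  res <- run_cohort(c(HD = 1, CAPD = 0), m,
                    costs = c(HD = 1000, CAPD = 0),
                    utilities = c(HD = 1, CAPD = 1),
                    n_cycles = 5, discount_rate = 0)
  expect_equal(res$totals$ly, 5)
  expect_equal(res$totals$qaly, 5)
  expect_equal(res$totals$cost, 5000)
})

test_that("certain first-cycle death yields half a life year", {
  m <- matrix(c(0, 0, 1, 0, 1, 0, 0, 0, 1), 3, byrow = TRUE,
              dimnames = list(health_states, health_states))
  res <- run_cohort(c(HD = 1, CAPD = 0), m,
                    costs = c(HD = 100, CAPD = 0),
                    utilities = c(HD = 1, CAPD = 1),
                    n_cycles = 5, discount_rate = 0)
  expect_equal(res$totals$ly, 0.5)
  expect_equal(res$totals$cost, 50)
})

test_that("cohort totals match the matrix-power oracle on random models", {
  set.seed(7)
  costs <- c(HD = 39790.58, CAPD = 37576.03)
  utils <- c(HD = 0.854, CAPD = 0.905)
  for (i in 1:100) {
    tpm <- random_tpm()
    init <- random_init()
    d <- stats::runif(1, 0, 0.1)
    res <- run_cohort(init, tpm, costs, utils, n_cycles = 5,
                      discount_rate = d)
    oracle <- markov_oracle(init, tpm, costs, utils, 5,
                            discount_rate = d)
    for (f in names(oracle)) {
      expect_equal(res$totals[[f]], oracle[[f]],
                   tolerance = 1e-10, label = f)
    }
  }
})

test_that("occupancy is conserved and death is monotone", {
  set.seed(8)
  for (i in 1:25) {
    res <- run_cohort(random_init(), random_tpm(),
                      costs = c(HD = 1, CAPD = 1),
                      utilities = c(HD = 0.9, CAPD = 0.9),
                      n_cycles = 10)
    occ <- res$trace[, c("HD", "CAPD", "Death")]
    expect_true(all(abs(rowSums(occ) - 1) < 1e-12))
    expect_true(all(diff(res$trace$Death) >= -1e-15))
    expect_true(all(diff(res$trace$HD + res$trace$CAPD) <= 1e-15))
    expect_lte(res$totals$ly, 10)
  }
})

test_that("discounted totals converge to undiscounted as the rate vanishes", {
  m <- build_transition_matrix(p_default)
  res <- run_cohort(c(HD = 0.6, CAPD = 0.4), m, params = p_default,
                    discount_rate = 1e-12)
  expect_equal(res$totals$disc_cost, res$totals$cost, tolerance = 1e-9)
  expect_equal(res$totals$disc_qaly, res$totals$qaly, tolerance = 1e-9)
})

test_that("half-timing discounting lies between none and end-of-cycle", {
  m <- build_transition_matrix(p_default)
  args <- list(init = c(HD = 0.6, CAPD = 0.4), tpm = m, params = p_default,
               discount_rate = 0.03)
  end <- do.call(run_cohort, c(args, discount_timing = "end"))
  half <- do.call(run_cohort, c(args, discount_timing = "half"))
  expect_gt(half$totals$disc_cost, end$totals$disc_cost)
  expect_lt(half$totals$disc_cost, end$totals$cost)
})

test_that("scenario mixing is exactly linear in the initial vector", {
  m <- build_transition_matrix(p_default)
  args <- list(tpm = m, params = p_default,
               discount_rate = p_default$settings$discount_rate)
  hd <- do.call(run_cohort, c(list(init = c(HD = 1, CAPD = 0)), args))
  capd <- do.call(run_cohort, c(list(init = c(HD = 0, CAPD = 1)), args))

  expect_equal(weighted_strategy_result(hd, capd,
                                        c(HD = 1, CAPD = 0))$totals,
               hd$totals, tolerance = 1e-15)

  half <- weighted_strategy_result(hd, capd, c(HD = 0.5, CAPD = 0.5))
  expect_equal(half$totals$qaly,
               (hd$totals$qaly + capd$totals$qaly) / 2, tolerance = 1e-15)

  mixed <- weighted_strategy_result(hd, capd, c(HD = 0.6, CAPD = 0.4))
  direct <- do.call(run_cohort,
                    c(list(init = c(HD = 0.6, CAPD = 0.4)), args))
  for (f in names(mixed$totals)) {
    expect_equal(mixed$totals[[f]], direct$totals[[f]], tolerance = 1e-12)
  }
})

test_that("mixing results from different settings is refused", {
  m <- build_transition_matrix(p_default)
  a <- run_cohort(c(HD = 1, CAPD = 0), m, params = p_default,
                  discount_rate = 0.03)
  b <- run_cohort(c(HD = 0, CAPD = 1), m, params = p_default,
                  discount_rate = 0.05)
  expect_error(weighted_strategy_result(a, b, c(HD = 0.5, CAPD = 0.5)),
               "settings", class = "dialcea_input_error")
})

test_that("degenerate or malformed inputs are rejected", {
  m <- build_transition_matrix(p_default)
  expect_error(run_cohort(c(HD = 0.7, CAPD = 0.4), m, params = p_default),
               "sum to 1", class = "dialcea_validation_error")
  bad <- m
  bad[1, 1] <- bad[1, 1] + 0.2
  expect_error(run_cohort(c(HD = 1, CAPD = 0), bad, params = p_default),
               "stochastic", class = "dialcea_validation_error")
})

test_that("tidy and glance expose the trace and totals", {
  res <- run_cohort(c(HD = 0.6, CAPD = 0.4),
                    build_transition_matrix(p_default),
                    params = p_default, scenario = "base_case")
  tr <- tidy(res)
  expect_equal(nrow(tr), p_default$settings$n_cycles + 1)
  expect_true(all(c("HD", "CAPD", "Death", "disc_cost") %in% names(tr)))
  g <- glance(res)
  expect_equal(g$scenario, "base_case")
  expect_lt(g$disc_cost, g$cost)
  expect_equal(g$ly, sum(tr$cycle_ly))
})
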