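mk_records <- function(months, events, start = as.Date("2012-01-01")) {
  tibble::tibble(
    patient_id = sprintf("P%02d", seq_along(months)),
    first_modality = "HD",
    start_date = start,
    terminal_event = ifelse(events == 1, "death", "administrative_censor"),
    terminal_date = start + round(months * 365.25 / 12)
  )
}

test_that("product-limit estimate matches a hand computation", {
  # event at month 1, censoring at month 2, event at month 3
  km <- km_estimate(mk_records(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(km$survival[1], 1)
  expect_equal(km$survival[km$n_event == 1],
               c(2 / 3, 0), tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 0))
})

test_that("an all-censored cohort gives a flat curve with a warning", {
  expect_warning(
    km <- km_estimate(mk_records(c(5, 8, 12), c(0, 0, 0))),
    "censored")
  expect_true(all(km$survival == 1))
})

test_that("km_estimate agrees exactly with brute-force enumeration", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(3:20, 1)
    months <- sample(1:36, n, replace = TRUE)
    events <- stats::rbinom(n, 1, 0.6)
    if (sum(events) == 0) events[1] <- 1
    rec <- mk_records(months, events)
    km <- km_estimate(rec)
    oracle <- km_oracle(
      as.numeric(rec$terminal_date - rec$start_date) / (365.25 / 12),
      events)
    # compare at each observed event time
    for (j in seq_along(oracle$time)) {
      got <- km$survival[which.min(abs(km$time - oracle$time[j]))]
      expect_equal(got, oracle$surv[j], tolerance = 1e-12)
    }
  }
})

test_that("adding a censored record never lowers the survivor function", {
  # the extra censored patient enlarges every earlier risk set, so each
  # product-limit factor (1 - d/n) can only grow
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    months <- sample(1:24, n, replace = TRUE)
    events <- stats::rbinom(n, 1, 0.7)
    if (sum(events) == 0) events[1] <- 1
    base <- mk_records(months, events)
    extra <- dplyr::bind_rows(base, mk_records(sample(1:30, 1), 0)[1, ])
    km1 <- km_estimate(base)
    km2 <- km_estimate(extra)
    for (t in sort(unique(months[events == 1]))) {
      s1 <- km1$survival[max(which(km1$time <= t + 0.01))]
      s2 <- km2$survival[max(which(km2$time <= t + 0.01))]
      expect_gte(s2, s1 - 1e-12)
    }
  }
})

test_that("ITT attribution keeps deaths after a switch with first modality", {
  reg <- generate_registry(400, seed = 11,
                           switch_hazard = c(HD_CAPD = 0.3, CAPD_HD = 0.5))
  rec <- collapse_registry(reg)
  expect_true(any(rec$n_switches > 0 & rec$terminal_event == "death"))
  # km_estimate consumes the collapsed record: the switchers' deaths count
  km <- km_estimate(rec)
  expect_equal(sum(km$n_event), sum(rec$terminal_event == "death"))
})

test_that("restricted mean survival reproduces simple areas", {
  flat <- structure(
    tibble::tibble(time = c(0, 60), n_risk = c(5, 5), n_event = c(0, 0),
                   n_censor = c(0, 5), survival = c(1, 1),
                   std_err = c(0, 0)),
    class = c("km_curve", class(tibble::tibble())))
  expect_equal(restricted_mean_survival(flat, 5), 5)

  rect <- structure(
    tibble::tibble(time = c(0, 12), n_risk = c(5, 5), n_event = c(0, 5),
                   n_censor = c(0, 0), survival = c(1, 0),
                   std_err = c(0, 0)),
    class = c("km_curve", class(tibble::tibble())))
  expect_equal(restricted_mean_survival(rect, 5), 1)
  expect_warning(restricted_mean_survival(rect[1, ], 5), "beyond")
})

test_that("KM life years recover the exponential closed form", {
  # pure death process at 0.25/yr; RMST over 5y = (1 - e^-1.25)/0.25
  reg <- generate_registry(
    5000, seed = 3,
    death_hazard = c(HD = 0.25, CAPD = 0.25),
    switch_hazard = c(HD_CAPD = 0, CAPD_HD = 0),
    censor_hazards = c(transplant = 0, recovery = 0,
                       lost_to_follow_up = 0))
  km <- km_estimate(collapse_registry(reg))
  rmst <- restricted_mean_survival(km, 5)
  expect_equal(rmst, (1 - exp(-1.25)) / 0.25, tolerance = 0.02)
})

test_that("annual event rates follow the mid-year convention", {
  expect_equal(annual_event_rate(100, 800)$rate, 0.125)
  expect_equal(annual_event_rate(0, 500)$rate, 0)
  multi <- annual_event_rate(
    c(0.12, 0.13, 0.12, 0.13, 0.125) * 1000, rep(1000, 5))
  expect_equal(multi$rate, 0.125)
  expect_equal(multi$n_years, 5L)
  expect_error(annual_event_rate(5, 0), "midyear_population")
})

test_that("rate-to-probability conversion is exact and monotone", {
  expect_equal(rate_to_probability(0, 1), 0)
  expect_equal(rate_to_probability(0.134, 1), 1 - exp(-0.134))
  expect_equal(rate_to_probability(0.134, 1), 0.125410, tolerance = 1e-5)
  expect_equal(rate_to_probability(0.125, 1), 0.117503, tolerance = 1e-5)
  expect_error(rate_to_probability(-0.1), "rate")

  r <- seq(0, 2, by = 0.01)
  expect_true(all(diff(rate_to_probability(r, 1)) > 0))
  small <- 10^seq(-7, -3.1, by = 0.5)
  expect_true(all(abs(rate_to_probability(small, 1) - small) / small < 1e-3))
})

test_that("registry rate estimation supports both attribution conventions", {
  reg <- generate_registry(2000, seed = 5)
  cur <- estimate_annual_rates(reg, attribution = "current")
  itt <- estimate_annual_rates(reg, attribution = "first")
  expect_setequal(paste(cur$from, cur$to),
                  c("HD CAPD", "HD Death", "CAPD HD", "CAPD Death"))
  expect_true(all(cur$rate >= 0))
  # switches counted by direction are identical under both conventions
  expect_equal(cur$events[cur$to != "Death"], itt$events[itt$to != "Death"])
  # CAPD -> HD switching dwarfs HD -> CAPD, as generated
  expect_gt(cur$rate[cur$from == "CAPD" & cur$to == "HD"],
            cur$rate[cur$from == "HD" & cur$to == "CAPD"])
})
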