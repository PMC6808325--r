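# Independent oracles, kept deliberately naive and separate from the
# package implementation paths.

# Product-limit estimator by direct enumeration of the formula:
# S(t) = prod over event times u <= t of (1 - d_u / n_u),
# with events processed before censorings at tied times.
km_oracle <- function(time, status) {
  ts <- sort(unique(time[status == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & status == 1)
    s <- s * (1 - d / n_at_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv,
       S = function(t) {
         if (length(ts) == 0 || t < ts[1]) return(1)
         surv[max(which(ts <= t))]
       })
}

# Brute-force cohort totals by explicit matrix powers: occupancy after k
# cycles is init %*% tpm^k, each cycle contributes the trapezoid of its
# boundary occupancies, discounted at the cycle's end (or midpoint).
markov_oracle <- function(init, tpm, costs, utilities, n_cycles,
                          cycle_length = 1, discount_rate = 0,
                          discount_timing = "end") {
  mat_pow <- function(m, k) {
    out <- diag(nrow(m))
    for (i in seq_len(k)) out <- out %*% m
    out
  }
  v0 <- c(init[["HD"]], init[["CAPD"]], 0)
  pay_c <- c(costs[["HD"]], costs[["CAPD"]], 0)
  pay_u <- c(utilities[["HD"]], utilities[["CAPD"]], 0)
  pay_l <- c(1, 1, 0)
  tot <- c(cost = 0, ly = 0, qaly = 0,
           disc_cost = 0, disc_ly = 0, disc_qaly = 0)
  for (k in seq_len(n_cycles)) {
    a <- as.numeric(v0 %*% mat_pow(tpm, k - 1))
    b <- as.numeric(v0 %*% mat_pow(tpm, k))
    mid <- (a + b) / 2
    expo <- if (discount_timing == "end") k else k - 0.5
    df <- (1 + discount_rate)^(-expo * cycle_length)
    contrib <- cycle_length * c(sum(mid * pay_c), sum(mid * pay_l),
                                sum(mid * pay_u))
    tot <- tot + c(contrib, contrib * df)
  }
  as.list(tot)
}

# random valid transition structure: exits drawn then scaled below 1
random_tpm <- function() {
  m <- matrix(0, 3, 3, dimnames = list(health_states, health_states))
  m["Death", "Death"] <- 1
  for (s in c("HD", "CAPD")) {
    exits <- stats::runif(2) * stats::runif(1, 0.1, 0.95) / 2
    others <- setdiff(health_states, s)
    m[s, others] <- exits
    m[s, s] <- 1 - sum(exits)
  }
  m
}

random_init <- function() {
  h <- stats::runif(1)
  c(HD = h, CAPD = 1 - h)
}

# collapse every (low, high) range onto the mean so that every fitted
# distribution is degenerate, and align the modality totals with the
# component sums (the printed totals differ by the 0.01 RM rounding gap)
degenerate_params <- function(params = default_parameters()) {
  sums <- tapply(params$costs$mean, params$costs$modality, sum)
  params$cost_totals$mean <-
    unname(sums[params$cost_totals$modality])
  params$costs$low <- params$costs$mean
  params$costs$high <- params$costs$mean
  params$cost_totals$low <- params$cost_totals$mean
  params$cost_totals$high <- params$cost_totals$mean
  params$utilities$low <- params$utilities$mean
  params$utilities$high <- params$utilities$mean
  params$rates$low <- params$rates$mean
  params$rates$high <- params$rates$mean
  params
}
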