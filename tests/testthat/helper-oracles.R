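# Independent brute-force oracles, written against the textbook
# definitions with plain loops. They share no code with the package.

# Kaplan-Meier by direct risk-set counting: returns a function of t
brute_km <- function(time, event, w = rep(1, length(time))) {
  tk <- sort(unique(time[event != 0]))
  s <- 1
  surv <- numeric(length(tk))
  for (k in seq_along(tk)) {
    at_risk <- sum(w[time >= tk[k]])
    died <- sum(w[event != 0 & time == tk[k]])
    s <- s * (1 - died / at_risk)
    surv[k] <- s
  }
  function(t) {
    vapply(t, function(tt) {
      i <- sum(tk <= tt)
      if (i == 0) 1 else surv[i]
    }, numeric(1))
  }
}

# Aalen-Johansen CIF for one cause by direct counting (product-limit
# overall survival); cause codes: 0 censor, others events
brute_cif <- function(time, event, cause, w = rep(1, length(time))) {
  tk <- sort(unique(time[event != 0]))
  s_lag <- 1
  f <- 0
  fk <- numeric(length(tk))
  for (k in seq_along(tk)) {
    at_risk <- sum(w[time >= tk[k]])
    d_all <- sum(w[event != 0 & time == tk[k]])
    d_j <- sum(w[event == cause & time == tk[k]])
    f <- f + s_lag * d_j / at_risk
    fk[k] <- f
    s_lag <- s_lag * (1 - d_all / at_risk)
  }
  function(t) {
    vapply(t, function(tt) {
      i <- sum(tk <= tt)
      if (i == 0) 0 else fk[i]
    }, numeric(1))
  }
}

# numerical integral of a function on [0, horizon] by a fine midpoint grid
grid_integral <- function(f, horizon, n_grid = 2e5) {
  dt <- horizon / n_grid
  mid <- (seq_len(n_grid) - 0.5) * dt
  sum(f(mid)) * dt
}

# random small cohort with two causes, ties, and weights
random_cohort <- function(n, max_code = 2) {
  # coarse grid of positive times so ties are common
  time <- sample(seq(0.1, 5, by = 0.1), n, replace = TRUE)
  event <- sample(0:max_code, n, replace = TRUE)
  exposure <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
  as_cohort(tibble::tibble(exposure = exposure, time = time, event = event))
}

random_weights <- function(n) round(runif(n, 0.2, 3), 2)

# Cox partial log-likelihood for a single binary covariate, Breslow ties,
# by direct summation
brute_cox_loglik <- function(beta, time, status, x, w = rep(1, length(time))) {
  ll <- 0
  for (tt in sort(unique(time[status == 1]))) {
    d <- status == 1 & time == tt
    at_risk <- time >= tt
    ll <- ll + sum(w[d] * beta * x[d]) -
      sum(w[d]) * log(sum(w[at_risk] * exp(beta * x[at_risk])))
  }
  ll
}
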