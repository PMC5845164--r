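two_group_cohort <- function(seed = 13, n = 120) {
  withr::local_seed(seed)
  as_cohort(tibble::tibble(
    exposure = rep_len(c(0, 1), n),
    time = sample(seq(0.2, 5, by = 0.2), n, replace = TRUE),
    event = sample(0:2, n, replace = TRUE)
  ))
}

test_that("RR and RD curves are null for identical groups and obey arithmetic", {
  s <- step_curve(c(0, 1, 2), c(1, 0.8, 0.5), kind = "survival",
                  horizon = 3)
  rr <- risk_ratio_curve(s, s)
  expect_true(all(rr$estimate[rr$defined] == 1))
  expect_false(rr$defined[rr$time == 0])   # both risks zero at origin

  rd <- risk_difference_curve(s, s)
  expect_true(all(rd$estimate == 0))

  s1 <- step_curve(c(0, 1), c(1, 0.8), kind = "survival", horizon = 2)
  s0 <- step_curve(c(0, 1), c(1, 0.9), kind = "survival", horizon = 2)
  expect_equal(risk_ratio_curve(s1, s0)$estimate[2], 2.0)
  expect_equal(risk_difference_curve(s1, s0)$estimate[2], 0.1)
})

test_that("RD(t) = (1 - S0(t)) * (RR(t) - 1) wherever RR is defined", {
  cohort <- two_group_cohort()
  g <- split(seq_len(nrow(cohort)), cohort$exposure)
  rk1 <- risk_table(cohort[g[["1"]], ], horizon = 4)
  rk0 <- risk_table(cohort[g[["0"]], ], horizon = 4)
  s1 <- weighted_km(rk1); s0 <- weighted_km(rk0)
  rr <- risk_ratio_curve(s1, s0)
  rd <- risk_difference_curve(s1, s0)
  ok <- rr$defined
  lhs <- rd$estimate[ok]
  rhs <- (1 - step_value(s0, rr$time[ok])) * (rr$estimate[ok] - 1)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("pointwise hazard ratios: identical groups give 1, doubled hazards give 2", {
  cohort <- two_group_cohort(seed = 21)
  rk <- risk_table(cohort, horizon = 4)
  hr_same <- hazard_ratio_curve(rk, rk, "all")
  expect_true(all(hr_same$estimate[hr_same$defined] == 1))

  # paired groups with identical risk sets (n = 100, 80, 60 at t = 1, 2, 3)
  # but group 1 suffers exactly twice the events: hazards 0.10 vs 0.05
  make_group <- function(d_events, x) {
    cens <- c(20 - d_events[1], 20 - d_events[2])
    tibble::tibble(
      exposure = x,
      time = c(rep(1, d_events[1]), rep(1.5, cens[1]),
               rep(2, d_events[2]), rep(2.5, cens[2]),
               rep(3, d_events[3]),
               rep(3.5, 60 - d_events[3])),
      event = c(rep(1L, d_events[1]), rep(0L, cens[1]),
                rep(1L, d_events[2]), rep(0L, cens[2]),
                rep(1L, d_events[3]),
                rep(0L, 60 - d_events[3])))
  }
  rk0 <- risk_table(make_group(c(5, 4, 3), 0), horizon = 3)
  rk1 <- risk_table(make_group(c(10, 8, 6), 1), horizon = 3)
  expect_equal(rk0$n_risk, c(100, 80, 60))
  expect_equal(rk1$n_risk, c(100, 80, 60))
  hr <- hazard_ratio_curve(rk1, rk0, "event")
  expect_equal(hr$estimate[hr$defined], rep(2, 3), tolerance = 1e-12)
})

test_that("subdistribution and cause-specific curves coincide without competing events", {
  cohort <- two_group_cohort(seed = 34)
  cohort$event[cohort$event == 2L] <- 1L
  g <- split(seq_len(nrow(cohort)), cohort$exposure)
  rk1 <- risk_table(cohort[g[["1"]], ], horizon = 4)
  rk0 <- risk_table(cohort[g[["0"]], ], horizon = 4)
  cs <- hazard_ratio_curve(rk1, rk0, "event")
  sd <- hazard_ratio_curve(rk1, rk0, "subdistribution")
  expect_equal(sd$time, cs$time)
  # without competing events both risk sets shrink identically, but the
  # subdistribution hazard divides by 1 - F(t-) instead of using n(t);
  # for pure event data the two discrete hazards are equal
  expect_equal(sd$estimate, cs$estimate, tolerance = 1e-10)
})

test_that("subdistribution HR curve ignores censoring-time reclassification beyond the horizon", {
  cohort <- two_group_cohort(seed = 55)
  g <- split(seq_len(nrow(cohort)), cohort$exposure)
  horizon <- 3
  shifted <- cohort
  late <- shifted$time > horizon
  shifted$time[late] <- shifted$time[late] + 5   # still beyond horizon
  rk1a <- risk_table(cohort[g[["1"]], ], horizon = horizon)
  rk0a <- risk_table(cohort[g[["0"]], ], horizon = horizon)
  rk1b <- risk_table(shifted[g[["1"]], ], horizon = horizon)
  rk0b <- risk_table(shifted[g[["0"]], ], horizon = horizon)
  a <- hazard_ratio_curve(rk1a, rk0a, "subdistribution")
  b <- hazard_ratio_curve(rk1b, rk0b, "subdistribution")
  expect_equal(a$time, b$time)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
})

test_that("weighted Cox matches a brute-force partial-likelihood oracle", {
  # n = 8 toy data, distinct times
  cohort <- as_cohort(tibble::tibble(
    exposure = c(1, 0, 1, 0, 1, 0, 1, 0),
    time = c(1, 2, 3, 4, 5, 6, 7, 8),
    event = c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L)))
  fit <- weighted_cox_binary(cohort, cause = "all")
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, brute_cox_loglik, numeric(1),
               time = cohort$time, status = as.integer(cohort$event != 0),
               x = cohort$exposure)
  expect_equal(fit$log_hr, grid[which.max(ll)], tolerance = 1e-3)
  expect_equal(fit$hr, exp(fit$log_hr))

  # weighted fit also maximizes the weighted partial likelihood
  w <- c(2, 1, 1, 0.5, 1, 1.5, 1, 1)
  fit_w <- weighted_cox_binary(cohort, weights = w, cause = "all")
  ll_w <- vapply(grid, brute_cox_loglik, numeric(1),
                 time = cohort$time, status = as.integer(cohort$event != 0),
                 x = cohort$exposure, w = w)
  expect_equal(fit_w$log_hr, grid[which.max(ll_w)], tolerance = 1e-3)
})

test_that("exhaustive small-case agreement with the partial-likelihood oracle", {
  withr::local_seed(77)
  grid <- seq(-4, 4, by = 5e-4)
  done <- 0
  while (done < 8) {
    n <- 10
    cohort <- tryCatch(random_cohort(n, max_code = 1), error = function(e) NULL)
    if (is.null(cohort)) next
    if (length(unique(cohort$time)) < n) next          # no ties
    ev1 <- sum(cohort$event != 0 & cohort$exposure == 1)
    ev0 <- sum(cohort$event != 0 & cohort$exposure == 0)
    if (ev1 == 0 || ev0 == 0) next
    fit <- weighted_cox_binary(cohort, cause = "all")
    ll <- vapply(grid, brute_cox_loglik, numeric(1),
                 time = cohort$time, status = as.integer(cohort$event != 0),
                 x = cohort$exposure)
    best <- grid[which.max(ll)]
    if (abs(best) > 3.5) next                          # interior optimum only
    expect_equal(fit$log_hr, best, tolerance = 2e-3)
    done <- done + 1
  }
})

test_that("symmetric groups give log HR 0 and permuted labels are null on average", {
  base <- tibble::tibble(time = c(1, 2, 3, 4, 5), event = c(1L, 1L, 0L, 1L, 0L))
  cohort <- as_cohort(dplyr::bind_rows(
    dplyr::mutate(base, exposure = 0), dplyr::mutate(base, exposure = 1)))
  fit <- weighted_cox_binary(cohort, cause = "all")
  expect_equal(fit$log_hr, 0, tolerance = 1e-8)

  withr::local_seed(123)
  n <- 60
  big <- as_cohort(tibble::tibble(
    exposure = rep_len(c(0, 1), n),
    time = rexp(n, 0.5), event = rbinom(n, 1, 0.7)))
  perms <- replicate(200, {
    d <- big
    d$exposure <- sample(d$exposure)
    tryCatch(weighted_cox_binary(d, cause = "all")$log_hr,
             error = function(e) NA_real_)
  })
  expect_lt(abs(mean(perms, na.rm = TRUE)),
            3 * sd(perms, na.rm = TRUE) / sqrt(sum(!is.na(perms))) + 0.02)
})

test_that("monotone likelihood (all events in one group) errors", {
  cohort <- as_cohort(tibble::tibble(
    exposure = rep_len(c(0, 1), 10),
    time = 1:10,
    event = as.integer(rep_len(c(0, 1), 10))))
  expect_error(weighted_cox_binary(cohort, cause = "all"),
               "monotone")
})

test_that("weighted Cox agrees with survival::coxph cross-check", {
  cohort <- two_group_cohort(seed = 41, n = 200)
  wm_w <- runif(nrow(cohort), 0.5, 2)
  fit <- weighted_cox_binary(cohort, weights = wm_w, cause = "event")
  ref <- survival::coxph(
    survival::Surv(time, event == 1) ~ exposure,
    data = as.data.frame(cohort), weights = wm_w, ties = "breslow")
  expect_equal(fit$log_hr, unname(coef(ref)), tolerance = 1e-8)
})
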