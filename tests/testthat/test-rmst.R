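test_that("step-curve integration is exact, bounded, and refuses to extrapolate", {
  flat <- step_curve(c(0, 5), c(1, 1), kind = "survival", horizon = 5)
  expect_equal(integrate_step_curve(flat, 5), 5)
  expect_equal(integrate_step_curve(flat, 0), 0)

  s <- step_curve(c(0, 1, 3), c(1, 0.5, 0.25), kind = "survival",
                  horizon = 5)
  expect_equal(integrate_step_curve(s, 5), 2.5)
  # independent oracle: fine-grid numerical integration
  expect_equal(integrate_step_curve(s, 5),
               grid_integral(function(t) step_value(s, t), 5),
               tolerance = 1e-4)
  expect_error(integrate_step_curve(s, 6), "beyond the curve")
})

test_that("integration is linear in the curve values on shared knots", {
  withr::local_seed(8)
  knots <- c(0, sort(runif(6, 0.1, 4)))
  v1 <- sort(runif(7, 0, 1), decreasing = TRUE); v1[1] <- 1
  v2 <- sort(runif(7, 0, 1), decreasing = TRUE); v2[1] <- 1
  s1 <- step_curve(knots, v1, kind = "survival", horizon = 4)
  s2 <- step_curve(knots, v2, kind = "survival", horizon = 4)
  a <- 0.3; b <- 0.7
  expect_equal(
    a * integrate_step_curve(s1, 4) + b * integrate_step_curve(s2, 4),
    sum((a * v1 + b * v2) * diff(c(knots, 4))),
    tolerance = 1e-12
  )
})

test_that("RMST via the weighted KM matches hand and closed-form values", {
  cohort <- as_cohort(tibble::tibble(exposure = c(0, 1, 0, 1),
                                     time = 1:4, event = c(1L, 1L, 0L, 0L)))
  est <- rmst_survival(cohort, 4, by_exposure = FALSE)
  expect_equal(est$estimate, 2.75)
  expect_equal(est$group, "overall")

  # no events before t*: RMST = t*
  cens <- as_cohort(tibble::tibble(exposure = c(0, 1), time = c(3, 4),
                                   event = 0L))
  expect_equal(rmst_survival(cens, 3, by_exposure = FALSE)$estimate, 3)

  # large-sample exponential: RMST(5) -> (1 - e^{-1}) / 0.2
  withr::local_seed(20)
  n <- 100000
  tt <- rexp(n, 0.2)
  exp_cohort <- as_cohort(tibble::tibble(
    exposure = rep_len(c(0, 1), n), time = tt, event = 1L))
  est <- rmst_survival(exp_cohort, 5, by_exposure = FALSE)
  expect_lt(abs(est$estimate - (1 - exp(-1)) / 0.2), 0.02)
})

test_that("event-free RMST reproduces the worked example and its identity", {
  cohort <- as_cohort(tibble::tibble(exposure = c(0, 1, 0, 1), time = 1:4,
                                     event = c(1L, 2L, 0L, 0L)))
  rk <- risk_table(cohort, horizon = 4)
  a1 <- 4 - integrate_step_curve(weighted_cif(rk, "event"), 4)
  l2 <- integrate_step_curve(weighted_cif(rk, "competing"), 4)
  expect_equal(a1, 3.25)
  expect_equal(l2, 0.5)

  est <- event_free_rmst(cohort, 4, by_exposure = FALSE)
  expect_equal(est$estimate, 2.75)
  # identity: equals the integral of overall event-free survival
  overall <- integrate_step_curve(weighted_km(rk), 4)
  expect_equal(est$estimate, overall, tolerance = 1e-12)

  # no competing events observed: reduces to RMST to event j
  single <- as_cohort(tibble::tibble(exposure = c(0, 1, 0, 1), time = 1:4,
                                     event = c(1L, 1L, 0L, 0L)))
  expect_equal(event_free_rmst(single, 4, by_exposure = FALSE)$estimate,
               rmst_survival(single, 4, by_exposure = FALSE)$estimate)
})

test_that("event-free RMST equals the integral identity on random cohorts", {
  withr::local_seed(99)
  for (rep in 1:30) {
    n <- sample(5:25, 1)
    cohort <- random_cohort(n)
    w <- random_weights(n)
    horizon <- max(cohort$time)
    est <- event_free_rmst(cohort, horizon, w, by_exposure = FALSE)
    rk <- risk_table(cohort, w, horizon = horizon)
    f1 <- weighted_cif(rk, "event")
    f2 <- weighted_cif(rk, "competing")
    at <- rk$time
    direct <- sum((1 - step_value(f1, c(0, at[-length(at)])) -
                     step_value(f2, c(0, at[-length(at)]))) *
                    diff(c(0, at)))
    expect_equal(est$estimate, direct, tolerance = 1e-12)
  }
})

test_that("RMST contrasts compute differences and ratios with guards", {
  a <- rmst_estimate(4.51, 5, group = "1")
  b <- rmst_estimate(4.70, 5, group = "0")
  expect_equal(rmst_contrast(a, b)$estimate, -0.19)
  expect_equal(rmst_contrast(rmst_estimate(2.5, 5, group = "1"),
                             rmst_estimate(2.0, 5, group = "0"),
                             scale = "ratio")$estimate, 1.25)
  expect_equal(rmst_contrast(a, a)$estimate, 0)
  expect_equal(rmst_contrast(a, a, scale = "ratio")$estimate, 1)
  expect_error(rmst_contrast(a, rmst_estimate(3.9, 4, group = "0")),
               "different horizons")
  expect_error(rmst_contrast(a, rmst_estimate(0, 5, group = "0"),
                             scale = "ratio"), "zero")
  # two-group table form
  both <- dplyr::bind_rows(a, b)
  class(both) <- class(a)
  expect_equal(rmst_contrast(both)$estimate, -0.19)
})

test_that("RMST is monotone and bounded in the horizon", {
  withr::local_seed(3)
  cohort <- random_cohort(40)
  w <- random_weights(40)
  horizons <- sort(unique(cohort$time[cohort$time <= max(cohort$time)]))
  vals <- vapply(horizons, function(h) {
    rmst_survival(cohort, h, w, by_exposure = FALSE)$estimate
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  expect_true(all(vals <= horizons + 1e-12))
  expect_true(all(vals >= 0))
})

test_that("difference curve is zero for identical groups, single point consistent", {
  base <- tibble::tibble(time = c(1, 2, 3, 4), event = c(1L, 1L, 0L, 0L))
  mirrored <- as_cohort(dplyr::bind_rows(
    dplyr::mutate(base, exposure = 0), dplyr::mutate(base, exposure = 1)
  ))
  curve <- rmst_difference_curve(mirrored)
  expect_true(all(abs(curve$estimate) < 1e-12))

  one <- rmst_difference_curve(mirrored, horizons = 3)
  est <- rmst_survival(mirrored, 3)
  expect_equal(one$estimate, rmst_contrast(est)$estimate)
})

test_that("dominating survival gives a non-negative, non-decreasing difference curve", {
  # group 1 events strictly later than group 0: S_1 dominates S_0
  g0 <- tibble::tibble(exposure = 0, time = c(1, 1.5, 2, 2.5, 6),
                       event = c(1L, 1L, 1L, 1L, 0L))
  g1 <- tibble::tibble(exposure = 1, time = c(3, 3.5, 4, 4.5, 6),
                       event = c(1L, 1L, 1L, 1L, 0L))
  cohort <- as_cohort(dplyr::bind_rows(g0, g1))
  curve <- rmst_difference_curve(cohort, horizons = c(1, 2, 3, 4, 5))
  expect_true(all(curve$estimate >= 0))
  expect_true(all(diff(curve$estimate) >= -1e-12))
})
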