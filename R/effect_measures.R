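#' Pointwise risk-ratio and risk-difference curves
#'
#' Comparator estimands computed from two weighted survival curves on the
#' union of their knots:
#' \deqn{RR(t) = \frac{1 - S_1(t)}{1 - S_0(t)}, \qquad
#'       RD(t) = (1 - S_1(t)) - (1 - S_0(t)).}
#' The risk ratio is undefined while both risks are zero (and whenever the
#' reference risk is zero); undefined points are carried as `NA`, never
#' interpolated.
#'
#' @param s1,s0 Survival [step_curve()]s for the index (exposed) and
#'   reference group.
#' @return A tibble of class `estimand_curve` with columns `time`,
#'   `estimate`, `defined`, and attributes `estimand` and `null_value`.
#' @export
risk_ratio_curve <- function(s1, s0) {
  grid <- curve_union_grid(s1, s0)
  r1 <- 1 - step_value(s1, grid)
  r0 <- 1 - step_value(s0, grid)
  est <- ifelse(r0 > 0, r1 / r0, NA_real_)
  estimand_curve(grid, est, "rr", null_value = 1)
}

#' @rdname risk_ratio_curve
#' @export
risk_difference_curve <- function(s1, s0) {
  grid <- curve_union_grid(s1, s0)
  est <- (1 - step_value(s1, grid)) - (1 - step_value(s0, grid))
  estimand_curve(grid, est, "rd", null_value = 0)
}

curve_union_grid <- function(s1, s0) {
  stopifnot(inherits(s1, "step_curve"), inherits(s0, "step_curve"))
  sort(unique(c(s1$time, s0$time)))
}

estimand_curve <- function(time, estimate, estimand, null_value) {
  out <- tibble::tibble(time = time, estimate = estimate,
                        defined = is.finite(estimate))
  attr(out, "estimand") <- estimand
  attr(out, "null_value") <- null_value
  class(out) <- c("estimand_curve", class(tibble::tibble()))
  out
}

#' Pointwise hazard-ratio curve between two groups
#'
#' Ratio of discrete hazards between two weighted risk tables at each
#' event time.
#'
#' * `cause = "all"`: all-cause discrete hazard
#'   \eqn{d^{\hat W}(t_k)/n^{\hat W}(t_k)} in each group.
#' * `cause = "event"` / `"competing"`: cause-specific discrete hazard
#'   for that event type.
#' * `cause = "subdistribution"`: discrete subdistribution hazard for the
#'   event of interest, \eqn{\Delta \hat F_j(t_k) / (1 - \hat F_j(t_k^-))},
#'   whose risk set conceptually retains subjects after a competing event.
#'
#' The curve is evaluated on the union of both groups' event times for
#' the chosen cause; points where either group's hazard is zero or its
#' risk set is empty are flagged undefined (`NA`), matching how pointwise
#' hazard-ratio panels are plotted. With no competing events the
#' subdistribution and cause-specific curves coincide.
#'
#' @param risk1,risk0 [risk_table()]s for the index and reference group.
#' @param cause `"all"`, `"event"`, `"competing"`, or
#'   `"subdistribution"`.
#' @param mode Overall-survival form used in the subdistribution CIF.
#' @return An `estimand_curve` tibble with null value 1.
#' @export
hazard_ratio_curve <- function(risk1, risk0,
                               cause = c("all", "event", "competing",
                                         "subdistribution"),
                               mode = "product_limit") {
  cause <- match.arg(cause)
  stopifnot(inherits(risk1, "risk_table"), inherits(risk0, "risk_table"))
  h1 <- discrete_hazards(risk1, cause, mode)
  h0 <- discrete_hazards(risk0, cause, mode)
  grid <- sort(unique(c(h1$time[h1$hazard > 0], h0$time[h0$hazard > 0])))
  lookup <- function(h, t) {
    i <- match(t, h$time)
    ifelse(is.na(i), 0, h$hazard[i])
  }
  v1 <- lookup(h1, grid)
  v0 <- lookup(h0, grid)
  est <- ifelse(v0 > 0 & v1 > 0, v1 / v0, NA_real_)
  estimand_curve(grid, est, paste0("hr_", cause), null_value = 1)
}

discrete_hazards <- function(risk, cause, mode) {
  if (cause == "subdistribution") {
    f <- weighted_cif(risk, "event", mode)
    # f has knots (0, t_1, ..., t_K); increments at the risk-table times
    df <- diff(f$estimate)
    f_lag <- f$estimate[-nrow(f)]       # F_j(t_k-)
    tibble::tibble(time = f$time[-1],
                   hazard = ifelse(1 - f_lag > 0, df / (1 - f_lag), NA_real_))
  } else {
    d <- switch(cause, all = risk$d_all, event = risk$d_event,
                competing = risk$d_competing)
    tibble::tibble(time = risk$time,
                   hazard = ifelse(risk$n_risk > 0, d / risk$n_risk,
                                   NA_real_))
  }
}

#' @export
autoplot.estimand_curve <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$defined),
                  ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = attr(object, "null_value"),
                        linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time", y = attr(object, "estimand")) +
    ggplot2::theme_minimal()
}

#' Weighted Cox proportional-hazards estimate for a binary exposure
#'
#' Single-coefficient weighted Cox partial-likelihood fit (Breslow tie
#' handling) for the exposure effect on a chosen cause, the conventional
#' summary contrasted against pointwise hazard-ratio curves. Competing
#' events are treated as censored for a cause-specific fit.
#'
#' @param data A cohort tibble.
#' @param weights `NULL`, numeric vector, or [fit_stabilized_weights()]
#'   model.
#' @param coding An [event_coding()].
#' @param cause `"all"`, `"event"`, or `"competing"`: which events count
#'   as failures (the rest are censored).
#' @return A one-row tibble with `term`, `log_hr`, `hr`; the underlying
#'   [survival::coxph()] fit is attached as attribute `fit`.
#' @export
weighted_cox_binary <- function(data, weights = NULL,
                                coding = event_coding(),
                                cause = c("all", "event", "competing")) {
  cause <- match.arg(cause)
  validate_cohort(data)
  w <- resolve_weights(weights, nrow(data))
  status <- switch(cause,
    all = as.integer(data$event != coding$censor),
    event = as.integer(data$event == coding$event_of_interest),
    competing = as.integer(data$event %in% coding$competing)
  )
  by_group <- tapply(status, data$exposure, sum)
  if (any(by_group == 0)) {
    stop("monotone partial likelihood: all events of this cause fall in one ",
         "exposure group", call. = FALSE)
  }
  df <- data.frame(time = data$time, status = status,
                   exposure = data$exposure, w = w)
  fit <- survival::coxph(survival::Surv(time, status) ~ exposure,
                         data = df, weights = w, ties = "breslow",
                         robust = FALSE,
                         control = survival::coxph.control(iter.max = 100))
  log_hr <- unname(stats::coef(fit)[["exposure"]])
  if (!is.finite(log_hr) || abs(log_hr) > 15) {
    stop("weighted Cox fit did not converge to a finite exposure effect",
         call. = FALSE)
  }
  out <- tibble::tibble(term = "exposure", log_hr = log_hr,
                        hr = exp(log_hr))
  attr(out, "fit") <- fit
  out
}
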