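#' Step curves: right-continuous piecewise-constant functions of time
#'
#' All survival and cumulative-incidence estimates in this package are
#' represented as step curves: a tibble with knots `time` (starting at 0)
#' and the curve `estimate` on each interval `[t_k, t_{k+1})`. Survival
#' curves start at 1 and are non-increasing; cumulative-incidence curves
#' start at 0 and are non-decreasing.
#'
#' @param time Strictly increasing knots, starting at 0.
#' @param estimate Curve value on `[time[k], time[k+1])`.
#' @param kind `"survival"` or `"cif"`.
#' @param horizon Optional horizon attribute carried from the risk table.
#' @return A tibble of class `step_curve`.
#' @export
step_curve <- function(time, estimate, kind = c("survival", "cif"),
                       horizon = max(time)) {
  kind <- match.arg(kind)
  stopifnot(length(time) == length(estimate), length(time) >= 1)
  if (time[1] != 0) {
    time <- c(0, time)
    estimate <- c(if (kind == "survival") 1 else 0, estimate)
  }
  if (is.unsorted(time, strictly = TRUE)) {
    stop("knots must be strictly increasing", call. = FALSE)
  }
  if (any(estimate < -1e-12) || any(estimate > 1 + 1e-12)) {
    stop("step-curve values must lie in [0, 1]", call. = FALSE)
  }
  if (kind == "survival") {
    if (estimate[1] != 1) stop("survival curves must start at 1", call. = FALSE)
    if (is.unsorted(rev(estimate))) {
      stop("survival curves must be non-increasing", call. = FALSE)
    }
  } else {
    if (estimate[1] != 0) stop("CIF curves must start at 0", call. = FALSE)
    if (is.unsorted(estimate)) {
      stop("CIF curves must be non-decreasing", call. = FALSE)
    }
  }
  out <- tibble::new_tibble(
    list(time = as.numeric(time), estimate = as.numeric(estimate)),
    nrow = length(time),
    class = "step_curve"
  )
  attr(out, "kind") <- kind
  attr(out, "horizon") <- horizon
  out
}

#' Evaluate a step curve
#'
#' Right-continuous evaluation: `step_value(curve, t)` returns the value on
#' the interval containing `t`.
#'
#' @param curve A [step_curve()].
#' @param t Numeric times (must be `>= 0`).
#' @return Numeric vector of curve values.
#' @export
step_value <- function(curve, t) {
  stopifnot(inherits(curve, "step_curve"), all(t >= 0))
  curve$estimate[findInterval(t, curve$time)]
}

#' Weighted Kaplan-Meier survival curve
#'
#' Product-limit estimator over the weighted risk table, pooling all event
#' types:
#' \deqn{\hat S(t) = \prod_{t_k \le t} \left(1 - d^{\hat W}(t_k) /
#'   n^{\hat W}(t_k)\right).}
#' With inverse-probability-of-exposure weights this is the
#' confounder-standardized survival curve.
#'
#' @param risk A [risk_table()].
#' @return A survival [step_curve()] with \eqn{\hat S(0) = 1}.
#' @export
weighted_km <- function(risk) {
  weighted_overall_survival(risk, mode = "product_limit")
}

#' Weighted overall survival curve
#'
#' All-cause weighted survival in one of two forms: the product-limit
#' (Kaplan-Meier) form \eqn{\prod(1 - d/n)}, or the exponential
#' cumulative-hazard (Breslow-type) form
#' \eqn{\hat S^{\hat W}(t) = \exp\{-\sum_{t_k \le t}
#'   d^{\hat W}(t_k)/n^{\hat W}(t_k)\}.}
#' The product-limit form satisfies the additivity identity
#' \eqn{\hat F_j + \hat F_{J\ne j} + \hat S = 1} exactly (and is the
#' default throughout); the exponential form always lies above it when
#' events occur, so the same sum exceeds 1. See the methods vignette.
#'
#' @param risk A [risk_table()].
#' @param mode `"product_limit"` (default) or `"exp_cumhaz"`.
#' @return A survival [step_curve()].
#' @export
weighted_overall_survival <- function(risk,
                                      mode = c("product_limit", "exp_cumhaz")) {
  mode <- match.arg(mode)
  stopifnot(inherits(risk, "risk_table"))
  check_risk_support(risk)
  h <- risk$d_all / risk$n_risk
  s <- if (mode == "product_limit") cumprod(1 - h) else exp(-cumsum(h))
  step_curve(c(0, risk$time), c(1, s), kind = "survival",
             horizon = attr(risk, "horizon"))
}

#' Weighted cumulative incidence function (Aalen-Johansen type)
#'
#' Inverse-probability-weighted cumulative incidence for one event type in
#' the presence of competing events:
#' \deqn{\hat F_j(t) = \sum_{t_k \le t} \hat S^{\hat W}(t_{k-1}) \,
#'   \frac{d_j^{\hat W}(t_k)}{n^{\hat W}(t_k)},}
#' where \eqn{d_j^{\hat W}(t_k)/n^{\hat W}(t_k)} is the discrete
#' cause-specific hazard and \eqn{\hat S^{\hat W}} is the overall
#' (all-cause) weighted survival, computed in the chosen `mode`.
#'
#' @param risk A [risk_table()].
#' @param event_type `"event"` (the event of interest), `"competing"` (the
#'   composite competing event), or an integer code from the coding.
#' @param mode Overall-survival form, as in [weighted_overall_survival()].
#' @return A CIF [step_curve()] with \eqn{\hat F_j(0) = 0}.
#' @export
weighted_cif <- function(risk, event_type = "event",
                         mode = c("product_limit", "exp_cumhaz")) {
  mode <- match.arg(mode)
  stopifnot(inherits(risk, "risk_table"))
  check_risk_support(risk)
  d_j <- risk_event_column(risk, event_type)
  h_all <- risk$d_all / risk$n_risk
  s <- if (mode == "product_limit") cumprod(1 - h_all) else exp(-cumsum(h_all))
  s_lag <- c(1, s[-length(s)])            # S(t_{k-1}), S(t_0) = 1
  f <- cumsum(s_lag * d_j / risk$n_risk)
  step_curve(c(0, risk$time), c(0, pmin(f, 1)), kind = "cif",
             horizon = attr(risk, "horizon"))
}

check_risk_support <- function(risk) {
  dead <- risk$n_risk <= 0
  if (any(dead)) {
    stop("weighted risk set is empty at time ",
         format(risk$time[which(dead)[1]]),
         ", before the horizon; the curve is undefined there", call. = FALSE)
  }
  invisible(risk)
}

#' @export
print.step_curve <- function(x, ...) {
  cat("<step_curve> kind:", attr(x, "kind"),
      "| knots:", nrow(x),
      "| horizon:", format(attr(x, "horizon")), "\n")
  NextMethod()
}

#' @export
autoplot.step_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = attr(object, "kind")) +
    ggplot2::theme_minimal()
}
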