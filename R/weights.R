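#' Stabilized inverse-probability-of-exposure weights
#'
#' Fits a logistic regression for the probability of the observed exposure
#' given baseline covariates and returns the stabilized weight
#' \deqn{\hat W_i = \hat P(X = x_i) / \hat P(X = x_i \mid Z_i),}
#' where the numerator is the marginal sample proportion of the subject's
#' own exposure level and the denominator is the fitted conditional
#' probability. Weighting by \eqn{\hat W_i} standardizes both exposure
#' groups to the covariate distribution of the full sample, so weighted
#' survival and cumulative-incidence curves are confounder-adjusted.
#'
#' Continuous covariates (numeric with more than five distinct values) are
#' expanded in a natural cubic spline basis with `spline_df` degrees of
#' freedom and interior knots at equally spaced quantiles; other covariates
#' enter as factors. Pass `formula` to override this default design.
#'
#' @param data A cohort tibble (see [as_cohort()]).
#' @param covariates Character vector of covariate column names for the
#'   denominator model. Empty (`character(0)`) fits an intercept-only model,
#'   making every stabilized weight exactly 1.
#' @param spline_df Degrees of freedom of the natural cubic spline basis
#'   for continuous covariates (default 4).
#' @param stabilize If `TRUE` (default) the numerator is the marginal
#'   exposure proportion; if `FALSE` the numerator is 1 (unstabilized
#'   weights).
#' @param formula Optional one-sided formula giving the denominator design
#'   explicitly (e.g. `~ splines::ns(age, 4) + sex`); overrides
#'   `covariates`/`spline_df`.
#'
#' @return An object of class `ipw_model`: a list with elements `weights`
#'   (per-subject stabilized weights, in row order), `fit` (the glm),
#'   `numerator` (named probabilities for exposure 1 and 0), `stabilized`,
#'   and `diagnostics` (min/max/mean weight and effective sample size
#'   \eqn{(\sum w)^2 / \sum w^2}). Supports [tidy()], [glance()] and
#'   `weights()`.
#' @examples
#' cohort <- sim_cohort(sim_config(n = 500, seed = 7))
#' wm <- fit_stabilized_weights(cohort, c("age", "cd4", "male"))
#' glance(wm)
#' @export
fit_stabilized_weights <- function(data, covariates = character(),
                                   spline_df = 4L, stabilize = TRUE,
                                   formula = NULL) {
  validate_cohort(data)
  if (is.null(formula)) {
    miss <- setdiff(covariates, names(data))
    if (length(miss) > 0) {
      stop("unknown covariate(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (any(!stats::complete.cases(data[covariates]))) {
      stop("missing covariate values; run complete_case_filter() first",
           call. = FALSE)
    }
    formula <- build_denominator_formula(data, covariates, spline_df)
  }
  formula <- stats::update(formula, exposure ~ .)

  n <- nrow(data)
  p_marg <- mean(data$exposure)
  fit <- stats::glm(formula, family = stats::binomial(), data = data)
  check_separation(fit, data)

  p1 <- stats::fitted(fit)            # P(X = 1 | Z)
  # clip only for overflow protection; extreme-but-real probabilities warn
  p1 <- pmin(pmax(p1, 1e-6), 1 - 1e-6)
  if (any(p1 < 0.01 | p1 > 0.99)) {
    warning("fitted exposure probabilities outside [0.01, 0.99] for ",
            sum(p1 < 0.01 | p1 > 0.99),
            " subject(s); weights may be unstable", call. = FALSE)
  }
  denom <- ifelse(data$exposure == 1, p1, 1 - p1)
  numer <- if (stabilize) ifelse(data$exposure == 1, p_marg, 1 - p_marg) else 1
  w <- numer / denom

  structure(
    list(
      weights = as.numeric(w),
      fit = fit,
      numerator = c(`P(X=1)` = p_marg, `P(X=0)` = 1 - p_marg),
      stabilized = stabilize,
      formula = formula,
      diagnostics = weight_diagnostics(w),
      n = n
    ),
    class = "ipw_model"
  )
}

build_denominator_formula <- function(data, covariates, spline_df) {
  if (length(covariates) == 0) {
    return(~1)
  }
  terms <- vapply(covariates, function(v) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(x)) > 5) {
      sprintf("splines::ns(%s, df = %d)", v, as.integer(spline_df))
    } else {
      sprintf("factor(%s)", v)
    }
  }, character(1))
  stats::as.formula(paste("~", paste(terms, collapse = " + ")),
                    env = globalenv())
}

# separation shows up as non-convergence or fitted probabilities at
# numerical 0/1 (<= ~3e-12 when the glm "converges" on separated data);
# small but genuine tail probabilities are tolerated (clipped + warned)
check_separation <- function(fit, data) {
  p <- stats::fitted(fit)
  if (!fit$converged || any(p < 1e-11) || any(p > 1 - 1e-11)) {
    cf <- stats::coef(fit)
    cf <- cf[names(cf) != "(Intercept)"]
    bad <- names(cf)[!is.na(cf) & abs(cf) > 15]
    stop("possible separation in the exposure model",
         if (length(bad)) paste0(" (term(s): ", paste(bad, collapse = ", "), ")"),
         call. = FALSE)
  }
  invisible(fit)
}

weight_diagnostics <- function(w) {
  list(min = min(w), max = max(w), mean = mean(w),
       ess = sum(w)^2 / sum(w^2))
}

#' Winsorize inverse-probability weights at percentiles
#'
#' Robustness utility: truncates weights at the given empirical percentiles
#' (inverse-ECDF order statistics, quantile type 1, so the bound is always
#' an observed weight). The untruncated weights are retained in
#' `$weights_raw` for audit. Estimation in this package uses untruncated
#' weights by default.
#'
#' @param model An [fit_stabilized_weights()] result.
#' @param lower_pct,upper_pct Percentile bounds in `[0, 100]`,
#'   `lower_pct < upper_pct`.
#' @return The modified `ipw_model` with recomputed diagnostics.
#' @export
truncate_weights <- function(model, lower_pct = 0, upper_pct = 100) {
  stopifnot(inherits(model, "ipw_model"))
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100)) {
    stop("require 0 <= lower_pct < upper_pct <= 100", call. = FALSE)
  }
  w <- if (is.null(model$weights_raw)) model$weights else model$weights_raw
  bounds <- stats::quantile(w, c(lower_pct, upper_pct) / 100, type = 1)
  model$weights_raw <- w
  model$weights <- pmin(pmax(w, bounds[[1]]), bounds[[2]])
  model$truncation <- c(lower_pct = lower_pct, upper_pct = upper_pct)
  model$diagnostics <- weight_diagnostics(model$weights)
  model
}

#' @export
weights.ipw_model <- function(object, ...) object$weights

#' @export
print.ipw_model <- function(x, ...) {
  d <- x$diagnostics
  cat("<ipw_model> ", if (x$stabilized) "stabilized " else "unstabilized ",
      "inverse-probability-of-exposure weights, n = ", x$n, "\n", sep = "")
  cat(sprintf("  weights: min %.3f | mean %.3f | max %.3f | ESS %.1f\n",
              d$min, d$mean, d$max, d$ess))
  invisible(x)
}

#' @rdname fit_stabilized_weights
#' @param x,object An `ipw_model`.
#' @param ... Unused.
#' @export
tidy.ipw_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "z value"],
    p.value = s[, "Pr(>|z|)"]
  )
}

#' @rdname fit_stabilized_weights
#' @export
glance.ipw_model <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    n = x$n,
    stabilized = x$stabilized,
    marginal_p_exposed = unname(x$numerator[1]),
    weight_min = d$min,
    weight_mean = d$mean,
    weight_max = d$max,
    ess = d$ess
  )
}

#' @export
autoplot.ipw_model <- function(object, ...) {
  df <- tibble::tibble(weight = object$weights)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = "stabilized weight", y = "subjects") +
    ggplot2::theme_minimal()
}

# resolve a weights argument: NULL (unit), numeric vector, or ipw_model
resolve_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1, n))
  if (inherits(weights, "ipw_model")) weights <- weights$weights
  weights <- as.numeric(weights)
  if (length(weights) != n) {
    stop("`weights` must have one entry per subject", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be strictly positive and finite", call. = FALSE)
  }
  weights
}
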