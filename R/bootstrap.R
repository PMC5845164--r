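#' Nonparametric percentile-bootstrap confidence intervals
#'
#' Resamples subjects with replacement (unrestricted, not stratified by
#' exposure) and re-runs the entire estimation pipeline — including
#' refitting the exposure-weight model — in every replicate, so the
#' interval reflects weight-estimation uncertainty. The 95% interval is
#' the 2.5th and 97.5th percentiles of the replicate estimates (empirical
#' quantiles with linear interpolation, type 7).
#'
#' All replicate index draws are generated up front from `seed`, so the
#' result is deterministic given `(data, statistic, n_boot, seed)` and
#' invariant to how replicates would be scheduled across workers.
#' Replicates that error (e.g. logistic separation in a small resample)
#' are dropped with a logged count; more than `max_fail_frac` failures is
#' an error.
#'
#' @param data A cohort tibble.
#' @param statistic A function `data -> numeric` mapping a cohort to one
#'   or more named estimates; the full pipeline (weights, curves, RMST)
#'   belongs inside it.
#' @param n_boot Number of bootstrap replicates (the motivating analysis
#'   used 10,000).
#' @param seed Integer seed controlling all resampling.
#' @param conf_level Confidence level (default 0.95, i.e. the
#'   2.5th/97.5th percentiles).
#' @param max_fail_frac Maximum tolerated fraction of failed replicates
#'   (default 0.05).
#' @return An object of class `bootstrap_result`: list with
#'   `point_estimate`, `replicates` (matrix, one row per successful
#'   replicate), `ci` (tibble: term, conf_low, conf_high), `n_boot`,
#'   `n_failed`, `seed`. Supports [tidy()] and [glance()].
#' @examples
#' cohort <- sim_cohort(sim_config(n = 200, seed = 3))
#' bt <- bootstrap_estimate(cohort,
#'   function(d) {
#'     est <- rmst_survival(d, horizon = 2)
#'     c(diff = rmst_contrast(est)$estimate)
#'   },
#'   n_boot = 50, seed = 11)
#' tidy(bt)
#' @export
bootstrap_estimate <- function(data, statistic, n_boot = 10000L, seed = 1L,
                               conf_level = 0.95, max_fail_frac = 0.05) {
  stopifnot(is.function(statistic), n_boot >= 1)
  validate_cohort(data)
  n <- nrow(data)

  point <- statistic(data)
  point <- vec_named(point)
  terms <- names(point)

  idx <- withr::with_seed(
    as.integer(seed),
    matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot,
           byrow = TRUE)
  )

  reps <- matrix(NA_real_, nrow = n_boot, ncol = length(point),
                 dimnames = list(NULL, terms))
  for (b in seq_len(n_boot)) {
    res <- tryCatch(
      suppressWarnings(suppressMessages(statistic(data[idx[b, ], , drop = FALSE]))),
      error = function(e) NULL
    )
    if (!is.null(res) && length(res) == length(point) && all(is.finite(res))) {
      reps[b, ] <- as.numeric(res)
    }
  }
  ok <- stats::complete.cases(reps)
  n_failed <- sum(!ok)
  if (n_failed > max_fail_frac * n_boot) {
    stop(n_failed, " of ", n_boot, " bootstrap replicates failed (> ",
         100 * max_fail_frac, "%); check for separation or sparse strata",
         call. = FALSE)
  }
  if (n_failed > 0) {
    message(n_failed, " bootstrap replicate(s) failed and were dropped")
  }
  reps <- reps[ok, , drop = FALSE]
  alpha <- (1 - conf_level) / 2
  ci <- tibble::tibble(
    term = terms,
    estimate = as.numeric(point),
    conf_low = unname(apply(reps, 2, stats::quantile, probs = alpha,
                            type = 7, names = FALSE)),
    conf_high = unname(apply(reps, 2, stats::quantile, probs = 1 - alpha,
                             type = 7, names = FALSE))
  )
  structure(
    list(point_estimate = point, replicates = reps, ci = ci,
         n_boot = as.integer(n_boot), n_failed = n_failed,
         seed = as.integer(seed), conf_level = conf_level),
    class = "bootstrap_result"
  )
}

vec_named <- function(x) {
  x <- unlist(x)
  nm <- names(x)
  if (is.null(nm)) nm <- paste0("estimate", seq_along(x))
  stats::setNames(as.numeric(x), nm)
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> ", x$n_boot, " replicates (",
      x$n_failed, " failed), seed ", x$seed, ", ",
      100 * x$conf_level, "% percentile CI\n", sep = "")
  print(x$ci)
  invisible(x)
}

#' @rdname bootstrap_estimate
#' @param x An object returned by `bootstrap_estimate()`.
#' @param ... Unused.
#' @export
tidy.bootstrap_result <- function(x, ...) x$ci

#' @rdname bootstrap_estimate
#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble::tibble(n_boot = x$n_boot, n_failed = x$n_failed,
                 seed = x$seed, conf_level = x$conf_level)
}

#' @export
autoplot.bootstrap_result <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object$replicates)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "term",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "replicate estimate", y = "count") +
    ggplot2::theme_minimal()
}

#' Attach bootstrap CIs to an RMST table
#'
#' Fills the `conf_low`/`conf_high` columns of an `rmst_df` from a
#' [bootstrap_estimate()] whose statistic returned one value per row of
#' the table (matched by position).
#'
#' @param estimates An `rmst_df`.
#' @param boot A `bootstrap_result` with as many terms as rows.
#' @return The `rmst_df` with confidence bounds filled in.
#' @export
add_bootstrap_ci <- function(estimates, boot) {
  stopifnot(inherits(estimates, "rmst_df"), inherits(boot, "bootstrap_result"),
            nrow(estimates) == nrow(boot$ci))
  estimates$conf_low <- boot$ci$conf_low
  estimates$conf_high <- boot$ci$conf_high
  estimates
}
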