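#' Run the full weighted-RMST analysis workflow
#'
#' End-to-end pipeline on a cohort table: complete-case filtering,
#' stabilized inverse-probability-of-exposure weights, weighted survival
#' and cumulative-incidence curves per exposure group, restricted-mean
#' estimates with percentile-bootstrap confidence intervals, group
#' contrasts, and comparator estimand curves — overall and within each
#' stratum of an optional grouping column (e.g. enrollment era). Weights
#' are re-fit within each stratum.
#'
#' @param data A cohort tibble, or `NULL` to read `config$cohort$path`.
#' @param config A list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{covariates}{character vector of confounder columns}
#'     \item{spline_df}{spline df for continuous confounders (default 4)}
#'     \item{coding}{list with `event_of_interest` and `competing` codes}
#'     \item{horizon}{RMST horizon \eqn{t^*}}
#'     \item{estimands}{subset of `c("rmst_survival", "event_free_rmst")`}
#'     \item{strata}{optional stratum column name}
#'     \item{n_boot}{bootstrap replicates (default 10000)}
#'     \item{seed}{integer seed}
#'     \item{out_dir}{optional output directory for the CSV bundle}
#'     \item{cohort}{when `data` is `NULL`: list with `path` and optional
#'       column-name mappings `exposure`, `time`, `event`, `id`}
#'   }
#' @return Invisibly, a list with tibbles `rmst` (estimates, contrasts and
#'   CIs per stratum, the machine-readable analogue of a stratified
#'   results table), `curves` (all step curves, long format),
#'   `effect_curves` (pointwise HR/RR/RD), `weight_diagnostics`, and
#'   `log` (seed, versions, config hash, exclusion counts). When
#'   `out_dir` is set the same objects are written as CSV plus a plain
#'   text log; partial outputs are removed if any stage fails.
#' @export
run_analysis <- function(data = NULL, config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- normalize_config(config)

  if (is.null(data)) {
    if (is.null(cfg$cohort$path)) {
      stop("stage read_cohort: no `data` given and no cohort path in config",
           call. = FALSE)
    }
    data <- stage("read_cohort", read_cohort(
      cfg$cohort$path,
      exposure = cfg$cohort$exposure %||% "exposure",
      time = cfg$cohort$time %||% "time",
      event = cfg$cohort$event %||% "event",
      id = cfg$cohort$id
    ))
  }
  stage("validate", validate_cohort(data))

  n_before <- nrow(data)
  if (length(cfg$covariates) > 0) {
    data <- stage("complete_case_filter",
                  suppressMessages(complete_case_filter(data, cfg$covariates)))
  }
  n_excluded <- attr(data, "n_excluded") %||% 0L

  strata <- list(`all` = data)
  if (!is.null(cfg$strata)) {
    if (!cfg$strata %in% names(data)) {
      stop("stage stratify: stratum column `", cfg$strata, "` not found",
           call. = FALSE)
    }
    lv <- sort(unique(as.character(data[[cfg$strata]])))
    for (s in lv) strata[[s]] <- data[as.character(data[[cfg$strata]]) == s, ]
  }

  results <- purrr::imap(strata, function(d, label) {
    stage(paste0("analyze[", label, "]"),
          analyze_stratum(d, cfg, stratum = label))
  })

  rmst <- dplyr::bind_rows(purrr::map(results, "rmst"))
  curves <- dplyr::bind_rows(purrr::map(results, "curves"))
  effect_curves <- dplyr::bind_rows(purrr::map(results, "effect_curves"))
  weight_diag <- dplyr::bind_rows(purrr::map(results, "weight_diagnostics"))

  log <- list(
    seed = cfg$seed, n_boot = cfg$n_boot, horizon = cfg$horizon,
    n_input = n_before, n_excluded_incomplete = n_excluded,
    n_analyzed = nrow(data),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("ipwrmst")),
    config_hash = rlang::hash(cfg)
  )
  out <- list(rmst = rmst, curves = curves, effect_curves = effect_curves,
              weight_diagnostics = weight_diag, log = log)

  if (!is.null(cfg$out_dir)) {
    stage("write_bundle", write_bundle(out, cfg$out_dir))
  }
  invisible(out)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

normalize_config <- function(config) {
  cfg <- config
  cfg$covariates <- as.character(cfg$covariates %||% character(0))
  cfg$spline_df <- cfg$spline_df %||% 4L
  cd <- cfg$coding %||% list()
  cfg$coding <- event_coding(
    event_of_interest = cd$event_of_interest %||% 1L,
    competing = unlist(cd$competing) %||% 2L
  )
  if (is.null(cfg$horizon)) stop("config must set `horizon`", call. = FALSE)
  cfg$estimands <- cfg$estimands %||% c("rmst_survival", "event_free_rmst")
  stopifnot(all(cfg$estimands %in% c("rmst_survival", "event_free_rmst")))
  cfg$n_boot <- as.integer(cfg$n_boot %||% 10000L)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg
}

analyze_stratum <- function(data, cfg, stratum) {
  coding <- cfg$coding
  horizon <- cfg$horizon
  wm <- fit_stabilized_weights(data, cfg$covariates,
                               spline_df = cfg$spline_df)
  w <- wm$weights

  estimate_all <- function(d) {
    m <- fit_stabilized_weights(d, cfg$covariates,
                                spline_df = cfg$spline_df)
    rows <- list()
    if ("rmst_survival" %in% cfg$estimands) {
      est <- rmst_survival(d, horizon, m, coding)
      rows$rs <- bind_rmst(list(est, rmst_contrast(est)))
    }
    if ("event_free_rmst" %in% cfg$estimands) {
      est <- event_free_rmst(d, horizon, m, coding)
      rows$ef <- bind_rmst(list(est, rmst_contrast(est)))
    }
    bind_rmst(rows)
  }

  point <- estimate_all(data)
  boot <- bootstrap_estimate(
    data,
    function(d) stats::setNames(estimate_all(d)$estimate,
                                paste(point$estimand, point$group)),
    n_boot = cfg$n_boot, seed = cfg$seed
  )
  rmst <- add_bootstrap_ci(point, boot)
  rmst <- dplyr::mutate(rmst, stratum = stratum, .before = 1)

  groups <- split_by_exposure(data, w)
  curve_rows <- purrr::imap(groups, function(g, label) {
    rk <- risk_table(g$data, g$w, coding, horizon)
    dplyr::bind_rows(
      curve_tbl(weighted_km(rk), "survival_all_cause", label),
      curve_tbl(weighted_cif(rk, "event"), "cif_event", label),
      curve_tbl(weighted_cif(rk, "competing"), "cif_competing", label)
    )
  })
  curves <- dplyr::mutate(dplyr::bind_rows(curve_rows),
                          stratum = stratum, .before = 1)

  rk1 <- risk_table(groups[["1"]]$data, groups[["1"]]$w, coding, horizon)
  rk0 <- risk_table(groups[["0"]]$data, groups[["0"]]$w, coding, horizon)
  s1 <- weighted_km(rk1)
  s0 <- weighted_km(rk0)
  effect_curves <- dplyr::bind_rows(
    effect_tbl(risk_ratio_curve(s1, s0)),
    effect_tbl(risk_difference_curve(s1, s0)),
    effect_tbl(hazard_ratio_curve(rk1, rk0, "all")),
    effect_tbl(hazard_ratio_curve(rk1, rk0, "event")),
    effect_tbl(hazard_ratio_curve(rk1, rk0, "subdistribution"))
  )
  effect_curves <- dplyr::mutate(effect_curves, stratum = stratum,
                                 .before = 1)

  wd <- dplyr::mutate(glance(wm), stratum = stratum, .before = 1)
  list(rmst = rmst, curves = curves, effect_curves = effect_curves,
       weight_diagnostics = wd)
}

curve_tbl <- function(x, what, group) {
  tibble::tibble(curve = what, group = group,
                 time = x$time, estimate = x$estimate)
}

effect_tbl <- function(curve) {
  tibble::tibble(estimand = attr(curve, "estimand"), time = curve$time,
                 estimate = curve$estimate, defined = curve$defined)
}

write_bundle <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("rmst.csv", "curves.csv",
                                "effect_curves.csv",
                                "weight_diagnostics.csv", "run_log.txt"))
  on_fail <- function(e) {
    unlink(paths)
    stop(conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    readr::write_csv(out$rmst, paths[1])
    readr::write_csv(out$curves, paths[2])
    readr::write_csv(out$effect_curves, paths[3])
    readr::write_csv(out$weight_diagnostics, paths[4])
    writeLines(paste(names(out$log), unlist(out$log), sep = ": "),
               paths[5])
  }, error = on_fail)
  invisible(out_dir)
}
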