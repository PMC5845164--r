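#' Construct and validate a cohort table
#'
#' A cohort table is a tibble with one row per subject and canonical columns
#' `id`, `exposure` (binary 0/1), `time` (non-negative follow-up time) and
#' `event` (integer event-type code: 0 = censored, positive codes for event
#' types). All remaining columns are treated as baseline covariates.
#'
#' @param data A data frame of subject-level records.
#' @param exposure,time,event Columns holding the binary exposure indicator,
#'   the observed follow-up time and the integer event-type code
#'   (tidy-select, unquoted).
#' @param id Optional column with a subject identifier; generated as row
#'   number when absent.
#' @param time_unit Unit string carried through to results (default
#'   `"years"`); the package itself is unit-agnostic.
#'
#' @return A tibble of class `cohort_df` whose first four columns are
#'   `id`, `exposure`, `time`, `event`, followed by covariate columns.
#' @examples
#' df <- data.frame(x = c(0, 1, 0, 1), t = c(1, 2, 3, 4),
#'                  j = c(1, 0, 2, 0), age = c(30, 40, 50, 60))
#' as_cohort(df, exposure = x, time = t, event = j)
#' @export
as_cohort <- function(data, exposure = exposure, time = time, event = event,
                      id = NULL, time_unit = "years") {
  stopifnot(is.data.frame(data))
  out <- tibble::as_tibble(data)
  exposure <- rlang::enquo(exposure)
  time <- rlang::enquo(time)
  event <- rlang::enquo(event)
  id <- rlang::enquo(id)

  loc_x <- tidyselect_one(out, exposure, "exposure")
  loc_t <- tidyselect_one(out, time, "time")
  loc_j <- tidyselect_one(out, event, "event")
  core <- c(exposure = loc_x, time = loc_t, event = loc_j)
  if (!rlang::quo_is_null(id)) {
    core <- c(id = tidyselect_one(out, id, "id"), core)
  }
  covar <- setdiff(seq_along(out), core)
  out <- dplyr::bind_cols(
    rlang::set_names(out[core], names(core)),
    out[covar]
  )
  if (!"id" %in% names(out)) {
    out <- dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
  }
  ev <- out$event
  frac <- is.finite(ev) & ev != floor(ev)
  if (any(frac)) {
    stop("event codes must be non-negative integers; offending row(s) ",
         rows_msg(which(frac)), call. = FALSE)
  }
  out$event <- as.integer(ev)
  validate_cohort(out)
  attr(out, "time_unit") <- time_unit
  class(out) <- c("cohort_df", class(tibble::tibble()))
  out
}

tidyselect_one <- function(data, quo, what) {
  loc <- tryCatch(
    tidyselect::eval_select(quo, data),
    error = function(e) {
      stop("cannot find the `", what, "` column: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(loc) != 1L) {
    stop("`", what, "` must select exactly one column", call. = FALSE)
  }
  unname(loc)
}

#' Validate cohort invariants
#'
#' Checks that exposure is binary with both levels present, follow-up times
#' are non-negative, and event codes are non-negative integers, with no
#' missing values in any of the three.
#'
#' @param data A data frame with columns `exposure`, `time`, `event`.
#' @param require_both_levels Require both exposure levels to be present
#'   (needed for contrasts; single-group subsets may disable it).
#' @return `data`, invisibly, if valid; otherwise an error naming the
#'   offending rows.
#' @export
validate_cohort <- function(data, require_both_levels = TRUE) {
  need <- c("exposure", "time", "event")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in need) {
    if (anyNA(data[[col]])) {
      stop("missing values in `", col, "` at row(s) ",
           rows_msg(which(is.na(data[[col]]))), call. = FALSE)
    }
  }
  if (!all(data$exposure %in% c(0, 1))) {
    stop("`exposure` must be coded 0/1; offending row(s) ",
         rows_msg(which(!data$exposure %in% c(0, 1))), call. = FALSE)
  }
  if (require_both_levels && length(unique(data$exposure)) < 2) {
    stop("both exposure levels required", call. = FALSE)
  }
  if (any(data$time < 0)) {
    stop("negative follow-up time at row(s) ",
         rows_msg(which(data$time < 0)), call. = FALSE)
  }
  ev <- data$event
  if (any(ev < 0) || any(ev != as.integer(ev))) {
    stop("event codes must be non-negative integers; offending row(s) ",
         rows_msg(which(ev < 0 | ev != as.integer(ev))), call. = FALSE)
  }
  invisible(data)
}

rows_msg <- function(idx, max_show = 10L) {
  shown <- utils::head(idx, max_show)
  msg <- paste(shown, collapse = ", ")
  if (length(idx) > max_show) msg <- paste0(msg, ", ... (", length(idx), " total)")
  msg
}

#' Read a cohort table from a delimited text file
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param exposure,time,event,id Column names (strings) in the file mapping
#'   to the canonical cohort fields; `id` may be `NULL`.
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` gives tab, otherwise comma).
#' @param time_unit Unit string for follow-up times.
#' @return A validated [as_cohort()] tibble; the row count is reported via
#'   a message.
#' @export
read_cohort <- function(path, exposure = "exposure", time = "time",
                        event = "event", id = NULL, delim = NULL,
                        time_unit = "years") {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  for (col in c(exposure, time, event, id)) {
    if (!col %in% names(raw)) {
      stop("column `", col, "` not found in ", path, call. = FALSE)
    }
  }
  out <- as_cohort(raw,
                   exposure = !!rlang::sym(exposure),
                   time = !!rlang::sym(time),
                   event = !!rlang::sym(event),
                   id = !!(if (is.null(id)) rlang::expr(NULL) else rlang::sym(id)),
                   time_unit = time_unit)
  message("read ", nrow(out), " subjects from ", path)
  out
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))` restores
#' the table field-for-field.
#'
#' @param data A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(data)), path)
  invisible(path)
}

#' Drop subjects with missing covariate values
#'
#' Complete-case exclusion over a named set of covariates, applied before
#' any estimation (no imputation). The number of excluded subjects is
#' reported and stored on the result as attribute `n_excluded`.
#'
#' @param data A cohort tibble.
#' @param covariates Character vector of covariate column names to screen.
#' @return The filtered tibble with attribute `n_excluded`; errors if no
#'   rows remain.
#' @examples
#' df <- data.frame(exposure = rep(0:1, 5), time = 1:10, event = 0,
#'                  cd4 = c(NA, 2:9, NA))
#' out <- complete_case_filter(as_cohort(df), "cd4")
#' attr(out, "n_excluded")  # 2
#' @export
complete_case_filter <- function(data, covariates) {
  miss <- setdiff(covariates, names(data))
  if (length(miss) > 0) {
    stop("unknown covariate(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  keep <- stats::complete.cases(data[covariates])
  n_excluded <- sum(!keep)
  if (n_excluded == nrow(data)) {
    stop("all rows have missing covariate values", call. = FALSE)
  }
  out <- data[keep, , drop = FALSE]
  message(n_excluded, " subject(s) excluded for missing covariate values (",
          sprintf("%.1f%%", 100 * n_excluded / nrow(data)), "); ",
          nrow(out), " remain")
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Event-type coding
#'
#' Declares which integer code marks the event of interest and which codes
#' form the composite competing event. Code 0 is always censoring. Multiple
#' competing causes are collapsed into one composite internally (e.g. death
#' and loss-to-clinic as a single competing event for ART initiation).
#'
#' @param event_of_interest Integer code of the event of interest.
#' @param competing Integer vector of codes treated as the composite
#'   competing event; may be empty for a single-cause analysis.
#' @param censor Censoring code, fixed at 0.
#' @return An object of class `event_coding`.
#' @export
event_coding <- function(event_of_interest = 1L, competing = 2L,
                         censor = 0L) {
  event_of_interest <- as.integer(event_of_interest)
  competing <- as.integer(competing)
  censor <- as.integer(censor)
  stopifnot(length(event_of_interest) == 1L, length(censor) == 1L)
  if (censor != 0L) stop("the censoring code is fixed at 0", call. = FALSE)
  if (event_of_interest %in% c(censor, competing)) {
    stop("`event_of_interest` must differ from censoring and competing codes",
         call. = FALSE)
  }
  if (censor %in% competing) {
    stop("the censoring code cannot be a competing code", call. = FALSE)
  }
  structure(
    list(event_of_interest = event_of_interest,
         competing = competing, censor = censor),
    class = "event_coding"
  )
}

#' @export
print.event_coding <- function(x, ...) {
  cat("<event_coding> interest:", x$event_of_interest,
      "| competing:", if (length(x$competing)) paste(x$competing, collapse = ",") else "none",
      "| censor:", x$censor, "\n")
  invisible(x)
}

# all codes a coding accepts, for validation against observed events
coding_codes <- function(coding) {
  c(coding$censor, coding$event_of_interest, coding$competing)
}
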