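#' Weighted risk table at distinct event times
#'
#' Aggregates a cohort into the ordered distinct event times
#' \eqn{t_k \le t^*}, with the weighted number at risk
#' \eqn{n^{\hat W}(t_k)}, weighted event counts per type
#' \eqn{d_j^{\hat W}(t_k)} (event of interest and composite competing
#' event), and weighted censorings in each inter-event interval. The
#' horizon \eqn{t^*} is always appended as a final knot so downstream
#' integration never extrapolates.
#'
#' Ties are resolved by the standard survival convention: a subject
#' censored at \eqn{t_k} is still in the risk set for events at
#' \eqn{t_k} (events precede censorings). Weighted counts are sums of
#' subject weights, never rounded.
#'
#' @param data A cohort tibble.
#' @param weights `NULL` (unit weights), a numeric vector, or an
#'   [fit_stabilized_weights()] model.
#' @param coding An [event_coding()] declaring the event of interest and
#'   the composite competing codes.
#' @param horizon Integration horizon \eqn{t^*}; must not exceed the
#'   maximum observed follow-up time (no extrapolation).
#' @return A tibble of class `risk_table` with columns `time`, `n_risk`,
#'   `d_event`, `d_competing`, `d_all`, `n_censor`, and attributes
#'   `horizon` and `coding`.
#' @examples
#' df <- data.frame(exposure = c(0, 1, 0, 1), time = 1:4,
#'                  event = c(1, 1, 0, 0))
#' risk_table(as_cohort(df), horizon = 4)
#' @export
risk_table <- function(data, weights = NULL, coding = event_coding(),
                       horizon) {
  validate_cohort(data, require_both_levels = FALSE)
  stopifnot(inherits(coding, "event_coding"), is.numeric(horizon),
            length(horizon) == 1L, horizon > 0)
  w <- resolve_weights(weights, nrow(data))
  if (horizon > max(data$time)) {
    stop("horizon ", horizon, " exceeds the maximum observed follow-up time ",
         max(data$time), "; no extrapolation beyond the data", call. = FALSE)
  }
  unknown <- setdiff(unique(data$event), coding_codes(coding))
  if (length(unknown) > 0) {
    stop("event code(s) not covered by the coding: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }

  time <- data$time
  is_event <- data$event == coding$event_of_interest
  is_comp <- data$event %in% coding$competing

  tk <- sort(unique(time[(is_event | is_comp) & time <= horizon]))
  tk <- unique(c(tk, horizon))

  # n at risk: subjects with follow-up >= t_k (censored-at-t_k included);
  # computed as total weight minus weight with time < t_k via one sort
  ord <- order(time)
  cw <- c(0, cumsum(w[ord]))
  total_w <- cw[length(cw)]
  # left-open intervals make findInterval count elements strictly < t_k
  below <- findInterval(tk, time[ord], left.open = TRUE)
  n_risk <- total_w - cw[below + 1]

  d_event <- weighted_count_at(tk, time[is_event], w[is_event])
  d_comp <- weighted_count_at(tk, time[is_comp], w[is_comp])
  cens_t <- time[!is_event & !is_comp]
  cens_w <- w[!is_event & !is_comp]
  # censorings in [t_k, t_{k+1}); last interval extends to Inf
  breaks <- c(tk, Inf)
  if (length(cens_t) > 0) {
    bin <- findInterval(cens_t, breaks)
    keep <- bin >= 1
    n_censor <- as.numeric(
      rowsum_padded(cens_w[keep], bin[keep], length(tk))
    )
  } else {
    n_censor <- numeric(length(tk))
  }

  out <- tibble::new_tibble(
    list(time = tk, n_risk = n_risk,
         d_event = d_event, d_competing = d_comp,
         d_all = d_event + d_comp, n_censor = n_censor),
    nrow = length(tk),
    class = "risk_table"
  )
  attr(out, "horizon") <- horizon
  attr(out, "coding") <- coding
  out
}

# sum of weights at exactly each knot time (exact matches only)
weighted_count_at <- function(tk, times, w) {
  if (length(times) == 0) return(numeric(length(tk)))
  idx <- match(times, tk)
  keep <- !is.na(idx)
  rowsum_padded(w[keep], idx[keep], length(tk))
}

rowsum_padded <- function(w, bin, n_bins) {
  out <- numeric(n_bins)
  if (length(w) > 0) {
    s <- rowsum(w, bin)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

# pull the per-type weighted event count column for an event code
risk_event_column <- function(risk, event_type) {
  coding <- attr(risk, "coding")
  if (identical(event_type, "event") ||
      identical(event_type, coding$event_of_interest)) {
    risk$d_event
  } else if (identical(event_type, "competing") ||
             (is.numeric(event_type) && event_type %in% coding$competing)) {
    risk$d_competing
  } else if (identical(event_type, "all")) {
    risk$d_all
  } else {
    stop("unknown event type: ", event_type, call. = FALSE)
  }
}
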