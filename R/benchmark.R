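#' Assemble the facility benchmark table
#'
#' One row per hospital with the six metric-by-method columns: crude DOT and
#' DASC per 1000 DP, method-1 O:E ratios and method-2 P:E ratios for both
#' outcomes, plus the corresponding rank columns (rank 1 = lowest use /
#' lowest ratio; ties get average ranks so downstream tau-b tie corrections
#' are exact).
#'
#' @param stays_eval Evaluation-period stay table.
#' @param oe_dot,oe_dasc Tibbles from [oe_ratios()] (`NULL` to omit).
#' @param pe_dot,pe_dasc Tibbles from [pe_ratios()] (`NULL` to omit).
#' @return Object of class `abx_benchmark` (a tibble); hospitals missing
#'   from any supplied column keep `NA` there and are flagged in the
#'   `complete` column.  Summary quantiles (median-unbiased, type 8) are in
#'   attribute `"summary"`.
#' @export
build_benchmark <- function(stays_eval, oe_dot = NULL, oe_dasc = NULL,
                            pe_dot = NULL, pe_dasc = NULL) {
  out <- aggregate_facility(stays_eval)
  add <- function(out, tab, value_col, new_name) {
    if (is.null(tab)) {
      return(out)
    }
    j <- match(out$hospital_id, tab$hospital_id)
    out[[new_name]] <- tab[[value_col]][j]
    out
  }
  out <- add(out, oe_dot, "oe", "oe_dot")
  out <- add(out, oe_dasc, "oe", "oe_dasc")
  out <- add(out, pe_dot, "pe", "pe_dot")
  out <- add(out, pe_dasc, "pe", "pe_dasc")
  metric_cols <- intersect(
    c(
      "crude_dot_rate", "crude_dasc_rate", "oe_dot", "oe_dasc",
      "pe_dot", "pe_dasc"
    ),
    names(out)
  )
  for (col in metric_cols) {
    r <- rep(NA_real_, nrow(out))
    ok <- !is.na(out[[col]])
    r[ok] <- rank(out[[col]][ok], ties.method = "average")
    out[[paste0("rank_", col)]] <- r
  }
  out$complete <- stats::complete.cases(out[metric_cols])
  if (any(!out$complete)) {
    warning(sum(!out$complete), " hospital(s) have incomplete benchmark rows")
  }
  summary_tab <- tibble::tibble(
    column = metric_cols,
    median = vapply(
      metric_cols,
      function(c) stats::median(out[[c]], na.rm = TRUE), numeric(1),
      USE.NAMES = FALSE
    ),
    q25 = vapply(
      metric_cols,
      function(c) stats::quantile(out[[c]], 0.25, na.rm = TRUE, type = 8),
      numeric(1), USE.NAMES = FALSE
    ),
    q75 = vapply(
      metric_cols,
      function(c) stats::quantile(out[[c]], 0.75, na.rm = TRUE, type = 8),
      numeric(1), USE.NAMES = FALSE
    )
  )
  attr(out, "summary") <- summary_tab
  class(out) <- c("abx_benchmark", class(out))
  out
}

#' Long (tidy) form of a benchmark table
#'
#' @param benchmark An `abx_benchmark`.
#' @return Tibble with one row per hospital x column (`hospital_id`,
#'   `column`, `value`, `rank`).
#' @export
benchmark_long <- function(benchmark) {
  metric_cols <- intersect(
    c(
      "crude_dot_rate", "crude_dasc_rate", "oe_dot", "oe_dasc",
      "pe_dot", "pe_dasc"
    ),
    names(benchmark)
  )
  do.call(rbind, lapply(metric_cols, function(col) {
    tibble::tibble(
      hospital_id = benchmark$hospital_id,
      column = col,
      value = benchmark[[col]],
      rank = benchmark[[paste0("rank_", col)]]
    )
  }))
}
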