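#' Antibiotic-use metrics: DOT, DASC and rates per 1000 days present
#'
#' Days of therapy (DOT) counts, for each antibiotic agent, the calendar days
#' on which the agent was administered during a stay, and sums over agents —
#' so a day of combination therapy with two agents contributes 2 DOT.  Days of
#' antimicrobial spectrum coverage (DASC) weights each agent-day by a positive
#' spectrum score, penalising broad-spectrum use.  Both are normalised by days
#' present (DP) when compared across units or facilities.
#'
#' @name metrics
NULL

#' Read a spectrum-score table
#'
#' A spectrum-score table maps antibiotic agent identifiers to positive,
#' unitless spectrum weights used to convert agent-days into DASC.  Accepts a
#' two-column CSV (`agent_id`, `score`) or a JSON object mapping agent ids to
#' scores.
#'
#' @param path Path to a CSV or JSON file.
#' @return A named numeric vector of scores, names are agent ids.
#' @export
read_spectrum_table <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    scores <- unlist(raw)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("agent_id", "score") %in% names(tab))) {
      stop("spectrum CSV must have columns 'agent_id' and 'score'")
    }
    scores <- stats::setNames(as.numeric(tab$score), tab$agent_id)
  }
  validate_spectrum_table(scores)
  scores
}

#' @rdname read_spectrum_table
#' @param scores Named numeric vector of spectrum scores.
#' @export
validate_spectrum_table <- function(scores) {
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("spectrum scores must be named by agent_id")
  }
  if (anyDuplicated(names(scores))) stop("duplicate agent_id in spectrum table")
  if (any(!is.finite(scores)) || any(scores <= 0)) {
    stop("all spectrum scores must be positive and finite")
  }
  invisible(scores)
}

#' Toy spectrum-score table shipped with the package
#'
#' A small synthetic table of ~20 agents with scores in \[1, 16\], for tests
#' and demonstrations only.  These are not published spectrum scores; real
#' analyses must supply their own table.
#'
#' @return Named numeric vector of scores.
#' @export
toy_spectrum_table <- function() {
  read_spectrum_table(system.file("extdata", "toy_spectrum_scores.csv",
    package = "abxbench", mustWork = TRUE
  ))
}

check_agent_days <- function(agent_days) {
  req <- c("stay_id", "agent_id", "n_days")
  if (!all(req %in% names(agent_days))) {
    stop("agent_days needs columns: ", paste(req, collapse = ", "))
  }
  if (any(agent_days$n_days < 0)) stop("n_days must be nonnegative")
  if (anyDuplicated(agent_days[c("stay_id", "agent_id")])) {
    stop("each agent_id must be unique within a stay")
  }
  invisible(agent_days)
}

#' Compute days of therapy per stay
#'
#' @param agent_days Data frame in long format with columns `stay_id`,
#'   `agent_id`, `n_days` (one row per agent administered during a stay).
#' @return A tibble with columns `stay_id` and `dot`.  Stays with no rows in
#'   `agent_days` are absent; join against the stay table and replace `NA`
#'   with 0 for a complete cohort.
#' @export
compute_dot <- function(agent_days) {
  check_agent_days(agent_days)
  agg <- stats::aggregate(n_days ~ stay_id, data = agent_days, FUN = sum)
  tibble::tibble(stay_id = agg$stay_id, dot = agg$n_days)
}

#' Compute days of antimicrobial spectrum coverage per stay
#'
#' DASC is the sum over agents of agent-days times the agent's spectrum
#' score; with unit scores it equals DOT.
#'
#' @inheritParams compute_dot
#' @param scores Named numeric vector of spectrum scores (see
#'   [read_spectrum_table()]).  Every agent in `agent_days` must be present;
#'   unknown agents are an error, never silently scored.
#' @return A tibble with columns `stay_id` and `dasc`.
#' @export
compute_dasc <- function(agent_days, scores) {
  check_agent_days(agent_days)
  validate_spectrum_table(scores)
  unknown <- setdiff(unique(agent_days$agent_id), names(scores))
  if (length(unknown) > 0) {
    stop(
      "agent(s) missing from spectrum table: ",
      paste(unknown, collapse = ", ")
    )
  }
  w <- agent_days$n_days * scores[agent_days$agent_id]
  agg <- stats::aggregate(w, by = list(stay_id = agent_days$stay_id), FUN = sum)
  tibble::tibble(stay_id = agg$stay_id, dasc = agg$x)
}

#' Rate per 1000 days present
#'
#' @param numerator Nonnegative metric total (DOT or DASC).
#' @param dp_total Positive days-present denominator.
#' @return `1000 * numerator / dp_total`, vectorised.
#' @export
rate_per_1000dp <- function(numerator, dp_total) {
  if (any(!is.finite(dp_total)) || any(dp_total < 1)) {
    stop("dp_total must be >= 1")
  }
  if (any(numerator < 0)) stop("numerator must be nonnegative")
  1000 * numerator / dp_total
}

#' Aggregate stays to unit-month records
#'
#' Sums DOT, DASC and DP within each unit x calendar-month cell and carries
#' the unit and facility attributes used by the single-level model.  Each
#' stay contributes wholly to its recorded month.
#'
#' @param stays Stay-level data frame with `hospital_id`, `unit_id`, `month`,
#'   `dp`, `dot`, `dasc`.
#' @param units Optional unit-attribute table (`unit_id`, `icu_floor`,
#'   `surgical_floor`, ...) joined onto the aggregate.
#' @param facilities Optional facility-attribute table (`hospital_id`,
#'   `complexity_level`, ...) joined onto the aggregate.
#' @return Tibble of unit-month records.
#' @export
aggregate_unit_month <- function(stays, units = NULL, facilities = NULL) {
  req <- c("hospital_id", "unit_id", "month", "dp", "dot", "dasc")
  if (!all(req %in% names(stays))) {
    stop("stays needs columns: ", paste(req, collapse = ", "))
  }
  if (!is.null(units)) {
    bad <- setdiff(unique(stays$unit_id), units$unit_id)
    if (length(bad) > 0) {
      stop("stays reference unknown unit(s): ", paste(bad, collapse = ", "))
    }
  }
  key <- list(
    hospital_id = stays$hospital_id, unit_id = stays$unit_id,
    month = stays$month
  )
  agg <- stats::aggregate(stays[c("dp", "dot", "dasc")], by = key, FUN = sum)
  agg$n_stays <- stats::aggregate(
    rep(1L, nrow(stays)),
    by = key, FUN = sum
  )$x
  out <- tibble::as_tibble(agg)
  if (!is.null(units)) {
    out <- merge_keep_order(out, units, by = "unit_id")
  }
  if (!is.null(facilities)) {
    out <- merge_keep_order(out, facilities, by = "hospital_id")
  }
  out
}

merge_keep_order <- function(x, y, by) {
  y <- y[!duplicated(y[[by]]), , drop = FALSE]
  idx <- match(x[[by]], y[[by]])
  extra <- setdiff(names(y), names(x))
  for (col in extra) x[[col]] <- y[[col]][idx]
  x
}

#' Aggregate stays to facility totals and crude rates
#'
#' @param stays Stay-level data frame with `hospital_id`, `dp`, `dot`, `dasc`.
#' @return Tibble with per-facility totals and crude DOT / DASC per 1000 DP.
#' @export
aggregate_facility <- function(stays) {
  agg <- stats::aggregate(stays[c("dp", "dot", "dasc")],
    by = list(hospital_id = stays$hospital_id), FUN = sum
  )
  tibble::tibble(
    hospital_id = agg$hospital_id,
    dp = agg$dp, dot = agg$dot, dasc = agg$dasc,
    crude_dot_rate = rate_per_1000dp(agg$dot, agg$dp),
    crude_dasc_rate = rate_per_1000dp(agg$dasc, agg$dp)
  )
}
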