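#' Single-level negative binomial risk adjustment (method 1)
#'
#' Method 1 mirrors the SAAR's modeling approach with richer covariates: a
#' negative binomial (NB2) regression on unit-month aggregates with a
#' `log(DP)` offset, fitted on the baseline period and applied to the
#' evaluation period to obtain facility observed-to-expected (O:E) ratios.
#'
#' @name nb_singlelevel
NULL

#' Assign average-length-of-stay quintiles
#'
#' Computes per-unit average length of stay (DP per stay) quintile cut
#' points on baseline records and applies them, frozen, to any later
#' records — evaluation data never moves the cuts.
#'
#' @param records Unit-month records with `dp` and `n_stays`.
#' @param cutpoints Previously computed cut points (`NULL` to compute).
#' @return `records` with an ordered-factor `avg_los_quintile` column;
#'   cut points in attribute `"los_cutpoints"`.
#' @export
assign_los_quintiles <- function(records, cutpoints = NULL) {
  avg_los <- records$dp / records$n_stays
  if (is.null(cutpoints)) {
    cutpoints <- stats::quantile(avg_los, probs = seq(0.2, 0.8, 0.2), type = 8)
  }
  records$avg_los_quintile <- factor(
    1L + findInterval(avg_los, cutpoints),
    levels = 1:5
  )
  attr(records, "los_cutpoints") <- cutpoints
  records
}

#' Fit the single-level NB2 model on unit-month records
#'
#' @param records Unit-month records (see [aggregate_unit_month()]).
#' @param outcome `"dot"` or `"dasc"` (DASC rounded to integer counts).
#' @param terms Character vector of covariate columns (factors enter as
#'   whole terms with their first level as reference).
#' @return Object of class `abx_nb`: the underlying [MASS::glm.nb] fit,
#'   `theta`, and a rate-ratio table with Wald 95% CIs.
#' @export
fit_nb <- function(records, outcome = "dot", terms = character()) {
  y <- records[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' not found")
  records$.y <- as.integer(round(y))
  if (length(unique(records$.y)) < 2) stop("outcome has < 2 distinct values")
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs, "+ offset(log(dp))"))
  fit <- suppressWarnings(MASS::glm.nb(fml, data = records, maxit = 100))
  if (!fit$converged) stop("NB fit did not converge")
  est <- stats::coef(fit)
  if (anyNA(est)) {
    warning(
      "collinear term(s) dropped: ",
      paste(names(est)[is.na(est)], collapse = ", ")
    )
  }
  se <- sqrt(diag(stats::vcov(fit)))
  ok <- !is.na(est)
  rr <- tibble::tibble(
    term = names(est)[ok],
    rate_ratio = exp(est[ok]),
    lower = exp(est[ok] - 1.96 * se),
    upper = exp(est[ok] + 1.96 * se)
  )
  structure(
    list(
      fit = fit, outcome = outcome, terms = terms,
      theta = fit$theta, rate_ratios = rr,
      xlevels = fit$xlevels,
      los_cutpoints = attr(records, "los_cutpoints")
    ),
    class = "abx_nb"
  )
}

#' @export
#' @method print abx_nb
print.abx_nb <- function(x, ...) {
  cat("NB2 unit-month model (", x$outcome, "), theta = ",
    signif(x$theta, 4), "\n",
    sep = ""
  )
  print(x$rate_ratios)
  invisible(x)
}

check_eval_levels <- function(model, records) {
  for (v in names(model$xlevels)) {
    seen <- model$xlevels[[v]]
    lev <- unique(as.character(records[[v]]))
    new <- setdiff(lev[!is.na(lev)], seen)
    if (length(new) > 0) {
      stop(
        "unseen level(s) of '", v, "' in evaluation data: ",
        paste(new, collapse = ", ")
      )
    }
  }
  invisible(TRUE)
}

#' Facility observed-to-expected ratios from a baseline NB model
#'
#' Scores evaluation-period unit-month records with the frozen baseline
#' model (fixed effects only), aggregates observed and expected outcome to
#' the facility, and returns O:E with an exact-Poisson-style interval on the
#' observed total (E treated as fixed) — the usual indirect-standardization
#' convention.
#'
#' @param model An `abx_nb` baseline fit.
#' @param records Evaluation-period unit-month records with the same
#'   covariate schema (unseen factor levels are an error).
#' @return Tibble (`hospital_id`, `observed`, `expected`, `oe`, `lower`,
#'   `upper`).
#' @export
oe_ratios <- function(model, records) {
  stopifnot(inherits(model, "abx_nb"))
  check_eval_levels(model, records)
  expected <- stats::predict(model$fit, newdata = records, type = "response")
  observed <- round(records[[model$outcome]])
  agg <- stats::aggregate(
    cbind(observed = observed, expected = expected),
    by = list(hospital_id = records$hospital_id), FUN = sum
  )
  o <- agg$observed
  lower <- ifelse(o == 0, 0, stats::qchisq(0.025, 2 * o) / 2)
  upper <- stats::qchisq(0.975, 2 * (o + 1)) / 2
  tibble::tibble(
    hospital_id = agg$hospital_id,
    observed = o, expected = agg$expected,
    oe = o / agg$expected,
    lower = lower / agg$expected, upper = upper / agg$expected
  )
}
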