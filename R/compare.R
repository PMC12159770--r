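#' Ranking agreement between benchmarking schemes
#'
#' Hospital rankings produced by different metric/adjustment combinations
#' are compared with the tie-corrected Kendall rank correlation (tau-b),
#' classified as strong (>= 0.7), moderate (0.5 to < 0.7) or weak (< 0.5).
#'
#' @name compare
NULL

#' Kendall tau-b rank correlation
#'
#' Tie-corrected Kendall correlation:
#' `tau_b = (C - D) / sqrt((n0 - n1) (n0 - n2))` with `C`/`D` the concordant
#' and discordant pair counts, `n0 = n(n-1)/2`, and `n1`, `n2` the tied-pair
#' counts within `x` and `y`.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return tau-b in `[-1, 1]`; `NA` with a warning when either vector is
#'   entirely tied (tau-b undefined).
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 2) {
    warning("fewer than 2 complete pairs; tau-b undefined")
    return(NA_real_)
  }
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  cd <- sum(sx * sy * upper.tri(sx)) # C - D over unordered pairs
  n0 <- n * (n - 1) / 2
  tied_pairs <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n1 <- tied_pairs(x)
  n2 <- tied_pairs(y)
  if (n1 == n0 || n2 == n0) {
    warning("all values tied in one vector; tau-b undefined")
    return(NA_real_)
  }
  cd / sqrt((n0 - n1) * (n0 - n2))
}

#' Classify a tau-b value by agreement strength
#'
#' @param tau Numeric vector of tau-b values.
#' @return Character vector: `"strong"` (>= 0.7), `"moderate"` (0.5 to
#'   < 0.7) or `"weak"` (< 0.5).
#' @export
classify_tau <- function(tau) {
  ifelse(is.na(tau), NA_character_,
    ifelse(tau >= 0.7, "strong", ifelse(tau >= 0.5, "moderate", "weak"))
  )
}

#' Pairwise tau-b matrix over benchmarking columns
#'
#' @param benchmark Facility benchmark table (see [build_benchmark()]).
#' @param columns Columns to correlate; defaults to the six
#'   metric-by-method columns present in the table.
#' @return Object of class `abx_tau_matrix`: `tau` (symmetric matrix),
#'   `classification` (same shape), `n` (complete hospitals used).
#' @export
tau_matrix <- function(benchmark, columns = NULL) {
  if (is.null(columns)) {
    columns <- intersect(
      c(
        "crude_dot_rate", "crude_dasc_rate", "oe_dot", "oe_dasc",
        "pe_dot", "pe_dasc"
      ),
      names(benchmark)
    )
  }
  stopifnot(length(columns) >= 2)
  dat <- as.matrix(benchmark[columns])
  complete <- stats::complete.cases(dat)
  if (sum(!complete) > 0) {
    message(sum(!complete), " incomplete hospital row(s) dropped")
  }
  dat <- dat[complete, , drop = FALSE]
  if (nrow(dat) < 2) stop("need >= 2 complete hospitals")
  p <- length(columns)
  tau <- diag(1, p)
  dimnames(tau) <- list(columns, columns)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      tau[i, j] <- tau[j, i] <- kendall_tau_b(dat[, i], dat[, j])
    }
  }
  structure(
    list(
      tau = tau,
      classification = matrix(classify_tau(tau), p, p, dimnames = dimnames(tau)),
      n = nrow(dat)
    ),
    class = "abx_tau_matrix"
  )
}

#' @export
#' @method print abx_tau_matrix
print.abx_tau_matrix <- function(x, ...) {
  cat("Kendall tau-b over", x$n, "hospitals\n")
  print(round(x$tau, 2))
  invisible(x)
}

#' Correlation between count and zero-inflation random intercepts
#'
#' Pairs each hospital's estimated count- and zero-component intercepts
#' (BLUPs) and reports their Spearman rank correlation — a positive value
#' means hospitals that start antibiotics more often also treat longer or
#' broader.
#'
#' @param model A fitted `abx_zinb_mixed`, or a BLUP tibble
#'   (`hospital_id`, `b_count`, `b_zero`).
#' @return List: `pairs` (tibble), `spearman_rho`, `p_value` (`NA` with a
#'   warning when the fit is degenerate).
#' @export
intercept_correlation <- function(model) {
  blups <- if (inherits(model, "abx_zinb_mixed")) model$blups else model
  stopifnot(nrow(blups) >= 3)
  if (stats::sd(blups$b_count) < 1e-10 || stats::sd(blups$b_zero) < 1e-10) {
    warning("degenerate intercepts (no variation); correlation undefined")
    return(list(pairs = blups, spearman_rho = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(blups$b_count, blups$b_zero,
      method = "spearman", exact = FALSE
    )
  )
  list(
    pairs = blups,
    spearman_rho = unname(ct$estimate), p_value = ct$p.value
  )
}
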