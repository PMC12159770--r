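#' @useDynLib abxbench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Build the two component design matrices from a stay table.  The zero
# component always carries log(dp) as a regular covariate; the count
# component uses log(dp) as an offset instead.
zinb_design <- function(stays, count_terms, zero_terms) {
  if (!"log_dp" %in% names(stays)) stays$log_dp <- log(stays$dp)
  mk <- function(terms) {
    if (length(terms) == 0) {
      return(matrix(1, nrow(stays), 1, dimnames = list(NULL, "(Intercept)")))
    }
    stats::model.matrix(stats::reformulate(terms), data = stays)
  }
  zt <- union(zero_terms, "log_dp")
  list(
    Xc = mk(count_terms), Xz = mk(zt),
    offset = stays$log_dp, y = NULL
  )
}

# Pure-R per-stay ZINB log-likelihood (kept independent of the compiled
# path; used by the dense-grid marginal likelihood).
zinb_stay_loglik_r <- function(y, etac, etaz, theta) {
  log_pi <- stats::plogis(etaz, log.p = TRUE)
  log_1mpi <- stats::plogis(-etaz, log.p = TRUE)
  mu <- exp(etac)
  log_p0 <- theta * (log(theta) - log(theta + mu))
  ll <- numeric(length(y))
  pos <- y > 0
  if (any(pos)) {
    ll[pos] <- log_1mpi[pos] +
      stats::dnbinom(y[pos], mu = mu[pos], size = theta, log = TRUE)
  }
  if (any(!pos)) {
    a <- log_pi[!pos]
    b <- log_1mpi[!pos] + log_p0[!pos]
    m <- pmax(a, b)
    ll[!pos] <- m + log(exp(a - m) + exp(b - m))
  }
  ll
}

#' Control settings for ZINB fitting
#'
#' @param maxit Maximum outer optimizer iterations.
#' @param pgtol Projected-gradient tolerance of the outer optimizer.
#' @param factr L-BFGS-B relative-precision factor.
#' @param log_sigma2_bounds Bounds on the log random-intercept variances.
#' @param log_theta_bounds Bounds on the log NB2 dispersion.
#' @return List of control settings.
#' @export
zinb_control <- function(maxit = 400, pgtol = 1e-6, factr = 1e7,
                         log_sigma2_bounds = c(-10, 3),
                         log_theta_bounds = c(-4, 8)) {
  list(
    maxit = maxit, pgtol = pgtol, factr = factr,
    log_sigma2_bounds = log_sigma2_bounds,
    log_theta_bounds = log_theta_bounds
  )
}

prep_outcome <- function(stays, outcome) {
  y <- stays[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' not found")
  if (any(y < 0)) stop("outcome must be nonnegative")
  yr <- round(y)
  if (max(abs(yr - y)) > 0) {
    # non-integer outcomes (DASC) enter the NB likelihood rounded
    y <- yr
  }
  as.numeric(y)
}

#' Fit a zero-inflated negative binomial model (no random effects)
#'
#' Maximum likelihood over `(beta_count, beta_zero, log theta)` with
#' `log(dp)` as the count-component offset and as a regular zero-component
#' covariate.  Used as the fixed-effect warm start of the mixed fit and for
#' sigma -> 0 comparisons.
#'
#' @param stays Stay table.
#' @param outcome Outcome column, `"dot"` or `"dasc"` (non-integer outcomes
#'   are rounded).
#' @param count_terms,zero_terms Character vectors of covariate columns.
#' @param control See [zinb_control()].
#' @return Object of class `abx_zinb` with elements `beta_count`,
#'   `beta_zero`, `theta`, `logLik`, `npar`, `convergence`.
#' @export
fit_zinb <- function(stays, outcome = "dot",
                     count_terms = character(), zero_terms = count_terms,
                     control = zinb_control()) {
  y <- prep_outcome(stays, outcome)
  d <- zinb_design(stays, count_terms, zero_terms)
  pc <- ncol(d$Xc)
  pz <- ncol(d$Xz)
  # warm starts from unmixed component fits
  pos <- y > 0
  init_c <- tryCatch(
    stats::glm.fit(d$Xc[pos, , drop = FALSE], y[pos],
      offset = d$offset[pos], family = stats::poisson()
    )$coefficients,
    error = function(e) rep(0, pc)
  )
  init_z <- tryCatch(
    stats::glm.fit(d$Xz, as.numeric(y == 0),
      family = stats::binomial()
    )$coefficients,
    error = function(e) rep(0, pz)
  )
  init_c[!is.finite(init_c)] <- 0
  init_z[!is.finite(init_z)] <- 0
  par0 <- c(init_c, init_z, 0)
  nll <- function(par) {
    etac <- as.vector(d$Xc %*% par[1:pc]) + d$offset
    etaz <- as.vector(d$Xz %*% par[pc + 1:pz])
    cpp_zinb_negll(y, etac, etaz, exp(par[pc + pz + 1]))
  }
  lower <- c(rep(-30, pc + pz), control$log_theta_bounds[1])
  upper <- c(rep(30, pc + pz), control$log_theta_bounds[2])
  opt <- stats::optim(par0, nll,
    method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(
      maxit = control$maxit, pgtol = control$pgtol, factr = control$factr
    )
  )
  structure(
    list(
      beta_count = stats::setNames(opt$par[1:pc], colnames(d$Xc)),
      beta_zero = stats::setNames(opt$par[pc + 1:pz], colnames(d$Xz)),
      theta = unname(exp(opt$par[pc + pz + 1])),
      logLik = -opt$value, npar = pc + pz + 1,
      outcome = outcome, count_terms = count_terms,
      zero_terms = union(zero_terms, "log_dp"),
      convergence = opt$convergence, n = length(y)
    ),
    class = "abx_zinb"
  )
}

#' @export
logLik.abx_zinb <- function(object, ...) {
  structure(object$logLik, df = object$npar, class = "logLik")
}

sorted_hospital_index <- function(stays) {
  ord <- order(stays$hospital_id)
  stays <- stays[ord, , drop = FALSE]
  hosp <- unique(stays$hospital_id)
  ends <- cumsum(table(factor(stays$hospital_id, levels = hosp)))
  list(
    stays = stays, hospitals = hosp,
    start = as.integer(c(0, ends)) # 0-based starts + total
  )
}

#' Marginal log-likelihood of the ZINB mixed model
#'
#' Evaluates the marginal log-likelihood of a zero-inflated negative
#' binomial model with independent hospital random intercepts in both
#' components, integrating each hospital's intercept pair either by the
#' Laplace approximation (the fitting path) or by dense two-dimensional grid
#' integration (the slow reference used to validate the approximation).
#'
#' @param stays Stay table.
#' @param outcome Outcome column.
#' @param count_terms,zero_terms Covariate columns per component.
#' @param beta_count,beta_zero Fixed-effect vectors (in design-column order).
#' @param theta NB2 dispersion.
#' @param sigma2_count,sigma2_zero Random-intercept variances.
#' @param method `"laplace"` or `"grid"`.
#' @param grid_nodes Grid points per dimension (grid method).
#' @param grid_width Half-width of the grid in random-intercept SDs.
#' @return Log-likelihood (scalar) with per-hospital contributions in
#'   attribute `"by_hospital"`.
#' @export
zinb_marginal_loglik <- function(stays, outcome = "dot",
                                 count_terms = character(),
                                 zero_terms = count_terms,
                                 beta_count, beta_zero, theta,
                                 sigma2_count, sigma2_zero,
                                 method = c("laplace", "grid"),
                                 grid_nodes = 161, grid_width = 7) {
  method <- match.arg(method)
  idx <- sorted_hospital_index(stays)
  stays <- idx$stays
  y <- prep_outcome(stays, outcome)
  d <- zinb_design(stays, count_terms, zero_terms)
  etac <- as.vector(d$Xc %*% beta_count) + d$offset
  etaz <- as.vector(d$Xz %*% beta_zero)
  nh <- length(idx$hospitals)
  if (method == "laplace") {
    warm <- matrix(0, nh, 2)
    res <- cpp_laplace_marginal(
      y, etac, etaz, theta, sigma2_count, sigma2_zero, idx$start, warm
    )
    out <- -res$nll
    attr(out, "by_hospital") <- stats::setNames(
      as.vector(res$ll_by_hospital), idx$hospitals
    )
    return(out)
  }
  sdc <- sqrt(sigma2_count)
  sdz <- sqrt(sigma2_zero)
  bc_grid <- seq(-grid_width * sdc, grid_width * sdc, length.out = grid_nodes)
  bz_grid <- seq(-grid_width * sdz, grid_width * sdz, length.out = grid_nodes)
  dc <- bc_grid[2] - bc_grid[1]
  dz <- bz_grid[2] - bz_grid[1]
  lw_c <- stats::dnorm(bc_grid, 0, sdc, log = TRUE)
  lw_z <- stats::dnorm(bz_grid, 0, sdz, log = TRUE)
  ll_h <- numeric(nh)
  for (h in seq_len(nh)) {
    rows <- (idx$start[h] + 1):idx$start[h + 1]
    yh <- y[rows]
    ech <- etac[rows]
    ezh <- etaz[rows]
    n <- length(rows)
    # log integrand over the (bc, bz) grid
    lmat <- matrix(0, grid_nodes, grid_nodes)
    ez_big <- rep(ezh, times = grid_nodes) +
      rep(bz_grid, each = n)
    y_big <- rep(yh, times = grid_nodes)
    for (j in seq_len(grid_nodes)) {
      ll <- zinb_stay_loglik_r(y_big, rep(ech + bc_grid[j], grid_nodes),
        ez_big, theta)
      lmat[j, ] <- colSums(matrix(ll, nrow = n)) + lw_c[j] + lw_z
    }
    m <- max(lmat)
    ll_h[h] <- m + log(sum(exp(lmat - m)) * dc * dz)
  }
  out <- sum(ll_h)
  attr(out, "by_hospital") <- stats::setNames(ll_h, idx$hospitals)
  out
}

#' Fit the ZINB mixed model (hospital random intercepts in both components)
#'
#' Maximizes the Laplace-approximated marginal likelihood over
#' `(beta_count, beta_zero, log theta, log sigma2_count, log sigma2_zero)`
#' by quasi-Newton (L-BFGS-B) with per-hospital Newton inner optimization of
#' the random-intercept modes.  Random intercepts are modeled as independent
#' normals across the two components; their empirical correlation is
#' examined post hoc via [intercept_correlation()].
#'
#' @inheritParams fit_zinb
#' @param sigma2_init Initial random-intercept variances.
#' @param hessian Compute the numerical Hessian at the optimum for Wald
#'   standard errors (default `TRUE`).
#' @return Object of class `abx_zinb_mixed`: fixed effects per component,
#'   `theta`, `sigma2_count`, `sigma2_zero`, `blups` (tibble of posterior
#'   modes per hospital), `logLik`, `vcov`, convergence diagnostics.
#' @export
fit_zinb_mixed <- function(stays, outcome = "dot",
                           count_terms = character(),
                           zero_terms = count_terms,
                           control = zinb_control(),
                           sigma2_init = c(0.1, 0.1),
                           hessian = TRUE) {
  idx <- sorted_hospital_index(stays)
  stays <- idx$stays
  if (length(idx$hospitals) < 2) stop("need >= 2 hospitals")
  y <- prep_outcome(stays, outcome)
  if (all(y == 0) || all(y > 0)) {
    stop("need both zero and positive outcomes to fit a ZINB model")
  }
  d <- zinb_design(stays, count_terms, zero_terms)
  pc <- ncol(d$Xc)
  pz <- ncol(d$Xz)
  init <- fit_zinb(stays, outcome, count_terms, zero_terms,
    control = zinb_control(maxit = 150)
  )
  par0 <- c(
    init$beta_count, init$beta_zero, log(init$theta),
    log(sigma2_init[1]), log(sigma2_init[2])
  )
  nh <- length(idx$hospitals)
  warm <- matrix(0, nh, 2)
  npar <- pc + pz + 3
  nll <- function(par) {
    etac <- as.vector(d$Xc %*% par[1:pc]) + d$offset
    etaz <- as.vector(d$Xz %*% par[pc + 1:pz])
    res <- cpp_laplace_marginal(
      y, etac, etaz, exp(par[pc + pz + 1]),
      exp(par[pc + pz + 2]), exp(par[pc + pz + 3]), idx$start, warm
    )
    res$nll
  }
  lower <- c(
    rep(-30, pc + pz), control$log_theta_bounds[1],
    rep(control$log_sigma2_bounds[1], 2)
  )
  upper <- c(
    rep(30, pc + pz), control$log_theta_bounds[2],
    rep(control$log_sigma2_bounds[2], 2)
  )
  opt <- stats::optim(par0, nll,
    method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(
      maxit = control$maxit, pgtol = control$pgtol, factr = control$factr
    )
  )
  if (opt$convergence != 0 && opt$convergence != 52) {
    warning("outer optimizer returned code ", opt$convergence, ": ", opt$message)
  }
  par <- opt$par
  etac <- as.vector(d$Xc %*% par[1:pc]) + d$offset
  etaz <- as.vector(d$Xz %*% par[pc + 1:pz])
  final <- cpp_laplace_marginal(
    y, etac, etaz, exp(par[pc + pz + 1]),
    exp(par[pc + pz + 2]), exp(par[pc + pz + 3]), idx$start, warm
  )
  vc <- NULL
  se <- rep(NA_real_, npar)
  if (hessian) {
    H <- tryCatch(stats::optimHess(par, nll), error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc)) se <- sqrt(pmax(0, diag(vc)))
    }
  }
  par_names <- c(
    paste0("count_", colnames(d$Xc)), paste0("zero_", colnames(d$Xz)),
    "log_theta", "log_sigma2_count", "log_sigma2_zero"
  )
  s2 <- unname(exp(par[pc + pz + 2:3]))
  structure(
    list(
      beta_count = stats::setNames(par[1:pc], colnames(d$Xc)),
      beta_zero = stats::setNames(par[pc + 1:pz], colnames(d$Xz)),
      theta = unname(exp(par[pc + pz + 1])),
      sigma2_count = s2[1], sigma2_zero = s2[2],
      boundary = any(s2 < 1e-4),
      blups = tibble::tibble(
        hospital_id = idx$hospitals,
        b_count = final$modes[, 1], b_zero = final$modes[, 2]
      ),
      logLik = -opt$value, npar = npar,
      par = stats::setNames(par, par_names),
      se = stats::setNames(se, par_names), vcov = vc,
      outcome = outcome, count_terms = count_terms,
      zero_terms = union(zero_terms, "log_dp"),
      convergence = opt$convergence,
      n_stays = length(y), n_hospitals = nh
    ),
    class = "abx_zinb_mixed"
  )
}

#' @export
logLik.abx_zinb_mixed <- function(object, ...) {
  structure(object$logLik, df = object$npar, class = "logLik")
}

#' @export
#' @method print abx_zinb_mixed
print.abx_zinb_mixed <- function(x, ...) {
  cat("ZINB mixed model (", x$outcome, "), ", x$n_hospitals, " hospitals, ",
    x$n_stays, " stays\n",
    sep = ""
  )
  cat("  theta = ", signif(x$theta, 4),
    ", sigma2 (count, zero) = ", signif(x$sigma2_count, 4), ", ",
    signif(x$sigma2_zero, 4), "\n",
    sep = ""
  )
  cat("  logLik = ", round(x$logLik, 2), ", AIC = ", round(AIC(x), 2), "\n",
    sep = ""
  )
  invisible(x)
}

#' Fixed-effect table with Wald 95% confidence intervals
#'
#' @param model A fitted `abx_zinb_mixed`.
#' @param level Confidence level.
#' @return Tibble with component, term, estimate, SE and CI bounds.
#' @export
fixef_table <- function(model, level = 0.95) {
  stopifnot(inherits(model, "abx_zinb_mixed"))
  pc <- length(model$beta_count)
  pz <- length(model$beta_zero)
  est <- model$par[1:(pc + pz)]
  se <- model$se[1:(pc + pz)]
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    component = c(rep("count", pc), rep("zero", pz)),
    term = c(names(model$beta_count), names(model$beta_zero)),
    estimate = unname(est), se = unname(se),
    lower = unname(est - z * se), upper = unname(est + z * se)
  )
}

#' Re-estimate hospital random intercepts on new data
#'
#' Holds the fixed effects, dispersion and variance components of a fitted
#' model frozen and recomputes each hospital's random-intercept posterior
#' mode (BLUP) from a new set of stays — the evaluation-period scoring step.
#' Hospitals with no stays in the new data are omitted with a warning;
#' hospitals whose stays match the fixed-effect predictions have BLUPs near
#' zero, and small hospitals shrink toward zero.
#'
#' @param model A fitted `abx_zinb_mixed`.
#' @param stays Evaluation-period stay table.
#' @return Tibble (`hospital_id`, `b_count`, `b_zero`).
#' @export
reestimate_blups <- function(model, stays) {
  stopifnot(inherits(model, "abx_zinb_mixed"))
  missing <- setdiff(model$blups$hospital_id, unique(stays$hospital_id))
  if (length(missing) > 0) {
    warning(
      "hospital(s) absent from evaluation data, omitted: ",
      paste(missing, collapse = ", ")
    )
  }
  idx <- sorted_hospital_index(stays)
  stays <- idx$stays
  y <- prep_outcome(stays, model$outcome)
  d <- zinb_design(stays, model$count_terms, setdiff(model$zero_terms, "log_dp"))
  etac <- as.vector(d$Xc %*% model$beta_count) + d$offset
  etaz <- as.vector(d$Xz %*% model$beta_zero)
  warm <- matrix(0, length(idx$hospitals), 2)
  res <- cpp_laplace_marginal(
    y, etac, etaz, model$theta, model$sigma2_count, model$sigma2_zero,
    idx$start, warm
  )
  tibble::tibble(
    hospital_id = idx$hospitals,
    b_count = res$modes[, 1], b_zero = res$modes[, 2]
  )
}

#' Per-stay expected outcome under the ZINB mixed model
#'
#' The expectation is the mixture mean `(1 - pi) * mu`.  With `blups`
#' supplied the hospital intercepts enter both linear predictors
#' ("predicted"); with `blups = NULL` they are set to zero ("expected", the
#' standardized-hospital estimate).
#'
#' @param model A fitted `abx_zinb_mixed`.
#' @param stays Stay table.
#' @param blups Optional tibble from [reestimate_blups()].
#' @return Numeric vector of per-stay expectations (in `stays` order).
#' @export
expected_outcome <- function(model, stays, blups = NULL) {
  d <- zinb_design(stays, model$count_terms, setdiff(model$zero_terms, "log_dp"))
  etac <- as.vector(d$Xc %*% model$beta_count) + d$offset
  etaz <- as.vector(d$Xz %*% model$beta_zero)
  if (!is.null(blups)) {
    j <- match(stays$hospital_id, blups$hospital_id)
    if (anyNA(j)) {
      stop(
        "no BLUP for hospital(s): ",
        paste(unique(stays$hospital_id[is.na(j)]), collapse = ", ")
      )
    }
    etac <- etac + blups$b_count[j]
    etaz <- etaz + blups$b_zero[j]
  }
  (1 - stats::plogis(etaz)) * exp(etac)
}

#' Facility predicted-to-expected (P:E) ratios
#'
#' Aggregates per-stay BLUP-based predictions and fixed-effects-only
#' expectations to the facility level; the ratio benchmarks each hospital
#' against a hypothetical standardized hospital while shrinking
#' small-hospital estimates toward 1.
#'
#' @param model A fitted `abx_zinb_mixed` (baseline fit).
#' @param stays Evaluation-period stays.
#' @param blups BLUPs from [reestimate_blups()] on the same stays (computed
#'   if `NULL`).
#' @return Tibble (`hospital_id`, `predicted`, `expected`, `pe`).
#' @export
pe_ratios <- function(model, stays, blups = NULL) {
  if (is.null(blups)) blups <- reestimate_blups(model, stays)
  pred <- expected_outcome(model, stays, blups)
  expc <- expected_outcome(model, stays, NULL)
  agg <- stats::aggregate(
    cbind(predicted = pred, expected = expc),
    by = list(hospital_id = stays$hospital_id), FUN = sum
  )
  if (any(agg$expected <= 0)) stop("zero expected total for a facility")
  tibble::tibble(
    hospital_id = agg$hospital_id,
    predicted = agg$predicted, expected = agg$expected,
    pe = agg$predicted / agg$expected
  )
}

#' Random-intercept variance reduction between two fits
#'
#' Compares hospital-level random-intercept variances of an unadjusted
#' (intercept-only) and an adjusted model fitted to the same stays:
#' `reduction = 1 - sigma2_adjusted / sigma2_null` per component.  Negative
#' values mean adjustment increased the unexplained hospital-level variance
#' in that component.
#'
#' @param null_model,adjusted_model Fitted `abx_zinb_mixed` objects.
#' @return List with `count` and `zero` reduction fractions (`NA` with a
#'   message when the null variance is numerically zero).
#' @export
variance_reduction <- function(null_model, adjusted_model) {
  red <- function(s2n, s2a) {
    if (s2n < 1e-8) {
      return(NA_real_)
    }
    unname(1 - s2a / s2n)
  }
  list(
    count = red(null_model$sigma2_count, adjusted_model$sigma2_count),
    zero = red(null_model$sigma2_zero, adjusted_model$sigma2_zero)
  )
}
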