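#' Variable screening and selection
#'
#' Patient-level candidate variables (binary comorbidity/procedure flags)
#' pass a prevalence-and-correlation prescreen, then are selected for the
#' two ZINB components by LASSO run independently on K random subsets of the
#' data, keeping only variables selected in every subset (strict consensus).
#' Facility- and unit-level variables are then selected by backward
#' elimination on AIC with the patient-level consensus variables held fixed.
#'
#' @name selection
NULL

default_candidates <- function(stays) {
  grep("^(cm|pr)_", names(stays), value = TRUE)
}

#' Prescreen candidate variables by prevalence and univariate correlation
#'
#' A candidate passes when at least `floor` of patients carry the flag and
#' the Spearman rank correlation between the flag and the stay-level outcome
#' per 1000 DP is significant at `alpha`.  Constant flags fail the screen
#' without error.
#'
#' @param stays Stay table.
#' @param outcome Outcome column(s); with several (e.g. `c("dot", "dasc")`)
#'   a variable passes if it passes for any of them (union rule).
#' @param floor Minimum prevalence (default 0.005).
#' @param alpha Significance level for the correlation screen.
#' @param candidates Candidate columns (default: all `cm_*` / `pr_*` flags).
#' @return Tibble (`variable_id`, `prevalence`, `screen_p_value`, `passed`);
#'   with several outcomes, `screen_p_value` is the minimum across outcomes.
#' @export
prescreen_candidates <- function(stays, outcome = "dot", floor = 0.005,
                                 alpha = 0.05, candidates = NULL) {
  if (is.null(candidates)) candidates <- default_candidates(stays)
  rates <- lapply(outcome, function(o) rate_per_1000dp(stays[[o]], stays$dp))
  res <- lapply(candidates, function(v) {
    x <- stays[[v]]
    prev <- mean(x)
    if (prev <= 0 || prev >= 1) {
      return(tibble::tibble(
        variable_id = v, prevalence = prev,
        screen_p_value = NA_real_, passed = FALSE
      ))
    }
    pvals <- vapply(rates, function(r) {
      suppressWarnings(
        stats::cor.test(x, r, method = "spearman", exact = FALSE)$p.value
      )
    }, numeric(1))
    p <- min(pvals)
    tibble::tibble(
      variable_id = v, prevalence = prev, screen_p_value = p,
      passed = prev >= floor && is.finite(p) && p < alpha
    )
  })
  do.call(rbind, res)
}

# BIC along a glmnet path: deviance + log(n) * df (constant offset from
# -2 logLik is common to all lambdas, so the argmin is unchanged)
glmnet_pick_bic <- function(fit, n) {
  dev <- (1 - fit$dev.ratio) * fit$nulldev
  which.min(dev + log(n) * fit$df)
}

#' LASSO selection for one ZINB component
#'
#' Penalized selection of patient-level variables for the count or
#' zero-inflation component.  Because a jointly penalized ZINB is not a
#' standard fit, the two components alternate (count then zero, up to
#' `max_cycles` cycles): the count component is a weighted penalized Poisson
#' regression with `log(dp)` offset, weighted by the current probability
#' that each zero is not structural; the zero component is a penalized
#' logistic fit to the working structural-zero probabilities with `log(dp)`
#' unpenalized; the NB dispersion used to update the working probabilities
#' is re-estimated by moments each cycle.
#'
#' @param stays Stay subset (needs both zero and positive outcomes).
#' @param component `"count"` or `"zero"`.
#' @param outcome Outcome column.
#' @param candidates Candidate columns.
#' @param lambda_rule `"bic"` (default; deterministic), `"cv"`
#'   (10-fold `cv.glmnet`, folds derived from `seed`), or a numeric penalty
#'   used as-is.
#' @param max_cycles Alternation cycles.
#' @param seed Fold seed for `lambda_rule = "cv"`.
#' @return Character vector: the selected candidate variables.
#' @export
lasso_select_zinb <- function(stays, component = c("count", "zero"),
                              outcome = "dot", candidates = NULL,
                              lambda_rule = "bic", max_cycles = 5,
                              seed = 1L) {
  component <- match.arg(component)
  if (is.null(candidates)) candidates <- default_candidates(stays)
  y <- prep_outcome(stays, outcome)
  if (all(y == 0) || all(y > 0)) {
    stop("subset must contain both zero and positive outcomes")
  }
  n <- length(y)
  if (n < 50) stop("subset too small for penalized selection (n = ", n, ")")
  log_dp <- log(stays$dp)
  X <- as.matrix(stays[candidates])
  pad <- ncol(X) < 2
  if (pad) X <- cbind(X, .pad = 0)

  pick <- function(fit, n_eff) {
    if (is.numeric(lambda_rule)) {
      return(which.min(abs(fit$lambda - lambda_rule)))
    }
    glmnet_pick_bic(fit, n_eff)
  }
  fit_count <- function(w) {
    if (identical(lambda_rule, "cv")) {
      set.seed(as.integer(seed))
      foldid <- sample(rep(1:10, length.out = n))
      cv <- glmnet::cv.glmnet(X, y,
        family = "poisson", offset = log_dp,
        weights = 1 - w, foldid = foldid, nlambda = 50
      )
      return(list(fit = cv$glmnet.fit, i = which(cv$glmnet.fit$lambda == cv$lambda.min)[1]))
    }
    fit <- glmnet::glmnet(X, y,
      family = "poisson", offset = log_dp,
      weights = 1 - w, nlambda = 50,
      lambda.min.ratio = if (is.numeric(lambda_rule)) 1e-5 else 1e-3
    )
    list(fit = fit, i = pick(fit, n))
  }
  fit_zero <- function(w) {
    Xz <- cbind(X, log_dp = log_dp)
    pf <- c(rep(1, ncol(X)), 0) # log(dp) is a forced regular variable
    yz <- cbind(1 - w, w)
    if (identical(lambda_rule, "cv")) {
      set.seed(as.integer(seed) + 1L)
      foldid <- sample(rep(1:10, length.out = n))
      cv <- glmnet::cv.glmnet(Xz, yz,
        family = "binomial", penalty.factor = pf,
        foldid = foldid, nlambda = 50
      )
      return(list(
        fit = cv$glmnet.fit,
        i = which(cv$glmnet.fit$lambda == cv$lambda.min)[1], Xz = Xz
      ))
    }
    fit <- glmnet::glmnet(Xz, yz,
      family = "binomial", penalty.factor = pf, nlambda = 50,
      lambda.min.ratio = if (is.numeric(lambda_rule)) 1e-5 else 1e-3
    )
    list(fit = fit, i = pick(fit, n), Xz = Xz)
  }

  w <- ifelse(y == 0, 0.5, 0) # working P(structural zero)
  cfit <- zfit <- NULL
  theta <- 1
  for (cycle in seq_len(max_cycles)) {
    cfit <- fit_count(w)
    mu <- as.vector(exp(stats::predict(cfit$fit,
      newx = X, s = cfit$fit$lambda[cfit$i], newoffset = log_dp
    )))
    wc <- 1 - w
    num <- sum(wc * mu^2)
    den <- sum(wc * ((y - mu)^2 - mu))
    theta <- if (den > 0) min(max(num / den, 0.05), 1e4) else 1e4
    zfit <- fit_zero(w)
    eta_z <- as.vector(stats::predict(zfit$fit,
      newx = zfit$Xz, s = zfit$fit$lambda[zfit$i]
    ))
    pi <- stats::plogis(eta_z)
    p0 <- (theta / (theta + mu))^theta
    w_new <- ifelse(y == 0, pi / (pi + (1 - pi) * p0), 0)
    if (max(abs(w_new - w)) < 1e-4 && cycle > 1) {
      w <- w_new
      break
    }
    w <- w_new
  }
  chosen <- if (component == "count") cfit else zfit
  beta <- as.matrix(stats::coef(chosen$fit, s = chosen$fit$lambda[chosen$i]))
  nz <- rownames(beta)[abs(beta[, 1]) > 1e-10]
  intersect(candidates, nz)
}

#' Consensus LASSO selection over K random subsets
#'
#' Partitions stays into K disjoint random subsets (stratified by hospital,
#' so every subset contains every hospital), runs [lasso_select_zinb()] for
#' both components on each subset, and keeps only variables selected in all
#' K subsets.
#'
#' @inheritParams lasso_select_zinb
#' @param K Number of subsets (default 10).
#' @param seed Partition seed.
#' @return Object of class `abx_consensus`: `per_subset` (lists of selected
#'   sets per component), `consensus` (their K-way intersections), `K`,
#'   `seed`.
#' @export
consensus_select <- function(stays, outcome = "dot", candidates = NULL,
                             K = 10, seed = 1L, lambda_rule = "bic",
                             max_cycles = 5) {
  stopifnot(K >= 1)
  if (is.null(candidates)) candidates <- default_candidates(stays)
  set.seed(as.integer(seed))
  subset_id <- integer(nrow(stays))
  for (h in unique(stays$hospital_id)) {
    idx <- which(stays$hospital_id == h)
    subset_id[idx] <- sample(rep_len(seq_len(K), length(idx)))
  }
  run <- function(k, component) {
    lasso_select_zinb(stays[subset_id == k, , drop = FALSE],
      component = component, outcome = outcome, candidates = candidates,
      lambda_rule = lambda_rule, max_cycles = max_cycles, seed = seed + k
    )
  }
  per_subset <- list(
    count = lapply(seq_len(K), run, component = "count"),
    zero = lapply(seq_len(K), run, component = "zero")
  )
  consensus <- lapply(per_subset, function(sets) Reduce(intersect, sets))
  if (all(lengths(consensus) == 0)) {
    warning("consensus selection is empty for both components")
  }
  structure(
    list(
      per_subset = per_subset, consensus = consensus,
      K = K, seed = seed, subset_id = subset_id
    ),
    class = "abx_consensus"
  )
}

#' @export
#' @method print abx_consensus
print.abx_consensus <- function(x, ...) {
  cat("Consensus selection over", x$K, "subsets\n")
  for (comp in names(x$consensus)) {
    cat(
      "  ", comp, ": ",
      if (length(x$consensus[[comp]]) == 0) {
        "(empty)"
      } else {
        paste(x$consensus[[comp]], collapse = ", ")
      }, "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Backward elimination of candidate terms by AIC
#'
#' Starting from the model containing all `fixed_in` and `candidates`
#' terms, repeatedly removes the candidate whose removal lowers AIC the
#' most, until no single removal lowers it.  `fixed_in` terms are never
#' dropped; a candidate whose removal makes the fit fail is kept (with a
#' warning).  Categorical terms enter and leave as whole terms.
#'
#' @param aic_fun Function taking a character vector of model terms and
#'   returning the fitted model's AIC (scalar).
#' @param fixed_in Terms always kept in the model.
#' @param candidates Terms eligible for elimination.
#' @return List: `selected` (surviving candidates), `terms` (full final term
#'   set), `aic` (final AIC), `trace` (tibble logging each elimination
#'   step).
#' @export
backward_aic <- function(aic_fun, fixed_in = character(), candidates) {
  current <- candidates
  aic_now <- aic_fun(c(fixed_in, current))
  trace <- list(tibble::tibble(
    step = 0L, dropped = NA_character_, aic = aic_now
  ))
  step <- 0L
  while (length(current) > 0) {
    step <- step + 1L
    aics <- vapply(current, function(v) {
      tryCatch(
        aic_fun(c(fixed_in, setdiff(current, v))),
        error = function(e) {
          warning("fit without '", v, "' failed, keeping it: ",
            conditionMessage(e),
            call. = FALSE
          )
          Inf
        }
      )
    }, numeric(1))
    if (min(aics) >= aic_now - 1e-8) break
    drop <- current[which.min(aics)]
    current <- setdiff(current, drop)
    aic_now <- min(aics)
    trace[[length(trace) + 1L]] <- tibble::tibble(
      step = step, dropped = drop, aic = aic_now
    )
  }
  list(
    selected = current, terms = c(fixed_in, current),
    aic = aic_now, trace = do.call(rbind, trace)
  )
}

#' AIC closure for the unit-month NB model
#'
#' @param records Unit-month records.
#' @param outcome Outcome column.
#' @return Function mapping a term vector to the model AIC, for
#'   [backward_aic()].
#' @export
nb_aic_fun <- function(records, outcome = "dot") {
  function(terms) stats::AIC(fit_nb(records, outcome, terms)$fit)
}

#' AIC closure for the ZINB mixed model
#'
#' Facility/unit candidates enter both components jointly (one term unit).
#'
#' @param stays Stay table.
#' @param outcome Outcome column.
#' @param control See [zinb_control()].
#' @return Function mapping a term vector to the marginal AIC.
#' @export
zinb_mixed_aic_fun <- function(stays, outcome = "dot",
                               control = zinb_control(maxit = 200)) {
  function(terms) {
    stats::AIC(fit_zinb_mixed(stays,
      outcome = outcome,
      count_terms = terms, zero_terms = terms,
      control = control, hessian = FALSE
    ))
  }
}
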