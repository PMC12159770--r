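# fabricate a frozen model object with known parameters (for BLUP tests)
frozen_model <- function(hospitals, beta_count, beta_zero, theta,
                         sigma2_count, sigma2_zero,
                         count_terms, zero_terms) {
  structure(
    list(
      beta_count = beta_count, beta_zero = beta_zero, theta = theta,
      sigma2_count = sigma2_count, sigma2_zero = sigma2_zero,
      blups = tibble::tibble(
        hospital_id = hospitals, b_count = 0, b_zero = 0
      ),
      outcome = "dot",
      count_terms = count_terms, zero_terms = union(zero_terms, "log_dp")
    ),
    class = "abx_zinb_mixed"
  )
}

test_that("the ZINB stay likelihood reduces to plain NB without inflation", {
  set.seed(5)
  y <- rnbinom(200, mu = 4, size = 1.5)
  etac <- rep(log(4), 200)
  etaz <- rep(-40, 200) # pi = 0
  ll_r <- sum(abxbench:::zinb_stay_loglik_r(y, etac, etaz, 1.5))
  ll_nb <- sum(dnbinom(y, mu = 4, size = 1.5, log = TRUE))
  expect_equal(ll_r, ll_nb, tolerance = 1e-10)
  # compiled and R paths agree across a spread of predictors
  etac <- rnorm(200, 1, 1)
  etaz <- rnorm(200, 0, 1.5)
  expect_equal(
    -abxbench:::cpp_zinb_negll(y, etac, etaz, 0.8),
    sum(abxbench:::zinb_stay_loglik_r(y, etac, etaz, 0.8)),
    tolerance = 1e-10
  )
})

test_that("Laplace marginal likelihood matches dense-grid integration", {
  cf <- recovery_config(n_hospitals = 4, stays = 15)
  co <- simulate_cohort(cf, seed = 77)
  bt <- cf$beta_count[c("(Intercept)", "age_std", "icu_stay")]
  bz <- c(
    cf$beta_zero[c("(Intercept)", "age_std", "icu_stay")],
    log_dp = cf$gamma_zero_logdp
  )
  la <- zinb_marginal_loglik(co$stays, "dot", recovery_terms, recovery_terms,
    bt, bz, cf$theta, cf$sigma_count^2, cf$sigma_zero^2,
    method = "laplace"
  )
  gr <- zinb_marginal_loglik(co$stays, "dot", recovery_terms, recovery_terms,
    bt, bz, cf$theta, cf$sigma_count^2, cf$sigma_zero^2,
    method = "grid", grid_nodes = 181
  )
  expect_lt(abs(la - gr) / abs(gr), 1e-3)
  # per-hospital contributions agree too
  expect_equal(
    attr(la, "by_hospital"), attr(gr, "by_hospital"),
    tolerance = 1e-3
  )
})

test_that("plain and mixed ZINB fits agree with glmmTMB", {
  cf <- recovery_config(n_hospitals = 15, stays = 150)
  co <- simulate_cohort(cf, seed = 19)
  d <- co$stays

  own <- fit_zinb(d, "dot", recovery_terms, recovery_terms)
  tmb <- glmmTMB::glmmTMB(
    dot ~ age_std + icu_stay + offset(log_dp),
    ziformula = ~ age_std + icu_stay + log_dp,
    family = glmmTMB::nbinom2, data = d
  )
  expect_equal(
    unname(own$beta_count),
    unname(glmmTMB::fixef(tmb)$cond),
    tolerance = 1e-3
  )
  expect_equal(
    unname(own$beta_zero[c(1, 2, 3, 4)]),
    unname(glmmTMB::fixef(tmb)$zi[c(1, 2, 3, 4)]),
    tolerance = 1e-3
  )
  expect_equal(own$theta, glmmTMB::sigma(tmb), tolerance = 1e-3)

  own_m <- fit_zinb_mixed(d, "dot", recovery_terms, recovery_terms,
    hessian = FALSE
  )
  tmb_m <- glmmTMB::glmmTMB(
    dot ~ age_std + icu_stay + offset(log_dp) + (1 | hospital_id),
    ziformula = ~ age_std + icu_stay + log_dp + (1 | hospital_id),
    family = glmmTMB::nbinom2, data = d
  )
  expect_equal(
    unname(own_m$beta_count),
    unname(glmmTMB::fixef(tmb_m)$cond),
    tolerance = 0.01
  )
  expect_equal(
    unname(own_m$beta_zero),
    unname(glmmTMB::fixef(tmb_m)$zi),
    tolerance = 0.01
  )
  vc <- glmmTMB::VarCorr(tmb_m)
  expect_equal(
    own_m$sigma2_count,
    unname(attr(vc$cond$hospital_id, "stddev"))^2,
    tolerance = 0.05
  )
  expect_equal(
    own_m$sigma2_zero,
    unname(attr(vc$zi$hospital_id, "stddev"))^2,
    tolerance = 0.05
  )
  expect_equal(own_m$logLik, as.numeric(logLik(tmb_m)), tolerance = 1e-4)
  # BLUP posterior modes agree with glmmTMB's random-effect modes
  re <- glmmTMB::ranef(tmb_m)
  expect_equal(
    own_m$blups$b_count,
    re$cond$hospital_id[own_m$blups$hospital_id, 1],
    tolerance = 0.01
  )
})

test_that("sigma = 0 data give a near-boundary fit matching plain ZINB", {
  cf <- recovery_config(n_hospitals = 15, stays = 150, sigma_count = 0,
    sigma_zero = 0)
  co <- simulate_cohort(cf, seed = 23)
  plain <- fit_zinb(co$stays, "dot", recovery_terms, recovery_terms)
  mixed <- fit_zinb_mixed(co$stays, "dot", recovery_terms, recovery_terms,
    hessian = FALSE
  )
  expect_lt(mixed$sigma2_count, 0.01)
  expect_lt(mixed$sigma2_zero, 0.02)
  expect_equal(
    unname(mixed$beta_count), unname(plain$beta_count),
    tolerance = 0.02
  )
  expect_equal(
    unname(mixed$beta_zero), unname(plain$beta_zero),
    tolerance = 0.03
  )
})

test_that("the maximized likelihood is invariant to hospital relabeling", {
  cf <- recovery_config(n_hospitals = 8, stays = 80)
  co <- simulate_cohort(cf, seed = 3)
  d <- co$stays
  m1 <- fit_zinb_mixed(d, "dot", recovery_terms, hessian = FALSE)
  set.seed(1)
  relab <- setNames(
    sample(sprintf("Z%02d", 1:8)),
    unique(d$hospital_id)
  )
  d2 <- d
  d2$hospital_id <- unname(relab[d$hospital_id])
  m2 <- fit_zinb_mixed(d2, "dot", recovery_terms, hessian = FALSE)
  expect_equal(m1$logLik, m2$logLik, tolerance = 1e-5)
})

test_that("BLUP re-estimation recovers planted intercepts as n grows", {
  design <- sim_config()$design
  b <- sparse_betas(design,
    count = c("(Intercept)" = log(0.9), age_std = 0.1, icu_stay = 0.3),
    zero = c("(Intercept)" = 0.6, age_std = -0.15, icu_stay = -0.8)
  )
  bt <- c(`(Intercept)` = log(0.9), age_std = 0.1, icu_stay = 0.3)
  bz <- c(`(Intercept)` = 0.6, age_std = -0.15, icu_stay = -0.8, log_dp = -0.4)
  planted <- c(b_count = 0.45, b_zero = -0.35)
  err <- sapply(c(60, 600, 6000), function(n) {
    cf <- sim_config(
      n_hospitals = 2, stays_per_hospital = c(n, n),
      beta_count = b$count, beta_zero = b$zero,
      sigma_count = 0.3, sigma_zero = 0.4, rho = 0, dasc = FALSE
    )
    co <- simulate_cohort(cf, seed = 100 + n, intercepts = tibble::tibble(
      hospital_id = c("H001", "H002"),
      b_count_dot = c(planted["b_count"], 0),
      b_zero_dot = c(planted["b_zero"], 0)
    ))
    mod <- frozen_model(c("H001", "H002"), bt, bz, 1.5, 0.09, 0.16,
      recovery_terms, recovery_terms
    )
    bl <- reestimate_blups(mod, co$stays)
    abs(bl$b_count[bl$hospital_id == "H001"] - planted["b_count"])
  })
  expect_lt(err[3], 0.1)
  expect_lt(err[3], err[1] + 0.05) # error shrinks with information
})

test_that("BLUPs shrink toward zero relative to the unshrunk offset", {
  design <- sim_config()$design
  b <- sparse_betas(design,
    count = c("(Intercept)" = log(0.9)), zero = c("(Intercept)" = 0.3)
  )
  cf <- sim_config(
    n_hospitals = 4, stays_per_hospital = c(1, 1),
    beta_count = b$count, beta_zero = b$zero, gamma_zero_logdp = 0,
    sigma_count = 0.3, sigma_zero = 0.4, rho = 0, dasc = FALSE
  )
  co <- simulate_cohort(cf, seed = 55)
  # keep hospitals whose single stay used antibiotics
  keep <- co$stays$dot > 0
  stays <- co$stays[keep, , drop = FALSE]
  expect_gt(nrow(stays), 0)
  bt <- c(`(Intercept)` = log(0.9))
  bz <- c(`(Intercept)` = 0.3, log_dp = 0)
  mod <- frozen_model(stays$hospital_id, bt, bz, 1.5, 0.09, 0.16,
    character(), character()
  )
  suppressWarnings(bl <- reestimate_blups(mod, stays))
  for (i in seq_len(nrow(stays))) {
    # unshrunk count offset: matches the single observed count exactly
    ml_c <- log(stays$dot[i]) - (log(0.9) + stays$log_dp[i])
    bi <- bl$b_count[bl$hospital_id == stays$hospital_id[i]]
    expect_lt(abs(bi), abs(ml_c) + 1e-8)
    expect_gt(abs(ml_c) - abs(bi), -1e-8)
  }
  # a hospital absent from the evaluation data is omitted with a warning
  mod2 <- frozen_model(c(stays$hospital_id, "H999"), bt, bz, 1.5, 0.09, 0.16,
    character(), character()
  )
  expect_warning(bl2 <- reestimate_blups(mod2, stays), "H999")
  expect_false("H999" %in% bl2$hospital_id)
})

test_that("P:E ratios are 1 under zero BLUPs and track planted effects", {
  cf <- recovery_config(n_hospitals = 10, stays = 120)
  co <- simulate_cohort(cf, seed = 9)
  m <- fit_zinb_mixed(co$stays, "dot", recovery_terms, hessian = FALSE)
  zero_blups <- tibble::tibble(
    hospital_id = m$blups$hospital_id, b_count = 0, b_zero = 0
  )
  pe0 <- pe_ratios(m, co$stays, zero_blups)
  expect_equal(pe0$pe, rep(1, nrow(pe0)), tolerance = 1e-12)

  # doubling a hospital's count intercept raises its P:E accordingly
  bump <- zero_blups
  bump$b_count[1] <- log(1.5)
  pe1 <- pe_ratios(m, co$stays, bump)
  expect_equal(pe1$pe[1], 1.5, tolerance = 1e-10)
  expect_equal(pe1$pe[-1], rep(1, nrow(pe1) - 1), tolerance = 1e-12)
})

test_that("variance reduction is 0 against itself and large when case mix
           mediates hospital differences", {
  cf <- recovery_config(n_hospitals = 12, stays = 120)
  co <- simulate_cohort(cf, seed = 14)
  m <- fit_zinb_mixed(co$stays, "dot", recovery_terms, hessian = FALSE)
  expect_equal(variance_reduction(m, m), list(count = 0, zero = 0))

  # hospital differences driven entirely by observable case mix
  design <- sim_config()$design
  b <- sparse_betas(design,
    count = c(
      "(Intercept)" = log(0.9), cm_01 = 0.5, cm_02 = 0.45, cm_03 = 0.4,
      pr_01 = 0.45, pr_02 = 0.4, pr_03 = 0.35
    ),
    zero = c("(Intercept)" = 0.6, cm_01 = -0.5, cm_02 = -0.4)
  )
  cfm <- sim_config(
    n_hospitals = 15, stays_per_hospital = c(200, 200),
    beta_count = b$count, beta_zero = b$zero,
    sigma_count = 0, sigma_zero = 0, case_mix_sd = 2, rho = 0, dasc = FALSE
  )
  com <- simulate_cohort(cfm, seed = 26)
  flags <- c("cm_01", "cm_02", "cm_03", "pr_01", "pr_02", "pr_03")
  null_m <- fit_zinb_mixed(com$stays, "dot", character(), character(),
    hessian = FALSE
  )
  adj_m <- fit_zinb_mixed(com$stays, "dot", flags, flags, hessian = FALSE)
  vr <- variance_reduction(null_m, adj_m)
  expect_gt(vr$count, 0.5)
  expect_gt(null_m$sigma2_count, adj_m$sigma2_count)
})
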