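# linear predictors implied by the generator's truth, recomputed directly
truth_linpred <- function(cohort) {
  cf <- cohort$truth$config
  s <- cohort$stays
  flag_names <- grep("^(cm|pr)_", cf$design, value = TRUE)
  X <- cbind(
    1, s$age_std, s$sex, s$icu_stay, s$surgical_specialty,
    as.matrix(s[flag_names])
  )
  b <- cohort$truth$intercepts
  j <- match(s$hospital_id, b$hospital_id)
  list(
    etac = as.vector(X %*% cf$beta_count) + s$log_dp + b$b_count_dot[j],
    etaz = as.vector(X %*% cf$beta_zero) +
      cf$gamma_zero_logdp * s$log_dp + b$b_zero_dot[j]
  )
}

test_that("cohorts are byte-identical for identical config and seed", {
  cf <- sim_config(n_hospitals = 6, stays_per_hospital = c(40, 60))
  a <- simulate_cohort(cf, seed = 5)
  b <- simulate_cohort(cf, seed = 5)
  expect_identical(a, b)
  c <- simulate_cohort(cf, seed = 6)
  expect_false(identical(a$stays$dot, c$stays$dot))
})

test_that("covariate prevalences match their configured values", {
  cf <- sim_config(
    n_hospitals = 30, stays_per_hospital = c(300, 300),
    prevalence_range = c(0.05, 0.25)
  )
  co <- simulate_cohort(cf, seed = 21)
  n <- nrow(co$stays)
  # each flag's sample prevalence within 3 binomial SEs of the drawn target
  # (targets are drawn from prevalence_range with the same seed stream, so
  # check the admissible envelope: range widened by 3 SEs at its edges)
  for (v in grep("^(cm|pr)_", names(co$stays), value = TRUE)) {
    p <- mean(co$stays[[v]])
    se <- sqrt(0.25 / n)
    expect_gte(p, 0.05 - 3 * sqrt(0.05 * 0.95 / n))
    expect_lte(p, 0.25 + 3 * sqrt(0.25 * 0.75 / n))
    expect_gt(p, 0)
    expect_lt(p, 1)
  }
  expect_error(
    sim_config(prevalence_range = c(0.001, 0.2)),
    "floor"
  )
})

test_that("zero fraction matches the closed-form mixture oracle", {
  cf <- sim_config(
    n_hospitals = 50, stays_per_hospital = c(400, 400),
    sigma_count = 0, sigma_zero = 0, dasc = FALSE
  )
  co <- simulate_cohort(cf, seed = 31)
  lp <- truth_linpred(co)
  pi <- stats::plogis(lp$etaz)
  p0 <- (cf$theta / (cf$theta + exp(lp$etac)))^cf$theta
  expected_zero <- mean(pi + (1 - pi) * p0)
  observed_zero <- mean(co$stays$dot == 0)
  se <- sqrt(expected_zero * (1 - expected_zero) / nrow(co$stays))
  expect_lt(abs(observed_zero - expected_zero), 4 * se)
})

test_that("degenerate configurations reduce to their closed-form limits", {
  design <- sim_config()$design
  # zero-inflation forced on: every outcome is zero
  b <- sparse_betas(design, zero = c("(Intercept)" = 30))
  cf <- sim_config(
    n_hospitals = 5, stays_per_hospital = c(50, 50),
    beta_count = b$count, beta_zero = b$zero, gamma_zero_logdp = 0,
    sigma_count = 0, sigma_zero = 0, dasc = FALSE
  )
  co <- simulate_cohort(cf, seed = 4)
  expect_true(all(co$stays$dot == 0))

  # zero-inflation off, large theta: Poisson-like mean/variance of Y
  b2 <- sparse_betas(design, count = c("(Intercept)" = log(0.8)),
    zero = c("(Intercept)" = -30))
  cf2 <- sim_config(
    n_hospitals = 10, stays_per_hospital = c(600, 600),
    beta_count = b2$count, beta_zero = b2$zero, gamma_zero_logdp = 0,
    theta = 1e6, sigma_count = 0, sigma_zero = 0, dasc = FALSE
  )
  co2 <- simulate_cohort(cf2, seed = 8)
  mu <- 0.8 * co2$stays$dp
  z <- (co2$stays$dot - mu) / sqrt(mu) # Poisson-standardized residuals
  expect_lt(abs(mean(z)), 4 / sqrt(length(z)))
  expect_lt(abs(var(z) - 1), 0.1)
})

test_that("marginal stratum mean matches (1 - pi) * mu when sigma = 0", {
  cf <- sim_config(
    n_hospitals = 40, stays_per_hospital = c(400, 400),
    sigma_count = 0, sigma_zero = 0, dasc = FALSE
  )
  co <- simulate_cohort(cf, seed = 17)
  lp <- truth_linpred(co)
  m <- (1 - stats::plogis(lp$etaz)) * exp(lp$etac)
  # stratum: ICU stays
  idx <- co$stays$icu_stay == 1
  se <- stats::sd(co$stays$dot[idx]) / sqrt(sum(idx))
  expect_lt(abs(mean(co$stays$dot[idx]) - mean(m[idx])), 3.5 * se)
})

test_that("split_periods partitions stays and keeps every hospital", {
  cf <- sim_config(n_hospitals = 10, stays_per_hospital = c(300, 300))
  co <- simulate_cohort(cf, seed = 2)
  sp <- split_periods(co, fraction = 0.67, seed = 3)
  expect_equal(
    sort(c(sp$baseline$stays$stay_id, sp$evaluation$stays$stay_id)),
    sort(co$stays$stay_id)
  )
  expect_length(
    intersect(sp$baseline$stays$stay_id, sp$evaluation$stays$stay_id), 0
  )
  nb <- table(sp$baseline$stays$hospital_id)
  ne <- table(sp$evaluation$stays$hospital_id)
  expect_true(all(abs(nb - 201) <= 1))
  expect_true(all(abs(ne - 99) <= 1))
  expect_identical(sp$baseline$truth, sp$evaluation$truth)

  # calendar split keeps every hospital too
  sp2 <- split_periods(co)
  expect_setequal(
    unique(sp2$evaluation$stays$hospital_id),
    unique(co$stays$hospital_id)
  )
})

test_that("evaluation crude rates track the true hospital intercepts", {
  cf <- sim_config(
    n_hospitals = 40, stays_per_hospital = c(300, 300),
    sigma_count = 0.4, sigma_zero = 0, case_mix_sd = 0, dasc = FALSE
  )
  co <- simulate_cohort(cf, seed = 13)
  ev <- split_periods(co)$evaluation
  fac <- aggregate_facility(ev$stays)
  j <- match(fac$hospital_id, co$truth$intercepts$hospital_id)
  rho <- stats::cor(fac$crude_dot_rate, co$truth$intercepts$b_count_dot[j],
    method = "spearman"
  )
  expect_gt(rho, 0.5)
})

test_that("agent-day expansion is consistent with simulated DOT", {
  stays <- small_cohort(seed = 6)$stays
  ad <- simulate_agent_days(stays, toy_spectrum_table(), seed = 9)
  expect_false(anyDuplicated(ad[c("stay_id", "agent_id")]) > 0)
  dot <- compute_dot(ad)
  j <- match(dot$stay_id, stays$stay_id)
  expect_equal(dot$dot, stays$dot[j])
  expect_true(all(ad$n_days >= 1))
  expect_true(all(ad$n_days <= stays$dp[match(ad$stay_id, stays$stay_id)]))
})
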