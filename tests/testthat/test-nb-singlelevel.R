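test_that("intercept-only NB fit reproduces the pooled rate", {
  # the NB2 score equation weights records by theta/(theta + mu); with a
  # common exposure the weights are equal and the fitted rate is exactly
  # the pooled rate
  rec <- simulate_unit_month_records(300, seed = 4)
  rec$dp <- 800L
  set.seed(4)
  rec$dot <- rnbinom(300, mu = 0.45 * rec$dp, size = 2)
  m <- fit_nb(rec, "dot", character())
  pooled <- sum(rec$dot) / sum(rec$dp)
  expect_equal(unname(exp(coef(m$fit)[1])), pooled, tolerance = 1e-6)
  # with varying exposure the identity holds approximately
  rec2 <- simulate_unit_month_records(500, seed = 5)
  m2 <- fit_nb(rec2, "dot", character())
  expect_equal(unname(exp(coef(m2$fit)[1])),
    sum(rec2$dot) / sum(rec2$dp),
    tolerance = 0.1
  )
})

test_that("NB2 recovery on simulated unit-months (coefficients and theta)", {
  truth <- c(
    "(Intercept)" = log(0.45), icu_floor = 0.45,
    surgical_floor = -0.2, acuity = 0.15
  )
  ests <- sapply(1:5, function(s) {
    rec <- simulate_unit_month_records(2000, beta = truth, theta = 2, seed = s)
    m <- fit_nb(rec, "dot", c("icu_floor", "surgical_floor", "acuity"))
    c(coef(m$fit), theta = m$theta)
  })
  bias <- rowMeans(ests[1:4, ]) - truth
  expect_lt(max(abs(bias)), 0.02)
  expect_lt(abs(mean(ests["theta", ]) - 2) / 2, 0.10)
})

test_that("Poisson-generated data drive theta large and match a Poisson fit", {
  set.seed(10)
  n <- 1500
  icu <- rbinom(n, 1, 0.2)
  dp <- as.integer(round(exp(runif(n, log(200), log(2000)))))
  rec <- tibble::tibble(
    hospital_id = "H1", unit_id = sprintf("U%d", 1:n), month = 1L,
    icu_floor = icu, dp = dp,
    dot = rpois(n, 0.4 * dp * exp(0.3 * icu))
  )
  m <- fit_nb(rec, "dot", "icu_floor")
  expect_gt(m$theta, 100)
  pois <- glm(dot ~ icu_floor + offset(log(dp)), poisson(), rec)
  expect_equal(unname(coef(m$fit)), unname(coef(pois)), tolerance = 0.01)
})

test_that("O:E ratios balance in sample and scale with observed outcome", {
  # constant exposure makes the saturated-by-facility NB2 score equation
  # equalize observed and expected exactly within each facility
  set.seed(30)
  n <- 240
  rec <- tibble::tibble(
    hospital_id = rep(sprintf("H%02d", 1:8), each = 30),
    unit_id = sprintf("U%03d", 1:n), month = 1L,
    dp = 600L,
    icu_floor = rbinom(n, 1, 0.2), surgical_floor = rbinom(n, 1, 0.4)
  )
  rec$dot <- rnbinom(n, mu = 0.45 * rec$dp * exp(0.2 * (rec$hospital_id ==
    "H01")), size = 3)
  m <- fit_nb(rec, "dot", "hospital_id")
  oe <- oe_ratios(m, rec)
  expect_equal(oe$oe, rep(1, nrow(oe)), tolerance = 1e-6)

  # an intercept model balances the totals
  m0 <- fit_nb(rec, "dot", "icu_floor")
  oe0 <- oe_ratios(m0, rec)
  expect_equal(sum(oe0$observed) / sum(oe0$expected), 1, tolerance = 1e-6)
  expect_true(all(oe0$lower <= oe0$oe & oe0$oe <= oe0$upper))

  # doubling one facility's observed counts post fit doubles its O:E
  rec2 <- rec
  idx <- rec2$hospital_id == oe0$hospital_id[1]
  rec2$dot[idx] <- 2 * rec2$dot[idx]
  oe2 <- oe_ratios(m0, rec2)
  expect_equal(oe2$oe[1], 2 * oe0$oe[1], tolerance = 1e-10)
})

test_that("planted facility effect is recovered by O:E", {
  design <- sim_config()$design
  b <- sparse_betas(design,
    count = c("(Intercept)" = log(0.9), icu_stay = 0.3),
    zero = c("(Intercept)" = -0.2, icu_stay = -0.5)
  )
  cf <- sim_config(
    n_hospitals = 12, stays_per_hospital = c(500, 500),
    beta_count = b$count, beta_zero = b$zero,
    sigma_count = 0, sigma_zero = 0, rho = 0, dasc = FALSE
  )
  co <- simulate_cohort(cf, seed = 44, intercepts = tibble::tibble(
    hospital_id = "H003", b_count_dot = log(1.5)
  ))
  sp <- split_periods(co)
  umb <- aggregate_unit_month(sp$baseline$stays, co$units, co$facilities)
  ume <- aggregate_unit_month(sp$evaluation$stays, co$units, co$facilities)
  m <- fit_nb(umb, "dot", "icu_floor")
  oe <- oe_ratios(m, ume)
  planted <- oe$oe[oe$hospital_id == "H003"]
  others <- oe$oe[oe$hospital_id != "H003"]
  expect_gt(planted, 1.3)
  expect_lt(planted, 1.7)
  expect_true(all(others < planted))
  expect_lt(abs(median(others) - 1), 0.1)
})

test_that("evaluation scoring rejects unseen covariate levels", {
  rec <- simulate_unit_month_records(200, seed = 6)
  rec$region <- factor(rep(c("east", "west"), 100))
  m <- fit_nb(rec, "dot", "region")
  rec2 <- rec
  levels(rec2$region) <- c("east", "north")
  expect_error(oe_ratios(m, rec2), "north")
})

test_that("length-of-stay quintile cut points freeze on baseline data", {
  co <- small_cohort(seed = 31)
  um <- aggregate_unit_month(co$stays)
  um <- assign_los_quintiles(um)
  cuts <- attr(um, "los_cutpoints")
  expect_length(cuts, 4)
  expect_true(all(table(um$avg_los_quintile) > 0))
  # applying frozen cuts to shifted data must not recompute them
  um2 <- um
  um2$dp <- um2$dp * 3
  um2 <- assign_los_quintiles(um2, cutpoints = cuts)
  expect_identical(attr(um2, "los_cutpoints"), cuts)
  expect_true(mean(as.integer(um2$avg_los_quintile) >= 4) > 0.8)
})
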