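# Small in-code fixtures shared across test files.

# a tiny stay table with hand-checkable values
tiny_stays <- function() {
  tibble::tibble(
    stay_id = c("S1", "S2", "S3", "S4"),
    hospital_id = c("H1", "H1", "H2", "H2"),
    unit_id = c("H1_U1", "H1_U1", "H2_U1", "H2_U2"),
    month = c(1L, 1L, 1L, 2L),
    dp = c(5L, 10L, 4L, 8L),
    dot = c(6L, 0L, 3L, 9L),
    dasc = c(30, 0, 12, 40)
  )
}

# small simulated cohort for structural tests (fast)
small_cohort <- function(seed = 42, ...) {
  cf <- sim_config(
    n_hospitals = 8, stays_per_hospital = c(60, 90),
    n_comorbidity = 4, n_procedure = 4, ...
  )
  simulate_cohort(cf, seed = seed)
}

# beta vectors with nonzero effects only on the named design columns, for
# parameter-recovery settings where the fitted model matches the generator
sparse_betas <- function(config_design, count = c(), zero = c()) {
  bc <- stats::setNames(numeric(length(config_design)), config_design)
  bz <- bc
  bc[names(count)] <- count
  bz[names(zero)] <- zero
  list(count = bc, zero = bz)
}

# config whose fixed effects involve exactly the modeled terms
recovery_config <- function(n_hospitals = 40, stays = 400,
                            sigma_count = 0.3, sigma_zero = 0.4,
                            theta = 1.5, rho = 0) {
  design <- sim_config()$design
  b <- sparse_betas(design,
    count = c("(Intercept)" = log(0.9), age_std = 0.10, icu_stay = 0.30),
    zero = c("(Intercept)" = 0.6, age_std = -0.15, icu_stay = -0.80)
  )
  sim_config(
    n_hospitals = n_hospitals, stays_per_hospital = c(stays, stays),
    beta_count = b$count, beta_zero = b$zero,
    theta = theta, sigma_count = sigma_count, sigma_zero = sigma_zero,
    rho = rho, dasc = FALSE
  )
}

recovery_terms <- c("age_std", "icu_stay")

# brute-force tau-b: explicit loop over pairs counting concordant,
# discordant and tied pairs (independent of the package implementation)
tau_b_bruteforce <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]
      dy <- y[i] - y[j]
      if (dx == 0 && dy == 0) {
        tx <- tx + 1
        ty <- ty + 1
      } else if (dx == 0) {
        tx <- tx + 1
      } else if (dy == 0) {
        ty <- ty + 1
      } else if (dx * dy > 0) {
        C <- C + 1
      } else {
        D <- D + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# cohort with three strong planted patient-level effects among noise flags
planted_cohort <- function(n_hospitals = 10, stays = 500, n_noise = 40,
                           seed = 1, effect = 0.5) {
  n_cm <- 3 + ceiling(n_noise / 2)
  n_pr <- floor(n_noise / 2)
  cf0 <- sim_config(n_comorbidity = n_cm, n_procedure = n_pr)
  b <- sparse_betas(cf0$design,
    count = c(
      "(Intercept)" = log(0.9),
      cm_01 = effect, cm_02 = effect, cm_03 = effect
    ),
    zero = c(
      "(Intercept)" = 0.4,
      cm_01 = -1.5 * effect, cm_02 = -1.5 * effect, cm_03 = -1.5 * effect
    )
  )
  cf <- sim_config(
    n_hospitals = n_hospitals, stays_per_hospital = c(stays, stays),
    n_comorbidity = n_cm, n_procedure = n_pr,
    prevalence_range = c(0.08, 0.3),
    beta_count = b$count, beta_zero = b$zero,
    sigma_count = 0.1, sigma_zero = 0.1, rho = 0, dasc = FALSE
  )
  simulate_cohort(cf, seed = seed)
}

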