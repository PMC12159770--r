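#' Simulation configuration for a multi-hospital cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()].  The
#' generative model mirrors the patient-level risk-adjustment model: each
#' hospital draws a pair of random intercepts (count and zero-inflation
#' components) from a bivariate normal; each stay draws sparse binary
#' comorbidity/procedure flags, demographics and a days-present (DP)
#' exposure; the probability of receiving no antibiotics is
#' `plogis(x'beta_zero + gamma_zero_logdp * log(dp) + b_zero)`, and positive
#' use is negative binomial (NB2, variance `mu + mu^2/theta`) with mean
#' `exp(x'beta_count + log(dp) + b_count)`.
#'
#' Fixed-effect vectors are named over the design columns
#' `(Intercept), age_std, sex, icu_stay, surgical_specialty, cm_01..,
#' pr_01..`.  Defaults put the crude DOT scale near 480 per 1000 DP with
#' roughly half of stays antibiotic-free, and plant a handful of nonzero
#' comorbidity/procedure effects; the remaining flags are noise.
#'
#' @param n_hospitals Number of hospitals.
#' @param units_per_hospital Inpatient units per hospital (first unit is the
#'   ICU, roughly half of the rest are surgical floors).
#' @param stays_per_hospital Length-2 integer range; each hospital draws a
#'   uniform stay count in it.
#' @param n_comorbidity,n_procedure Number of binary flag covariates.
#' @param prevalence_range Range from which flag prevalences are drawn.
#' @param prevalence_floor Minimum admissible prevalence (default 0.005).
#' @param beta_count,beta_zero Named fixed-effect vectors; `NULL` uses the
#'   defaults described above.
#' @param gamma_zero_logdp Coefficient on `log(dp)` in the zero component.
#' @param theta NB2 dispersion (> 0).
#' @param sigma_count,sigma_zero Random-intercept standard deviations.
#' @param rho Correlation between a hospital's two intercepts.
#' @param dasc Logical; also generate a DASC outcome.  DASC shares the DOT
#'   outcome's structural-zero event (a stay with no antibiotic days has
#'   both metrics zero) and zero-component intercepts, with its own
#'   negative binomial count draw whose intercept is shifted by
#'   `log(dasc_scale)` and whose hospital intercepts correlate with the DOT
#'   ones at `dasc_intercept_cor`.
#' @param dasc_scale Multiplicative DASC/DOT scale (default 6.5, matching the
#'   empirical ratio of the two metrics' typical rates).
#' @param dasc_intercept_cor Correlation between a hospital's DOT and DASC
#'   count-component intercepts.  High by default: the two metrics measure
#'   the same prescribing, DASC merely reweights it by spectrum.
#' @param case_mix_sd Per-hospital case-mix severity scale: hospital severity
#'   `s_h ~ N(0,1)` shifts the logit prevalence of every effect-bearing flag
#'   by `case_mix_sd * s_h`, confounding crude rates with case mix.
#' @param severity_to_facility Strength of the association between hospital
#'   severity and the facility complexity attributes (so facility-level
#'   factors can partially proxy case mix, as in real complexity ratings).
#' @param dp_mean,dp_size DP is `1 + rnbinom(mu = dp_mean - 1, size = dp_size)`.
#' @param months_baseline,months_eval Calendar months in each period; a stay
#'   falls wholly in one uniformly drawn month.
#' @param icu_frac Fraction of stays assigned to the ICU unit.
#' @return An object of class `abx_sim_config`.
#' @export
sim_config <- function(n_hospitals = 50,
                       units_per_hospital = 6,
                       stays_per_hospital = c(200, 500),
                       n_comorbidity = 10,
                       n_procedure = 10,
                       prevalence_range = c(0.02, 0.30),
                       prevalence_floor = 0.005,
                       beta_count = NULL,
                       beta_zero = NULL,
                       gamma_zero_logdp = -0.4,
                       theta = 1.5,
                       sigma_count = 0.3,
                       sigma_zero = 0.4,
                       rho = 0.5,
                       dasc = TRUE,
                       dasc_scale = 6.5,
                       dasc_intercept_cor = 0.9,
                       case_mix_sd = 0,
                       severity_to_facility = 1,
                       dp_mean = 5,
                       dp_size = 2,
                       months_baseline = 24,
                       months_eval = 12,
                       icu_frac = 0.12) {
  design <- c(
    "(Intercept)", "age_std", "sex", "icu_stay", "surgical_specialty",
    sprintf("cm_%02d", seq_len(n_comorbidity)),
    sprintf("pr_%02d", seq_len(n_procedure))
  )
  default_beta <- function(intercept, age, icu, surg, cm, pr) {
    b <- stats::setNames(numeric(length(design)), design)
    b["(Intercept)"] <- intercept
    b["age_std"] <- age
    b["icu_stay"] <- icu
    b["surgical_specialty"] <- surg
    b[sprintf("cm_%02d", seq_len(min(3, n_comorbidity)))] <-
      cm[seq_len(min(3, n_comorbidity))]
    b[sprintf("pr_%02d", seq_len(min(3, n_procedure)))] <-
      pr[seq_len(min(3, n_procedure))]
    b
  }
  if (is.null(beta_count)) {
    beta_count <- default_beta(
      log(0.9), 0.10, 0.30, 0.10,
      c(0.30, 0.25, 0.20), c(0.25, 0.20, 0.15)
    )
  }
  if (is.null(beta_zero)) {
    beta_zero <- default_beta(
      0.6, -0.15, -0.8, 0.2,
      c(-0.5, -0.4, -0.3), c(-0.4, -0.3, -0.2)
    )
  }
  stopifnot(
    length(stays_per_hospital) == 2, stays_per_hospital[1] >= 1,
    theta > 0, sigma_count >= 0, sigma_zero >= 0,
    rho >= -1, rho <= 1,
    prevalence_range[1] > 0, prevalence_range[2] < 1
  )
  if (prevalence_range[1] < prevalence_floor) {
    stop(
      "prevalence_range[1] = ", prevalence_range[1],
      " is below the prevalence floor ", prevalence_floor
    )
  }
  if (!identical(names(beta_count), design) ||
    !identical(names(beta_zero), design)) {
    stop("beta_count/beta_zero must be named over the design columns: ",
      paste(design, collapse = ", "))
  }
  structure(
    list(
      n_hospitals = n_hospitals, units_per_hospital = units_per_hospital,
      stays_per_hospital = stays_per_hospital,
      n_comorbidity = n_comorbidity, n_procedure = n_procedure,
      prevalence_range = prevalence_range,
      prevalence_floor = prevalence_floor,
      design = design,
      beta_count = beta_count, beta_zero = beta_zero,
      gamma_zero_logdp = gamma_zero_logdp,
      theta = theta, sigma_count = sigma_count, sigma_zero = sigma_zero,
      rho = rho,
      dasc = dasc, dasc_scale = dasc_scale,
      dasc_intercept_cor = dasc_intercept_cor,
      case_mix_sd = case_mix_sd, severity_to_facility = severity_to_facility,
      dp_mean = dp_mean, dp_size = dp_size,
      months_baseline = months_baseline, months_eval = months_eval,
      icu_frac = icu_frac
    ),
    class = "abx_sim_config"
  )
}

draw_intercepts <- function(n, sigma_count, sigma_zero, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  cbind(b_count = sigma_count * z1, b_zero = sigma_zero * z2)
}

#' Simulate a multi-hospital cohort with known ground truth
#'
#' @param config An [sim_config()] object.
#' @param seed Integer seed; identical `config` + `seed` give a
#'   byte-identical cohort.
#' @param intercepts Optional data frame overriding drawn hospital
#'   intercepts: `hospital_id` (e.g. `"H001"`) plus any of `b_count_dot`,
#'   `b_zero_dot`, `b_count_dasc`, `b_zero_dasc`.  Used to plant known
#'   hospital effects.
#' @return An `abx_cohort`: list with `stays` (one row per stay, including
#'   simulated `dot` and, if configured, `dasc` outcomes), `units` and
#'   `facilities` attribute tables, and `truth` (the config, realized
#'   per-hospital intercepts and severities).
#' @export
simulate_cohort <- function(config, seed = 1L, intercepts = NULL) {
  stopifnot(inherits(config, "abx_sim_config"))
  set.seed(as.integer(seed))
  cf <- config
  hosp_ids <- sprintf("H%03d", seq_len(cf$n_hospitals))

  severity <- stats::rnorm(cf$n_hospitals)
  int_dot <- draw_intercepts(cf$n_hospitals, cf$sigma_count, cf$sigma_zero, cf$rho)
  r <- cf$dasc_intercept_cor
  int_dasc <- r * int_dot + sqrt(max(0, 1 - r^2)) *
    draw_intercepts(cf$n_hospitals, cf$sigma_count, cf$sigma_zero, cf$rho)
  if (!is.null(intercepts)) {
    j <- match(intercepts$hospital_id, hosp_ids)
    if (anyNA(j)) stop("unknown hospital_id in 'intercepts'")
    override <- function(mat, col, src) {
      if (!is.null(intercepts[[src]])) mat[j, col] <- intercepts[[src]]
      mat
    }
    int_dot <- override(int_dot, "b_count", "b_count_dot")
    int_dot <- override(int_dot, "b_zero", "b_zero_dot")
    int_dasc <- override(int_dasc, "b_count", "b_count_dasc")
    int_dasc <- override(int_dasc, "b_zero", "b_zero_dasc")
  }

  facilities <- simulate_facility_attributes(hosp_ids, severity,
    strength = cf$severity_to_facility
  )
  units <- simulate_unit_attributes(hosp_ids, cf$units_per_hospital)

  n_flags <- cf$n_comorbidity + cf$n_procedure
  flag_names <- c(
    sprintf("cm_%02d", seq_len(cf$n_comorbidity)),
    sprintf("pr_%02d", seq_len(cf$n_procedure))
  )
  prev <- stats::runif(n_flags, cf$prevalence_range[1], cf$prevalence_range[2])
  names(prev) <- flag_names
  effect_flags <- flag_names[
    abs(cf$beta_count[flag_names]) + abs(cf$beta_zero[flag_names]) > 0
  ]

  stay_rng <- seq.int(cf$stays_per_hospital[1], cf$stays_per_hospital[2])
  n_stays <- if (length(stay_rng) == 1L) {
    rep.int(stay_rng, cf$n_hospitals)
  } else {
    sample(stay_rng, cf$n_hospitals, replace = TRUE)
  }
  total <- sum(n_stays)
  h_idx <- rep(seq_len(cf$n_hospitals), n_stays)

  # per-hospital logit shift of effect-bearing flag prevalences: case mix
  logit <- function(p) log(p / (1 - p))
  prev_mat <- matrix(rep(prev, each = total), nrow = total,
    dimnames = list(NULL, flag_names))
  if (cf$case_mix_sd > 0 && length(effect_flags) > 0) {
    shift <- cf$case_mix_sd * severity[h_idx]
    for (fl in effect_flags) {
      prev_mat[, fl] <- stats::plogis(logit(prev[fl]) + shift)
    }
  }
  flags <- matrix(
    stats::rbinom(total * n_flags, 1L, as.vector(prev_mat)),
    nrow = total, dimnames = list(NULL, flag_names)
  )

  # units: first unit of each hospital is the ICU
  unit_pick <- function(h) {
    k <- cf$units_per_hospital
    p <- c(cf$icu_frac, rep((1 - cf$icu_frac) / (k - 1), k - 1))
    sample.int(k, n_stays[h], replace = TRUE, prob = p)
  }
  unit_no <- unlist(lapply(seq_len(cf$n_hospitals), unit_pick))
  unit_id <- sprintf("%s_U%d", hosp_ids[h_idx], unit_no)
  u_row <- match(unit_id, units$unit_id)

  age <- pmin(100, pmax(20, stats::rnorm(total, 70, 10)))
  stays <- tibble::tibble(
    stay_id = sprintf("S%07d", seq_len(total)),
    hospital_id = hosp_ids[h_idx],
    unit_id = unit_id,
    month = sample.int(cf$months_baseline + cf$months_eval, total, replace = TRUE),
    age = age,
    age_std = (age - 70) / 10,
    sex = stats::rbinom(total, 1L, 0.1),
    icu_stay = units$icu_floor[u_row],
    surgical_specialty = units$surgical_floor[u_row],
    dp = 1L + stats::rnbinom(total, mu = cf$dp_mean - 1, size = cf$dp_size)
  )
  stays$period <- ifelse(stays$month <= cf$months_baseline,
    "baseline", "evaluation"
  )
  stays <- cbind(stays, tibble::as_tibble(flags))
  stays <- tibble::as_tibble(stays)
  stays$log_dp <- log(stays$dp)

  X <- cbind(`(Intercept)` = 1, as.matrix(
    stays[c("age_std", "sex", "icu_stay", "surgical_specialty", flag_names)]
  ))
  colnames(X)[1] <- "(Intercept)"

  draw_count <- function(beta_count, b_count) {
    eta_c <- as.vector(X %*% beta_count) + stays$log_dp + b_count[h_idx]
    stats::rnbinom(total, mu = exp(eta_c), size = cf$theta)
  }
  # one structural-zero event shared by both outcomes: a stay with no
  # antibiotic days has DOT = DASC = 0 by construction
  eta_z <- as.vector(X %*% cf$beta_zero) +
    cf$gamma_zero_logdp * stays$log_dp + int_dot[h_idx, "b_zero"]
  structural <- stats::rbinom(total, 1L, stats::plogis(eta_z))
  stays$dot <- ifelse(structural == 1L, 0L,
    draw_count(cf$beta_count, int_dot[, "b_count"])
  )
  if (cf$dasc) {
    beta_cd <- cf$beta_count
    beta_cd["(Intercept)"] <- beta_cd["(Intercept)"] + log(cf$dasc_scale)
    int_dasc[, "b_zero"] <- int_dot[, "b_zero"]
    stays$dasc <- as.numeric(ifelse(structural == 1L, 0L,
      draw_count(beta_cd, int_dasc[, "b_count"])
    ))
  } else {
    int_dasc <- int_dot
    stays$dasc <- as.numeric(stays$dot)
  }

  structure(
    list(
      stays = stays, units = units, facilities = facilities,
      truth = list(
        config = cf,
        severity = stats::setNames(severity, hosp_ids),
        intercepts = tibble::tibble(
          hospital_id = hosp_ids,
          b_count_dot = int_dot[, "b_count"],
          b_zero_dot = int_dot[, "b_zero"],
          b_count_dasc = int_dasc[, "b_count"],
          b_zero_dasc = int_dasc[, "b_zero"]
        )
      )
    ),
    class = "abx_cohort"
  )
}

simulate_facility_attributes <- function(hosp_ids, severity, strength = 1) {
  n <- length(hosp_ids)
  noisy <- function(s) strength * severity + stats::rnorm(n)
  to_levels <- function(x, labels, probs) {
    counts <- diff(round(cumsum(c(0, probs)) / sum(probs) * n))
    counts[counts < 0] <- 0
    counts[length(counts)] <- n - sum(counts[-length(counts)])
    factor(rep(labels, counts)[rank(x, ties.method = "first")],
      levels = labels
    )
  }
  tibble::tibble(
    hospital_id = hosp_ids,
    # highest complexity label for the most severe case mix
    complexity_level = to_levels(
      -noisy(severity), c("1a", "1b", "1c", "2", "3"),
      c(0.32, 0.24, 0.22, 0.10, 0.12)
    ),
    icu_complexity = to_levels(
      -noisy(severity), c("5", "4", "3", "2", "1"),
      c(0.45, 0.19, 0.23, 0.03, 0.10)
    ),
    surgical_complexity = to_levels(
      -noisy(severity), c("4", "3", "2", "1", "0.5", "0"),
      c(0.59, 0.23, 0.09, 0.026, 0.026, 0.038)
    ),
    trainees_quintile = factor(
      1L + (rank(stats::rnorm(n), ties.method = "first") - 1L) %/%
        ceiling(n / 5),
      levels = 1:5
    )
  )
}

simulate_unit_attributes <- function(hosp_ids, units_per_hospital) {
  grid <- expand.grid(
    unit_no = seq_len(units_per_hospital),
    hospital_id = hosp_ids, stringsAsFactors = FALSE
  )
  tibble::tibble(
    unit_id = sprintf("%s_U%d", grid$hospital_id, grid$unit_no),
    hospital_id = grid$hospital_id,
    icu_floor = as.integer(grid$unit_no == 1L),
    surgical_floor = as.integer(grid$unit_no > 1L &
      grid$unit_no <= 1L + (units_per_hospital - 1L) %/% 2L)
  )
}

#' Split a cohort into baseline and evaluation periods
#'
#' Both halves keep every hospital and share the same true intercepts; stays
#' are partitioned disjointly.  With `fraction = NULL` the split follows the
#' calendar months generated by [simulate_cohort()] (baseline months first);
#' otherwise a random per-hospital partition with the given baseline fraction
#' is drawn.
#'
#' @param cohort An `abx_cohort`.
#' @param fraction Baseline fraction in (0,1), or `NULL` for the calendar
#'   split.
#' @param seed Seed for the random split (ignored for the calendar split).
#' @return List with elements `baseline` and `evaluation`, both `abx_cohort`s
#'   sharing `units`, `facilities` and `truth`.
#' @export
split_periods <- function(cohort, fraction = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "abx_cohort"))
  stays <- cohort$stays
  if (is.null(fraction)) {
    in_base <- stays$period == "baseline"
  } else {
    stopifnot(fraction > 0, fraction < 1)
    set.seed(as.integer(seed))
    in_base <- logical(nrow(stays))
    for (h in unique(stays$hospital_id)) {
      idx <- which(stays$hospital_id == h)
      n_b <- round(fraction * length(idx))
      in_base[sample(idx, n_b)] <- TRUE
    }
  }
  part <- function(keep) {
    out <- cohort
    out$stays <- stays[keep, , drop = FALSE]
    out
  }
  base <- part(in_base)
  eval <- part(!in_base)
  for (nm in c("baseline", "evaluation")) {
    sub <- if (nm == "baseline") base else eval
    missing <- setdiff(unique(stays$hospital_id), unique(sub$stays$hospital_id))
    if (length(missing) > 0) {
      stop(
        "hospital(s) with no stays in the ", nm, " period: ",
        paste(missing, collapse = ", ")
      )
    }
  }
  list(baseline = base, evaluation = eval)
}

#' Simulate unit-month aggregate records from a plain NB2 model
#'
#' Generates unit-month records directly (no patient level) for exercising
#' the single-level negative binomial machinery: covariates `icu_floor`,
#' `surgical_floor` and a continuous `acuity` score, DP drawn log-uniform in
#' the hundreds-to-thousands range, and outcome
#' `dot ~ NB2(exp(x'beta + log dp), theta)`.
#'
#' @param n Number of records.
#' @param beta Named vector over `(Intercept), icu_floor, surgical_floor,
#'   acuity`.
#' @param theta NB2 dispersion.
#' @param seed Integer seed.
#' @return Tibble of records (with `dasc = dot` so either outcome name fits).
#' @export
simulate_unit_month_records <- function(n,
                                        beta = c(
                                          "(Intercept)" = log(0.45),
                                          icu_floor = 0.45,
                                          surgical_floor = -0.2,
                                          acuity = 0.15
                                        ),
                                        theta = 2,
                                        seed = 1L) {
  set.seed(as.integer(seed))
  icu <- stats::rbinom(n, 1L, 0.15)
  surg <- stats::rbinom(n, 1L, 0.4)
  acuity <- stats::rnorm(n)
  dp <- as.integer(round(exp(stats::runif(n, log(200), log(3000)))))
  eta <- beta["(Intercept)"] + beta["icu_floor"] * icu +
    beta["surgical_floor"] * surg + beta["acuity"] * acuity + log(dp)
  tibble::tibble(
    hospital_id = sprintf("H%03d", 1L + (seq_len(n) - 1L) %% 50L),
    unit_id = sprintf("U%05d", seq_len(n)),
    month = 1L + (seq_len(n) - 1L) %/% 50L,
    icu_floor = icu, surgical_floor = surg, acuity = acuity,
    dp = dp,
    dot = stats::rnbinom(n, mu = exp(eta), size = theta),
    dasc = stats::rnbinom(n, mu = exp(eta), size = theta)
  )
}

#' Expand simulated DOT into per-agent administration days
#'
#' The coupled demo mode: distributes each stay's DOT across 1-3 agents from
#' a spectrum table so the metrics pipeline (agent days -> DOT/DASC) can be
#' exercised end to end.  Per-agent days never exceed the stay's DP; DOT that
#' cannot be packed within `ceiling(dot/dp)` agents adds further agents.
#'
#' @param stays Stay table with `stay_id`, `dp`, `dot`.
#' @param scores Spectrum-score table (named numeric).
#' @param seed Integer seed.
#' @return Long tibble (`stay_id`, `agent_id`, `n_days`); stays with
#'   `dot == 0` have no rows.
#' @export
simulate_agent_days <- function(stays, scores = toy_spectrum_table(), seed = 1L) {
  set.seed(as.integer(seed))
  agents <- names(scores)
  idx <- which(stays$dot > 0)
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    dot <- stays$dot[i]
    dp <- stays$dp[i]
    n_agents <- max(ceiling(dot / dp), sample(1:3, 1))
    n_agents <- min(n_agents, length(agents))
    picked <- sample(agents, n_agents)
    # pack days: each agent at most dp days, sum exactly dot
    days <- rep(0L, n_agents)
    remaining <- dot
    for (j in seq_len(n_agents)) {
      cap <- min(dp, remaining - (n_agents - j)) # leave >=1 for the rest
      d <- if (j == n_agents) remaining else sample(seq_len(max(1, cap)), 1)
      d <- min(d, dp, remaining)
      days[j] <- d
      remaining <- remaining - d
    }
    if (remaining > 0) { # spill over extra agents if still unpacked
      extra <- setdiff(agents, picked)
      while (remaining > 0 && length(extra) > 0) {
        a <- extra[1]
        extra <- extra[-1]
        d <- min(dp, remaining)
        picked <- c(picked, a)
        days <- c(days, d)
        remaining <- remaining - d
      }
    }
    keep <- days > 0
    out[[k]] <- tibble::tibble(
      stay_id = stays$stay_id[i], agent_id = picked[keep], n_days = days[keep]
    )
  }
  do.call(rbind, out)
}

#' Canned study scenario: strong patient-level case-mix confounding
#'
#' Returns the [sim_config()] used for ranking-pattern experiments: hospital
#' case-mix severity strongly shifts the prevalence of the effect-bearing
#' flags (`case_mix_sd = 2.5`), facility complexity attributes are only a
#' weak proxy of that severity (`severity_to_facility = 0.5`), hospital
#' intercept SDs are modest relative to the case-mix signal, and the DOT and
#' DASC count intercepts are nearly colinear.  Under these conditions crude
#' rankings are dominated by case mix, facility-level adjustment removes
#' only part of it, and patient-level adjustment removes almost all of it.
#'
#' @param n_hospitals,stays_per_hospital Cohort size (defaults 60 hospitals
#'   of 500-700 stays).
#' @return An `abx_sim_config`.
#' @export
scenario_confounded <- function(n_hospitals = 60,
                                stays_per_hospital = c(500, 700)) {
  sim_config(
    n_hospitals = n_hospitals, stays_per_hospital = stays_per_hospital,
    case_mix_sd = 2.5, severity_to_facility = 0.5,
    sigma_count = 0.2, sigma_zero = 0.3, rho = 0.5,
    dasc_intercept_cor = 0.95
  )
}
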