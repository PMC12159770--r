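#' Validate a stay table before fitting
#'
#' Schema and invariant checks: required columns present, `dp >= 1`, flag
#' columns binary, outcomes nonnegative, and (when supplied) every agent in
#' the administration table covered by the spectrum table with per-agent
#' days not exceeding the stay's DP.  Fails nothing: returns a violation
#' report for the caller to act on.
#'
#' @param stays Stay table.
#' @param agent_days Optional long administration table.
#' @param scores Optional spectrum-score table.
#' @return Tibble (`rule`, `id`, `detail`), empty when the input is valid.
#' @export
validate_stays <- function(stays, agent_days = NULL, scores = NULL) {
  v <- list()
  bad <- function(rule, id, detail) {
    tibble::tibble(rule = rule, id = as.character(id), detail = detail)
  }
  req <- c("stay_id", "hospital_id", "unit_id", "month", "dp")
  miss <- setdiff(req, names(stays))
  if (length(miss) > 0) {
    v[[length(v) + 1]] <- bad("missing_column", miss, "required column absent")
  }
  if ("dp" %in% names(stays)) {
    i <- which(!is.finite(stays$dp) | stays$dp < 1)
    if (length(i) > 0) {
      v[[length(v) + 1]] <- bad("dp_ge_1", stays$stay_id[i], "dp must be >= 1")
    }
  }
  for (col in grep("^(cm|pr)_|^sex$|^icu_stay$|^surgical_specialty$",
    names(stays),
    value = TRUE
  )) {
    i <- which(!stays[[col]] %in% c(0, 1))
    if (length(i) > 0) {
      v[[length(v) + 1]] <- bad(
        "flag_binary", stays$stay_id[i],
        paste0("column '", col, "' must be 0/1")
      )
    }
  }
  for (col in intersect(c("dot", "dasc"), names(stays))) {
    i <- which(stays[[col]] < 0)
    if (length(i) > 0) {
      v[[length(v) + 1]] <- bad(
        "outcome_nonnegative", stays$stay_id[i],
        paste0("column '", col, "' must be nonnegative")
      )
    }
  }
  if (!is.null(agent_days)) {
    if (anyDuplicated(agent_days[c("stay_id", "agent_id")])) {
      d <- agent_days[duplicated(agent_days[c("stay_id", "agent_id")]), ]
      v[[length(v) + 1]] <- bad(
        "agent_unique", d$stay_id, "duplicate agent within stay"
      )
    }
    j <- match(agent_days$stay_id, stays$stay_id)
    i <- which(is.na(j))
    if (length(i) > 0) {
      v[[length(v) + 1]] <- bad(
        "agent_stay_known", agent_days$stay_id[i], "unknown stay_id"
      )
    }
    ok <- !is.na(j)
    i <- which(agent_days$n_days[ok] > stays$dp[j[ok]])
    if (length(i) > 0) {
      v[[length(v) + 1]] <- bad(
        "agent_days_le_dp", agent_days$stay_id[ok][i],
        "per-agent days exceed the stay's DP"
      )
    }
    if (!is.null(scores)) {
      unknown <- setdiff(unique(agent_days$agent_id), names(scores))
      if (length(unknown) > 0) {
        v[[length(v) + 1]] <- bad(
          "agent_in_spectrum", unknown, "agent missing from spectrum table"
        )
      }
    }
  }
  if (length(v) == 0) {
    return(tibble::tibble(
      rule = character(), id = character(), detail = character()
    ))
  }
  do.call(rbind, v)
}

#' Run the full benchmarking pipeline on a simulated cohort
#'
#' Orchestrates the whole workflow: simulate (or accept) a cohort, split
#' into baseline and evaluation periods, pick patient-level variables
#' (prescreen, optionally consensus LASSO), fit the method-1 NB unit-month
#' models (with backward-AIC facility/unit selection) and the method-2 ZINB
#' mixed models on baseline data, score the evaluation period (O:E and P:E),
#' and assemble the benchmark table and tau-b matrix.  Baseline fitting
#' never sees evaluation-period stays.
#'
#' @param cohort An `abx_cohort`, or `NULL` to simulate from `config`.
#' @param config [sim_config()] used when `cohort` is `NULL`.
#' @param seed Master seed; per-stage seeds derive from it.
#' @param outcomes Subset of `c("dot", "dasc")`.
#' @param methods Subset of `c("crude", "method1", "method2")`.
#' @param do_selection Run consensus LASSO for patient variables (else the
#'   prescreen alone trims the flag candidates).
#' @param K Consensus subsets.
#' @param patient_terms Patient-level terms for method 2; `NULL` derives
#'   them (demographics plus screened flags).
#' @param method1_terms Facility/unit candidate terms for method 1.
#' @param method1_backward Run backward-AIC elimination for method 1.
#' @param variance_decomposition Also fit intercept-only ZINB mixed models
#'   and report random-intercept variance reductions.
#' @param control Optimizer control for ZINB fits.
#' @param out_dir Directory for CSV/JSON artifacts (`NULL` = do not write).
#' @return List: `benchmark`, `tau`, `models`, `selection`,
#'   `variance_reduction`, `intercept_correlation`, `manifest`.
#' @export
run_pipeline <- function(cohort = NULL, config = sim_config(), seed = 1L,
                         outcomes = c("dot", "dasc"),
                         methods = c("crude", "method1", "method2"),
                         do_selection = FALSE, K = 10,
                         patient_terms = NULL,
                         method1_terms = c(
                           "complexity_level", "icu_complexity",
                           "surgical_complexity", "trainees_quintile",
                           "avg_los_quintile", "icu_floor", "surgical_floor"
                         ),
                         method1_backward = TRUE,
                         variance_decomposition = FALSE,
                         control = zinb_control(),
                         out_dir = NULL) {
  seed <- as.integer(seed)
  if (is.null(cohort)) cohort <- simulate_cohort(config, seed = seed)
  periods <- split_periods(cohort)
  base <- periods$baseline$stays
  eval_stays <- periods$evaluation$stays
  models <- list()
  selection <- list()

  # patient-level variable selection (baseline data only)
  if (is.null(patient_terms)) {
    screen <- prescreen_candidates(base, outcome = outcomes)
    selection$prescreen <- screen
    flags <- screen$variable_id[screen$passed]
    if (do_selection) {
      cons <- consensus_select(base,
        outcome = outcomes[1], candidates = flags,
        K = K, seed = seed + 101L
      )
      selection$consensus <- cons
      flags <- union(cons$consensus$count, cons$consensus$zero)
    }
    patient_terms <- c(
      "age_std", "sex", "icu_stay", "surgical_specialty", flags
    )
  }
  selection$patient_terms <- patient_terms

  oe <- pe <- list(dot = NULL, dasc = NULL)
  var_red <- list()
  icorr <- list()

  if ("method1" %in% methods) {
    um_base <- aggregate_unit_month(base, cohort$units, cohort$facilities)
    um_base <- assign_los_quintiles(um_base)
    cuts <- attr(um_base, "los_cutpoints")
    um_eval <- aggregate_unit_month(eval_stays, cohort$units, cohort$facilities)
    um_eval <- assign_los_quintiles(um_eval, cutpoints = cuts)
    for (oc in outcomes) {
      terms <- method1_terms
      if (method1_backward) {
        bw <- backward_aic(nb_aic_fun(um_base, oc), candidates = method1_terms)
        selection[[paste0("method1_backward_", oc)]] <- bw
        terms <- bw$selected
      }
      m <- fit_nb(um_base, outcome = oc, terms = terms)
      m$los_cutpoints <- cuts
      models[[paste0("nb_", oc)]] <- m
      oe[[oc]] <- oe_ratios(m, um_eval)
    }
  }

  if ("method2" %in% methods) {
    for (oc in outcomes) {
      m <- fit_zinb_mixed(base,
        outcome = oc,
        count_terms = patient_terms, zero_terms = patient_terms,
        control = control, hessian = FALSE
      )
      models[[paste0("zinb_", oc)]] <- m
      blups <- reestimate_blups(m, eval_stays)
      pe[[oc]] <- pe_ratios(m, eval_stays, blups)
      icorr[[oc]] <- intercept_correlation(m)
      if (variance_decomposition) {
        null_m <- fit_zinb_mixed(base,
          outcome = oc,
          count_terms = character(), zero_terms = character(),
          control = control, hessian = FALSE
        )
        models[[paste0("zinb_null_", oc)]] <- null_m
        var_red[[oc]] <- variance_reduction(null_m, m)
      }
    }
  }

  benchmark <- build_benchmark(
    eval_stays,
    oe_dot = oe$dot, oe_dasc = oe$dasc,
    pe_dot = pe$dot, pe_dasc = pe$dasc
  )
  tau <- tau_matrix(benchmark)

  manifest <- list(
    package_version = as.character(utils::packageVersion("abxbench")),
    seed = seed, outcomes = outcomes, methods = methods,
    do_selection = do_selection, K = K,
    patient_terms = patient_terms,
    n_hospitals = length(unique(cohort$stays$hospital_id)),
    n_stays_baseline = nrow(base),
    n_stays_evaluation = nrow(eval_stays)
  )
  result <- list(
    benchmark = benchmark, tau = tau, models = models,
    selection = selection, variance_reduction = var_red,
    intercept_correlation = icorr, manifest = manifest
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$benchmark,
    file.path(out_dir, "benchmark_wide.csv"),
    row.names = FALSE
  )
  utils::write.csv(benchmark_long(result$benchmark),
    file.path(out_dir, "benchmark_long.csv"),
    row.names = FALSE
  )
  utils::write.csv(
    as.data.frame(result$tau$tau),
    file.path(out_dir, "tau_matrix.csv")
  )
  jsonlite::write_json(
    result$manifest,
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(out_dir)
}
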