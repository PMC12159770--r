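#!/usr/bin/env Rscript

# Simulate the demo cohort: 60 hospitals under strong case-mix confounding
# (hospital severity shifts comorbidity/procedure prevalences; facility
# complexity ratings are only a weak proxy of severity), with known hospital
# intercepts in both ZINB components.  Writes the stay, unit and facility
# tables plus the ground truth under results/data/.

library(abxbench)

seed <- 20260925L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

config <- scenario_confounded()
cohort <- simulate_cohort(config, seed = seed)

stopifnot(nrow(validate_stays(cohort$stays)) == 0)

write.csv(cohort$stays, "results/data/stays.csv", row.names = FALSE)
write.csv(cohort$units, "results/data/units.csv", row.names = FALSE)
write.csv(cohort$facilities, "results/data/facilities.csv", row.names = FALSE)
write.csv(cohort$truth$intercepts, "results/data/truth_intercepts.csv",
  row.names = FALSE
)
jsonlite::write_json(
  list(
    seed = seed, n_hospitals = config$n_hospitals,
    n_stays = nrow(cohort$stays),
    sigma_count = config$sigma_count, sigma_zero = config$sigma_zero,
    rho = config$rho, theta = config$theta,
    case_mix_sd = config$case_mix_sd,
    severity_to_facility = config$severity_to_facility
  ),
  "results/data/simulation_manifest.json",
  auto_unbox = TRUE, pretty = TRUE
)

base <- subset(cohort$stays, period == "baseline")
eval <- subset(cohort$stays, period == "evaluation")
cat(sprintf(
  paste0(
    "Simulated %d stays at %d hospitals (%d baseline, %d evaluation).\n",
    "Zero fraction: %.2f;  crude DOT/1000DP: %.0f;  DASC/1000DP: %.0f.\n"
  ),
  nrow(cohort$stays), config$n_hospitals, nrow(base), nrow(eval),
  mean(cohort$stays$dot == 0),
  1000 * sum(eval$dot) / sum(eval$dp),
  1000 * sum(eval$dasc) / sum(eval$dp)
))
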