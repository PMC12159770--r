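Package: abxbench
Title: Risk-Adjusted Benchmarking of Inpatient Antibiotic Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes inpatient antibiotic-use metrics (days of therapy, days
    of antimicrobial spectrum coverage, days present) and benchmarks hospitals
    under three levels of risk adjustment: crude rates per 1000 days present,
    observed-to-expected ratios from single-level negative binomial models
    with facility- and unit-level factors, and predicted-to-expected ratios
    from patient-level zero-inflated negative binomial models with
    hospital-specific random intercepts in both the count and zero-inflation
    components.  Includes a synthetic multi-hospital cohort generator with
    known ground truth, prevalence/correlation prescreening, consensus LASSO
    variable selection over random data subsets, backward-AIC elimination of
    facility-level factors, and Kendall tau-b comparison of hospital rankings
    across metrics and adjustment methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    glmmTMB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
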