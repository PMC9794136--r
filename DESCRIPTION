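Package: targetmr
Title: Drug-Target Mendelian Randomization Screening with Colocalization
    and Mediation Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomization from GWAS/QTL summary
    statistics for drug-target screens: harmonization of exposure and
    outcome effect alleles, LD-aware instrument selection at tiered
    significance thresholds, Wald-ratio/IVW/MR-Egger/weighted-median/mode
    estimators, heterogeneity and pleiotropy diagnostics (Cochran's Q,
    MR-PRESSO-style outlier detection, Steiger directionality), Bayesian
    colocalization via Wakefield approximate Bayes factors, a
    blood-pressure-style mediation consistency benchmark with conditional
    summary statistics, drug direction-of-effect inference from
    perturbation-similarity signs, and an LD-structured synthetic
    summary-statistics generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
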