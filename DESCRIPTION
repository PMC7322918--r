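Package: ewasmr
Title: Methylation EWAS, Region Calling and Mendelian Randomization for
    Cancer Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for asking whether blood DNA methylation
    mediates the effect of oropharyngeal-cancer prognostic factors
    (smoking, alcohol intake, HPV16 E6 serostatus) on approximately
    three-year survival. Provides per-CpG linear and Cox
    proportional-hazards epigenome-wide association engines with
    surrogate-variable adjustment, differentially methylated region (DMR)
    calling by correlation-aware inverse-variance combination with Sidak
    adjustment, construction of methylation quantitative trait locus
    (mQTL) instruments by iterative per-CpG LD clumping and REML
    meta-analysis to a region-average effect, and two-sample Mendelian
    randomization against survival (Wald ratio, correlated-instrument IVW
    and MR-Egger) with an asymptotic power calculator. A synthetic-cohort
    generator with known genotype-methylation-survival mediation supplies
    ground truth for calibration and recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
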