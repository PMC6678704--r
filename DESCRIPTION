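Package: nagburden
Title: Somatic Alteration Burden and Immunogenicity Stratification for
    Early-Stage Lung Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gene-level somatic alteration burden analysis for early-stage
    non-small cell lung cancer cohorts. Builds binary patient-by-gene
    alteration matrices from non-synonymous variant calls and copy-number
    log-R-ratio profiles, selects a prognostic gene panel with an
    elastic-net penalized Cox model fitted by coordinate descent, scores
    patients by their number of altered panel genes (NAG), derives a
    differential-expression proxy signature with per-patient risk scores,
    enumerates mutant 8-11mer peptides and classifies patients by MHC
    class I immunogenicity, and stratifies survival with Kaplan-Meier,
    log-rank and multivariate Cox analyses. Ships a synthetic cohort
    generator with planted prognostic effects so the whole pipeline can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    seqinr,
    stats,
    survival,
    utils,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
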