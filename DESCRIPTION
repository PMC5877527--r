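Package: metaphen
Title: Integrated Clinical-Metabolomic Phenotyping of COPD Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating clinical/demographic variables with targeted
    serum metabolite concentrations and untargeted mass-spectrometric profiles of
    serum and exhaled breath condensate into a single unit-interval data matrix,
    and for mining that matrix for disease phenotypes. Implements spectral binning
    to a 1 Da grid, total-ion-count normalization, log and logistic transforms,
    per-variable max-scaling, volcano-style two-group testing, one-way ANOVA with
    Tukey HSD post hoc comparisons across GOLD strata, principal component
    analysis with per-block variance accounting, a sparse partial least squares
    discriminant analysis with repeated cross-validated tuning, hierarchical
    clustering with a battery of nine cluster-validity indices, and a de novo
    phenotyping workflow that scores candidate clusterings against a GOLD-based
    positive control. A synthetic-cohort generator with planted, recoverable
    effects makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    mclust,
    mixOmics
Config/testthat/edition: 3
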