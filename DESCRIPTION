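Package: ftdclust
Title: Multi-Step Cluster Selection and Subgroup Validation for Ordinal
    Symptom Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies patient cohorts by ordinal symptom items (e.g. PANSS
    and SANS formal-thought-disorder ratings) with a four-checkpoint cluster
    selection protocol: (i) an internal validity and leave-one-column-out
    stability screen across k-means, hierarchical (average and Ward linkage)
    and PAM solutions with a majority rule; (ii) a multi-index optimal-k vote;
    (iii) cophenetic, silhouette and bootstrap stability (ST) diagnostics; and
    (iv) cross-validated prediction strength with a retention threshold.
    Includes the downstream subgroup-validation layer (normality-gated
    Mann-Whitney or Welch tests, chi-square association, rank effect sizes,
    Benjamini-Hochberg FDR within declared families, FDR-corrected
    correlograms) and a calibrated synthetic-cohort generator for end-to-end
    testing when clinical data cannot be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
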