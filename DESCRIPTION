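Package: pairedscreen
Title: Analysis of Paired Pooled CRISPR-Cas9 Dropout Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of pooled CRISPR-Cas9 knockout screens run in
    matched pairs of cell lines (for example a primary cell line and its
    transformed counterpart). Quantifies sgRNA spacers in sequencing reads,
    normalizes counts to reads per million, computes per-sgRNA log2 fold
    changes against a day-1 reference, aggregates them into per-gene CRISPR
    scores with one-sample t or Kolmogorov-Smirnov significance tests,
    classifies genes into nine differential-essentiality groups by sign and
    significance in the two cell lines, calls strictly essential genes at a
    32-fold depletion threshold, and summarizes screens with cumulative
    sgRNA-frequency curves and cross-screen correlations. Includes a
    simulator of paired negative-selection screens with planted fitness
    effects, per-guide efficiencies, exponential abundance dynamics and
    multinomial or Dirichlet-multinomial sequencing noise, with ground-truth
    labels for validating recovery of the classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
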