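Package: adaptsig
Title: Data-Driven Analysis of Adaptive Drug Response in Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for relating multiplexed (phospho)protein
    measurements to drug-induced phenotypes in cancer cell lines. Covers
    reverse-phase protein array (RPPA) style preprocessing (replicate
    outlier filtering, antibody quality control, log2 fold-change
    normalization, autoscaling), construction of a non-apoptotic viability
    response from single-cell counts, partial least squares regression
    (NIPALS) with tenfold cross-validation, signed variable-importance
    (VIP) signatures with dual-analysis consistency filtering,
    hierarchical clustering of adaptation profiles, dose-response (Hill)
    fitting with IC50/Emax/AUC summaries, Bliss-independence synergy
    mapping, two-marker single-cell gating, and Spearman / partial
    Spearman biomarker screens. Ships a latent-factor synthetic data
    generator with recorded ground truth so that every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    mclust,
    ape
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
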