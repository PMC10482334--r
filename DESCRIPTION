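Package: longomix
Title: Longitudinal Two-Condition Multi-Omics Analysis with OPLS-DA
Version: 0.1.0
Author: longomix authors
Maintainer: longomix authors <longomix@example.org>
Description: Analysis pipeline for longitudinal two-condition omics studies
    (e.g. fed-batch CHO cultures profiled by untargeted LC-MS metabolomics
    and TMT proteomics). Implements feature-retention filtering, pareto
    scaling and mean centering, a from-scratch OPLS-DA (orthogonal
    projections to latent structures discriminant analysis) with NIPALS-style
    deflation, stratified cross-validated Q2, label-permutation model
    validation, and a predictive-loading significance rule; area-under-the-
    curve (AUC) and maximum per-day fold-change statistics over culture time
    with signed-fold conventions and infinity sentinels; a tiered
    identification-confidence engine (tiers 1, 1*, 2-5) driven by retention
    time, mass-accuracy (ppm), isotope-fit and MS/MS evidence; and a
    synthetic-data generator with planted ground truth for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
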