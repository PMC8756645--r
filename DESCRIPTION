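Package: evoflux
Title: Transcriptome-Guided Evolution of Flux Bounds for Metabolic Target Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modelling toolkit for identifying
    metabolic-engineering targets that explain suboptimal product formation in
    batch fermentations. Provides a tabular metabolic-model dialect with
    equation parsing, flux balance analysis (FBA) and flux variability
    analysis (FVA) on a built-in simplex solver, a dynamic FBA simulator of
    mixed glucose/xylose batch fermentation with two-pool phosphate kinetics
    and a scheduled product-output cap, mapping of transcript-level expression
    (TPM) and differential expression onto reactions through AND/OR
    association rules, an evolutionary algorithm that mutates flux bounds of
    differentially expressed reactions to reproduce an observed product flux,
    and post-processing of evolved solutions into a ranked table of
    up-/down-regulation targets with product-flux percent increases.
    Ships seeded synthetic fixtures (toy models, expression tables, reference
    trajectories) so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
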