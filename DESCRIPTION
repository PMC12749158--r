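Package: vascsynergy
Title: Paired Stressor-Synergy Analysis for Vascular Cell Transcriptomes
    and Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for paired-design studies of obesity-associated
    metabolic and humoral stressor synergy in vascular cells. Implements
    fragments-per-million normalization, a fold-change significance threshold
    derived from control-sample variability (3 x average coefficient of
    variation), paired stressor-effect ratios with log-scale confidence
    intervals and the exclusion-of-1 test, additive-versus-measured synergy
    decomposition with through-origin scatter slopes and CI-based set
    reconciliation, the printed gene-ontology enrichment score, and the
    formula-defined phenotype readouts of the study design (cell shape and
    contraction, DAPI-integral cell-cycle gating, BrdU positivity, lipid
    scores, mito-stress-test oxygen consumption parameters, random motility,
    metabolic fluxes, caspase rates, nuclear-to-perinuclear ratios). A seeded
    negative-binomial count simulator with paired animal structure and known
    per-gene truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
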