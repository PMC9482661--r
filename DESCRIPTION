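Package: tempomics
Title: Stage-Resolved Integration of TF Binding, Chromatin State, and Expression
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for stage-resolved multi-omic analysis of
    transcription-factor binding during a three-stage in vitro differentiation:
    replicate-consensus peak calling under a reciprocal-fraction overlap rule,
    temporal binding classification across time points, nearest-TSS peak
    annotation, k-means temporal expression clustering, negative-binomial
    differential expression and differential binding between genotypes,
    chromatin-state coenrichment and bivalency calling with state-transition
    tabulation, direction-concordant integration of differentially bound
    regions with differentially expressed genes, PWM motif scanning with
    Fisher enrichment, and a synthetic multi-layer study generator with a
    machine-readable truth ledger for planted-truth recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
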