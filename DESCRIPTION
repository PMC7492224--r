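Package: variantTriage
Title: Rare-Variant Triage for Targeted Gene Panels: Predictor Score
    Aggregation, Splice-Consequence Simulation, Depth-Based CNV Calling and
    Conservation Logos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a desk-scale interpretation pipeline for rare variants
    found by targeted panel sequencing, as used in pulmonary arterial
    hypertension (PAH) gene-panel studies. In-silico predictor outputs from
    seven tools (Annovar impact, CADD, SIFT, PolyPhen-2, MutationAssessor,
    FATHMM, VEST) are discretized to damaging / possibly damaging / benign
    calls, aggregated into a 7-point score, mapped to ACMG computational
    evidence codes (BP4 / PP3 / PVS1) and combined with caller-supplied
    evidence through the published ACMG rules into a five-tier class.
    A transcript model supports exon-skipping and indel consequence
    simulation with HGVS r./p. output, frame status and truncated protein
    lengths. A cohort read-depth module normalizes per-target depths to dose
    ratios and calls deletions/duplications by dose and Z-score thresholds.
    Multi-species sequence windows are converted to sequence-logo matrices
    with per-position information content and a conservation class. Seeded
    synthetic-data generators provide ground-truth inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
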