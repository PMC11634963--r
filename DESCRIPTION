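Package: ctdnatriage
Title: Circulating Tumor DNA Detection and Group Triage from Targeted cfDNA Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream decision logic for a targeted cell-free DNA (cfDNA)
    sequencing panel in metastatic castration-resistant prostate cancer:
    gene-level copy-number ratios against a panel of normals with five-control
    within-sample normalization, two-caller SNV/indel consensus with
    pathogenicity and germline/somatic filtering, four-caller structural-variant
    breakend consensus with AR gene structural rearrangement (AR-GSR) detection,
    ligand-binding-domain truncation rules and an ecDNA signature, a
    three-group ctDNA-positivity classification anchored to a healthy-donor
    aneuploidy threshold, and Kaplan-Meier / log-rank survival summaries.
    Includes a fully synthetic cohort generator emulating fraction-dependent
    signal dilution, multi-caller jitter and group-dependent survival, so the
    whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    survival,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
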