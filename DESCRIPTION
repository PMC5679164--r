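Package: stimprint
Title: Modular Transcriptional Fingerprinting of Stimulated Whole Blood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multidimensional whole-blood stimulation
    assays: donor-normalized inducible transcriptomics (intensity flooring,
    ratio-to-medium normalization, detection filtering, Welch ANOVA with
    Benjamini-Hochberg correction), extraction of disjoint reference
    coexpression modules by per-stimulus clustering, cocluster scoring and
    clique selection, modular fingerprint scoring, the molecular distance to
    medium (MDTM) composite statistic, weighted coexpression network module
    detection with eigengenes, and integration of module eigengenes with
    cell-surface (FACS) and secreted-protein (Luminex) traits, including
    gene-significance/module-membership hub-gene analysis and annotation of
    network modules by overlap with reference modules. Includes a seeded
    synthetic-data generator that emulates the assay's structure (per-donor
    baselines, a medium control per donor, stimulus-specific induced
    programs, detection failures, trait couplings) so the full pipeline is
    exercisable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
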