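Package: crisprmeta
Title: Cross-Screen Meta-Analysis and Companion Pipelines for CRISPRi FACS
    Modifier Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pooled CRISPR interference (CRISPRi)
    fluorescence-activated cell sorting (FACS) screens of protein-level
    modifiers and their companion assays. Provides dual-sgRNA read-pair
    parsing with recombination filtering and permutation-based gene scoring;
    harmonization of heterogeneous per-screen gene statistics to a common
    standardized-beta/z scale followed by inverse-variance fixed-effect
    meta-analysis with Cochran's Q heterogeneity, false-discovery-rate
    adjustment, novelty calling and directional hit classification;
    single-timepoint dynamic SILAC protein half-life estimation with
    harmonic-mean peptide rollup and differential turnover testing;
    percent-spliced-in (PSI) based cryptic splice-junction calling and
    categorization; and a bulk RNA-seq normalization chain (gene-length
    normalization, counts per million, pedestalled log2, cyclic loess) with
    CV-versus-mean noise filtering and differential expression. A synthetic
    data module generates every pipeline input with planted ground truth so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    limma,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
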