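Package: bclineage
Title: Multi-Omic Breast Cancer Subtype and Lineage Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational procedures for linking breast cancer subtypes to
    their putative cells of origin from multi-omic data. Implements
    bootstrapped PAM50 nearest-centroid subtyping with ER-balanced median
    adjustment (bulk and single-nucleus cluster level), FPKM-UQ
    normalization, per-cell RNA and snATAC quality filters, snATAC peak-atlas
    construction (501-bp summit resizing, iterative overlap removal,
    score-per-million normalization, promoter annotation), multi-caller
    somatic and germline variant consensus filtering with pathogenicity
    tiers and a one-sided Fisher loss-of-heterozygosity test,
    barcode-resolved variant-to-cell mapping, staged set-algebra calling of
    lineage-specific genes and TF motifs, tumor cell-surface marker
    screening, overlap-weighted segment-to-gene copy-number calls, and
    multiplex immunofluorescence quantifications. Synthetic-data generators
    with planted ground truth make every step testable without restricted
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    EBImage,
    igraph,
    jsonlite,
    tiff,
    vcfR,
    Rsamtools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
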