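Package: zwstrata
Title: Sex-Linkage Assignment and Evolutionary Strata Inference for ZW
    Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing heteromorphic ZW sex chromosomes from
    two-sex whole-genome resequencing evidence: genome-size estimation
    from k-mer depth spectra, classification of assembly scaffolds as
    Z-linked, W-linked or autosomal from normalized male:female read
    depth, sex-contrasted heterozygosity under depth and quality variant
    filters, windowed evidence tracks along the Z chromosome (relative
    female depth, Z/W divergence, W-fragment density, cross-species
    conservation, repeat density) with multivariate changepoint
    segmentation into evolutionary strata, and quantification of W
    gametolog degeneration (open-reading-frame disruption scans,
    divergence estimation, neighbor-joining topology tests).  A
    deterministic synthetic ZW data generator with known ground truth
    supports validation end-to-end, and a command-line interface wraps
    the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    IRanges,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
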