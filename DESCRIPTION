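Package: NDRquant
Title: Nucleosome Occupancy and Promoter NDR Dynamics from MNase-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify nucleosome occupancy and promoter
    nucleosome-depleted region (NDR) dynamics from MNase-seq data in
    compact fungal genomes. Implements clonal (duplicate) read removal by
    a Poisson cutoff, half-fragment read shifting, quantile-normalised
    per-base-pair occupancy tracks, per-base Poisson differential
    occupancy between conditions, TSS-anchored NDR length quantification,
    shrinkage ranking between conditions, TSS-aligned meta-gene profiles
    with -1 nucleosome shift estimation, Fisher gene-set overlap
    enrichment, and the accompanying ChIP/qPCR ratio normalisations.
    Includes a synthetic nucleosome-map simulator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'NDRquant-package.R'
    'calls.R'
    'coverage.R'
    'enrichment.R'
    'io.R'
    'metagene.R'
    'ndr.R'
    'pipeline.R'
    'qpcr.R'
    'simulate.R'
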