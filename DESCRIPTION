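Package: regloops
Title: Chromatin Loop and Regulatory Element Analysis for Plant ChIA-PET Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of ChIA-PET chromatin interaction data in
    plant genomes. Annotates promoter-proximal regions and candidate distal
    regulatory elements from epigenomic tracks (ChIP peaks, MNase
    accessibility, whole-genome bisulfite methylation), categorizes
    paired-end tags and calls chromatin loops with tag-count and peak-support
    filters, classifies loops into promoter-promoter (PPI) and
    promoter-distal (PDI) interactions, tests co-expression of looped gene
    pairs against distance-matched permutation nulls, and integrates eQTL and
    GWAS tables with loops using simulated-loop and random-region null
    models. Ships a seed-reproducible synthetic data generator with a planted
    ground-truth manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    igraph,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
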