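Package: hypoblocks
Title: Hypomethylated Block Detection and Genomic Correlates in Tumor Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects large hypomethylated genomic blocks from tiled per-CpG
    bisulfite methylation data by differential tiling with FDR control, merging
    of nearby significant tiles, and CpG-count filtering. Quantifies the spatial
    association of blocks with genomic feature tracks (binomial projection test,
    Jaccard permutation test, fold enrichment), relates copy-number alteration
    segments to blocks with coverage-normalized densities, and computes
    expression statistics used in global-hypomethylation studies of ovarian
    cancer: a regularized (shrunken-variance) two-sample t-test,
    proliferation-normalized expression ratios, in-block expression variability
    (MAD), and chromosomal-instability signature scores. A seeded synthetic-data
    module generates methylomes, feature tracks, CNA segments and expression
    matrices with planted ground truth so every stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
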