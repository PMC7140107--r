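# hypoblocks

Tumor genomes with global DNA hypomethylation do not lose 5-methylcytosine
uniformly: the loss concentrates in **hypomethylated blocks** — contiguous
regions of hundreds of kilobases to megabases, typically overlapping
late-replicating, lamina-associated heterochromatin — and these blocks
associate with chromosomal instability and distinctive gene expression.
`hypoblocks` is an R package plus a small analysis workflow for studying
this phenomenon from tiled per-CpG methylation data. It is written for
epigenomics analysts who have CpG-level methylation fractions for two
sample groups (e.g. hypomethylated tumors vs normal epithelium) and want
the block calls and their genomic correlates.

## What it computes

**Block calling.** The genome is tiled into 5 kb windows; per tile, group
methylation is compared with a Welch t-test on per-sample tile means and
Benjamini–Hochberg FDR across testable tiles. Tiles with q ≤ 0.05 and an
average methylation decrease ≥ 35% (Δβ ≤ −0.35) are merged into blocks when
≤ 250 kb apart, and blocks with < 5 CpGs are dropped. DMRs (runs of ≥ 3
same-sign CpGs with ≥ 1 CpG at |Δβ| > 0.20, p ≤ 0.05) and per-context DMC
counts are also provided.

**Spatial enrichment.** For a feature track against a block set covering
genome fraction *f*, the fold enrichment of features with midpoint in
blocks is (k/n)/f, tested with an exact binomial projection test
(site-like tracks) or a Jaccard permutation test with a
relocation-within-chromosome null (span-like tracks).

**CNA.** Per-sample CNA index (fraction of genome gained or lost, union of
calls), Mann–Whitney group comparison, and coverage-normalized CNA density
inside vs outside blocks (ratio = 1 under uniform placement), tested by
Wilcoxon signed-rank across samples.

**Expression statistics.** A regularized two-sample t-test with variance
shrinkage toward an intensity-ranked background
(s²ᵣ = (ν·s²_bg + (n−2)·s²_g)/(ν + n − 2); ν = 0 recovers the pooled t);
DEG shares; proliferation-normalized ratios log₂(gene) − log₂(MKI67);
per-gene MAD expression variability in vs out of blocks; and
chromosomal-instability signature scores (mean log₂ fold change over a
supplied gene list such as CIN25).

**Synthetic data.** Seeded generators produce methylomes with planted
blocks, feature tracks with known in-block enrichment, non-overlapping CNA
segments with known in-block concentration, and expression matrices with
planted effects — so every stage is verifiable against ground truth.

## Worked example

The `analysis/` directory is a five-step workflow over a synthetic study
(two groups of four samples, 2 × 25 Mb genome, ~15% of the genome planted
as blocks with 35–50% methylation decrease):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_blocks.R
Rscript analysis/03_enrichment.R
Rscript analysis/04_cna.R
Rscript analysis/05_expression.R
```

which prints, step by step:

```
simulated 99930 CpGs over 50 Mb; 12 truth blocks covering 15.2% of the genome
called 12 blocks spanning 7.6 Mb (15.2% of genome); Jaccard with planted truth 0.995
1543 DMRs (1543 hypo); DMCs in blocks: 15384 hypo / 0 hyper
LAD       1186/ 4000 midpoints in blocks (30%), fold 1.96, Direct, jaccard p = 0.000999
uniform    561/ 4000 midpoints in blocks (14%), fold 0.93, Indirect, projection p = 0.0472
CNA index medians: ref 0.080, case 0.248 (Mann-Whitney p = 0.0131)
case CNA density: 0.6202/bp in blocks vs 0.1815/bp outside (ratio 3.42, p = 0.125)
26 DEGs at p < 0.01; 21 (81%) up in the case group
DNMT1/MKI67 ratio medians: ref -1.31, case -2.62 (MW p = 0.0286)
DNMT3A/MKI67 ratio medians: ref 1.73, case 0.21 (MW p = 0.0286)
UHRF1/MKI67 ratio medians: ref 2.24, case 1.13 (MW p = 0.114)
case-sample MAD: median 0.265 in blocks vs 0.137 outside (MW p = 1.47e-30)
instability signature: mean log2FC 0.79, 22/25 genes p < 0.05
```

Reading the output: the caller recovers the planted blocks almost exactly
(Jaccard 0.995 against truth, 15.2% of the genome as planted); the track
planted at 2× concentration shows fold 1.96 ("Direct", significant) while
the uniform control sits near fold 1 (its p of 0.047 at this seed is the
kind of borderline value a 5% test produces under the null about one run
in twenty); the case group's CNA index is three-fold higher and its CNA
density is ~3× higher inside blocks than outside, as planted (the signed-
rank p of 0.125 is the smallest attainable with four case samples); and
the expression stage finds the planted proliferation-marker effect (the
DNMT1/MKI67 ratio drops by ~1.3 log₂ units in the case group), the doubled
in-block MAD, and the planted 0.8 log₂ signature shift (0.79 recovered).

The same pipeline runs as one call from a config file:

```r
library(hypoblocks)
report <- run_pipeline(system.file("extdata", "demo_config.yaml",
                                   package = "hypoblocks"),
                       outdir = "demo_run")
```

## Formats

Plain text throughout: genome model as two-column TSV (chrom, length);
intervals as BED3/BED6 (0-based half-open); methylome as TSV
(`chrom`, `pos`, one fraction column per sample, `NA` = unobserved);
CNA segments as SEG-like TSV (`sample`, `chrom`, `start`, `end`,
`call` ∈ gain/loss/neutral); expression as TSV (`gene` + one log₂ column
per sample); results as TSV/JSON with fixed column orders.
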