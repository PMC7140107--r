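---
title: "Calling hypomethylated blocks and their genomic correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling hypomethylated blocks and their genomic correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoblocks)
```

## The problem

Global DNA hypomethylation in tumors is not a uniform erosion of
5-methylcytosine: it concentrates in large contiguous genomic regions —
hypomethylated blocks — that span hundreds of kilobases to megabases and
preferentially cover heterochromatic, late-replicating, lamina-associated
territory. This package implements the quantitative machinery for studying
that phenomenon from tiled per-CpG methylation data: calling the blocks,
measuring how genomic features distribute relative to them, relating
copy-number alterations (CNA) to them, and computing the expression
statistics that accompany such studies (proliferation-normalized expression
of maintenance-methylation genes, in-block expression variability, an
aneuploidy expression-signature score, and a shrunken-variance differential
expression test).

All coordinates are 0-based half-open (BED convention), because every
external track the analysis consumes is BED-family. The genome size used in
any denominator always comes from the supplied genome model — two-column
TSV of chromosome name and length — never from a constant.

## Block calling

The block caller follows the tiled-FDR definition:

1. The genome is cut into fixed 5 kb tiles.
2. Each sample's tile value is the mean of its observed CpG methylation
   fractions in the tile (a CpG contributes only for samples where it is
   observed; missing values are `NA` in the methylome table). A tile is
   testable when at least `min_tile_cpgs` CpGs are observed in at least one
   sample.
3. Per tile, the case and reference groups are compared with a Welch t-test
   on the per-sample tile means, and p-values are Benjamini–Hochberg
   adjusted **over the testable tiles only** — untestable tiles carry no
   evidence, so they do not dilute the correction.
4. Tiles with `q <= 0.05` and a methylation decrease of at least 35%
   (`delta <= -0.35`) are kept; kept tiles on a chromosome are merged into a
   single block when the gap between them is at most 250 kb, and the block
   spans from the first tile's start to the last tile's end, gaps included —
   this is what produces the multi-hundred-kb block sizes.
5. Blocks with fewer than 5 CpGs (summed over member tiles) are dropped. A
   block's `mean_delta` is the CpG-count-weighted mean of its member tiles'
   deltas.

Two conventions here are this package's own choices rather than published
facts. First, the tile test: tiled-methylome pipelines often use
hierarchical models; we use the Welch t-test because it is simple,
calibrated, and checkable against an independent oracle, and we additionally
support a delta-only mode (`test = "none"`, `use_fdr = FALSE`) for designs
with fewer than two samples per group, where no within-group variance
exists. Second, a block's CpG count includes only CpGs observed in at least
one sample within member tiles, not the unobserved span — conservative and
reproducible.

DMRs are defined as maximal runs of consecutive CpGs (inter-CpG gap at most
1 kb) with a same-sign group difference, containing at least 3 CpGs of which
at least one shows `|delta| > 0.20` at `p <= 0.05`. The run construction is
again a convention this package fixes explicitly, since "regions of any
length" admits several readings; a delta of exactly zero breaks a run. DMCs
are counted per genomic context (islands, shores, shelves, open seas, genes)
with BH correction applied within each context independently, because the
contexts are reported independently.

## Spatial enrichment of features in blocks

For a feature track and a block set on the same genome we report:

- the number and percent of features whose **midpoint** lies in a block.
  Midpoint assignment is the default because it gives each feature exactly
  one unambiguous location; any-overlap counting is available as an option.
- fold enrichment = (fraction of features in blocks) / (fraction of the
  genome covered by blocks). The unrounded feature fraction is used in the
  ratio; reported values are rounded to two decimals. Fold above 1 is
  labelled "Direct" (enrichment), below 1 "Indirect" (depletion), exactly 1
  "Neutral".
- a p-value: for site-like tracks (TF binding sites) an exact two-sided
  binomial **projection test** of the midpoint count against the blocks'
  coverage fraction; for span-like tracks (histone domains, LADs,
  replication timing, repeats) a **Jaccard permutation test**. The
  permutation null relocates each query interval uniformly within its own
  chromosome, preserving its length and allowing overlap among relocated
  intervals — a simple exchangeable null in the spirit of relocation-based
  interval-correlation tools. The permutation p-value uses the add-one
  estimator `(1 + #{J_perm >= J_obs}) / (n_perm + 1)`, with the analogous
  left tail for depletion; the direction label comes from the sign of
  `J_obs - median(J_perm)`.

With 100 permutations the smallest attainable p is ~0.01; the default of
1000 permutations resolves p ≈ 0.001. Permutations are seeded and
reproducible.

## CNA index and block overlap

A sample's CNA index is the fraction of the genome covered by the union of
its gain and loss segments — gains and losses pooled, each base counted
once. Groups are compared with a two-sided Mann–Whitney test. For the
relationship between CNA and blocks, each sample's altered bases are split
into the part inside and outside the block compartment and normalized by
the compartment sizes, giving per-bp densities whose ratio is 1 under
uniform placement. The across-sample comparison defaults to a Wilcoxon
signed-rank test on the per-sample density pairs; a paired t-test is
available. A factorial ANOVA layout is deliberately not offered: the factor
structure such analyses assume is study-specific, and the paired
nonparametric test answers the same question with fewer assumptions.

## Expression statistics

**Regularized t.** The shrunken-variance two-sample test pools each gene's
variance with a background variance estimated from the `window = 101` genes
nearest in average intensity (microarray variance depends strongly on
intensity), with `prior_df = 10` pseudo-observations:
`s2_reg = (prior_df * s2_bg + (n - 2) * s2_gene) / (prior_df + n - 2)`,
t on the shrunk pooled variance with `prior_df + n - 2` degrees of freedom.
With `prior_df = 0` this is exactly the ordinary pooled t-test — the tests
verify agreement to 1e-10 — so the prior strength is interpretable as
added pseudo-replicates. The exact windowing of the original Bayesian
microarray tools is not published in a reimplementable form; this windowed
running-mean background is our documented variant, with both knobs exposed.

**Proliferation normalization.** Maintenance methylation is S-phase work,
so raw expression of DNMT/UHRF1 confounds abundance with proliferation. The
per-sample statistic is `log2(gene) - log2(marker)` against a canonical
proliferation marker (MKI67 by default; PLK1/BUB1 behave similarly), groups
compared by Mann–Whitney. Linear-scale input (values > 30) is rejected with
a message rather than silently log-transformed.

**In-block variability.** Per-gene variability across the case samples is
the raw median absolute deviation `median(|x - median(x)|)` (no consistency
constant — the statistic is compared between gene sets, not against a
normal scale). Genes map to the block compartment by midpoint. The default
comparison is an unpaired Mann–Whitney; a paired mode matches each in-block
gene to the out-of-block gene nearest in mean expression and applies a
paired t-test, since pairing by expression level controls the
intensity–variance relationship.

**Instability signature score.** Given a signature gene list (an input
file — published signatures are not hard-coded), the score is the mean
case-vs-reference log2 fold change over the signature genes present, with
per-gene regularized-t p-values; missing genes warn.

## The synthetic-data generator

Every input the pipeline consumes can be generated with planted, known
structure, so each stage's recovery is testable without external data. The
defaults are the study conditions the analysis assumes: two groups of 4
samples on a 2 × 25 Mb genome; CpGs at mean 500 bp exponential spacing
(dense targeted-methylome-like coverage); baseline methylation 0.8 with
truncated-normal noise sd 0.05 on [0, 1]; planted blocks of 300–900 kb
covering 15% of the genome with per-block decreases uniform in [0.35, 0.5];
feature midpoints placed in blocks with probability `min(1, factor * c)` so
the expected midpoint fold enrichment equals the requested factor; CNA
segments placed in the block compartment with probability
`k*c / (k*c + 1 - c)` so the expected in/out density ratio equals the
concentration `k`; expression with normal baselines, named case-group
shifts (proliferation markers, a 25-gene signature at 0.8 ± 0.1 log2), and
case-sample noise doubled inside blocks. Planted blocks are kept at least
600 kb apart so that distinct planted blocks remain distinct under the
caller's 250 kb merge gap.

What the generator does **not** emulate: beta-distributed methylation noise
(a truncated normal is bounded and simpler; a beta option exists but is off
by default), read-level coverage variation, CpG-density structure (islands
vs open sea), correlated noise between neighbouring CpGs, and tumor purity.
Passing recovery tests therefore demonstrates correctness of the
computations under idealized noise, not performance on real tumor
methylomes.

## Numerical choices and degenerate inputs

- BH ties use the standard cumulative-minimum step-up; `p.adjust` is
  order-invariant, so no tie-break is needed.
- Zero-variance tiles/CpGs: equal means give p = 1, unequal means p = 0
  (the limit of the t statistic).
- Projection test with block coverage exactly 0 or 1: a consistent count
  gives p = 1, an impossible one is guarded to p = 0.
- Empty tile sets and no-pass filters yield empty block sets, not errors;
  empty query/reference sets in the Jaccard test are errors (the statistic
  is undefined).
- Adjacent touching intervals merge during normalization (base-coverage
  semantics), and interval bounds are validated against the genome model
  with errors naming chromosome and coordinates.
- Overlapping same-sample CNA segments with conflicting calls are resolved
  deterministically (later-read call wins on the overlap) with a warning.

## Problem sizes used in the tests

The shipped tests run the block caller over 20 seeds on 2 × 25 Mb genomes
(~100k CpGs × 8 samples each), 100 null runs of 500 tiles for the
false-call rate, 500 null simulations for projection-test calibration, and
200 seeded runs of 100 permutations for the uniformity of the Jaccard
permutation p — sizes chosen to give stable Monte-Carlo estimates while
keeping a full run of the suite comfortable on a laptop. The same sizes are
used by `scripts/acceptance.R`.

## Known limitations

- The Welch-on-tile-means test ignores within-tile CpG count differences
  between samples; a hierarchical/beta-binomial model would weight tiles by
  evidence but is out of scope.
- The Jaccard relocation null conditions on the chromosome of each query
  interval but not on local genome composition (GC, gaps).
- Block-level precision/recall in the tests defines a match at 50%
  reciprocal base overlap; block boundaries are tile-quantized, so exact
  boundary agreement is not expected.
- The two-sample designs here assume independent samples; matched designs
  are not modelled.
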