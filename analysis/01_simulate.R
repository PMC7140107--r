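#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with planted ground truth.
#
# Two sample groups (4 reference epithelium, 4 hypomethylated tumors) on a
# 2 x 25 Mb genome: ~15% of the genome planted as hypomethylated blocks
# (35-50% methylation decrease), a feature track enriched 2x inside blocks
# and a uniform control track, CNA segments concentrated 3x inside blocks,
# and an expression matrix with proliferation-marker shifts, a planted
# instability signature, and 2x in-block expression variability.

suppressMessages(library(hypoblocks))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  seed = 20260919,
  n_chrom = 2, chrom_length = 25e6,
  tracks = list(
    list(name = "LAD", n = 4000, length = 20000, enrichment = 2),
    list(name = "uniform", n = 4000, length = 1000, enrichment = 1)))

mt <- simulate_methylome(cfg)
tracks <- simulate_tracks(cfg, mt$truth, mt$genome)
segs <- simulate_cna(cfg, mt$truth, mt$genome)
xp <- simulate_expression(cfg, mt$truth, mt$genome)

write_genome(mt$genome, "results/data/genome.tsv")
write_methylome(mt$methylome, "results/data/methylome.tsv")
write_bed(mt$truth, "results/data/truth_blocks.bed")
for (nm in names(tracks)) {
  write_bed(tracks[[nm]], sprintf("results/data/track_%s.bed", nm))
}
write_segments(segs, "results/data/segments.tsv")
write_expression(xp$expr, "results/data/expression.tsv")
write_bed(xp$coords, "results/data/genes.bed")
writeLines(c("sample\tgroup",
             paste(mt$samples$ref, "ref", sep = "\t"),
             paste(mt$samples$case, "case", sep = "\t")),
           "results/data/groups.tsv")

cat(sprintf("simulated %d CpGs over %.0f Mb; %d truth blocks covering %.1f%% of the genome\n",
            nrow(mt$methylome), genome_size(mt$genome) / 1e6, nrow(mt$truth),
            100 * coverage_fraction(mt$truth, mt$genome)))
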