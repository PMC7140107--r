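#!/usr/bin/env Rscript
# Stage 2: tiled differential methylation and hypomethylated-block calling.
# 5 kb tiles, Welch t on per-sample tile means, BH FDR <= 0.05 with a >= 35%
# methylation decrease, significant tiles merged when <= 250 kb apart, final
# blocks require >= 5 CpGs. Also calls DMRs and per-context DMCs.

suppressMessages(library(hypoblocks))

genome <- read_genome("results/data/genome.tsv")
meth <- read_methylome("results/data/methylome.tsv", genome)
groups <- read_groups("results/data/groups.tsv")
ref <- names(groups)[groups == "ref"]
case <- names(groups)[groups == "case"]

ts <- tile_differential(meth, ref, case, genome)
write.table(ts, "results/tiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

blocks <- call_hypo_blocks(ts)
out <- blocks
out$name <- sprintf("block_%d", seq_len(nrow(out)))
out$score <- round(-100 * out$mean_delta)
write_bed(out, "results/blocks.bed")

sm <- summarize_blocks(blocks, genome)
truth <- read_bed("results/data/truth_blocks.bed", genome)
cat(sprintf("called %d blocks spanning %.1f Mb (%.1f%% of genome); Jaccard with planted truth %.3f\n",
            sm$n_blocks, sm$total_bases / 1e6, 100 * sm$genome_fraction,
            jaccard_index(blocks[, 1:3], truth)))

dmr <- call_dmr(meth, ref, case)
write.table(dmr, "results/dmr.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
contexts <- list(blocks = truth,
                 outside = interval_complement(truth, genome))
dmc <- call_dmc(meth, ref, case, contexts)
write.table(dmc, "results/dmc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("%d DMRs (%d hypo); DMCs in blocks: %d hypo / %d hyper\n",
            nrow(dmr), sum(dmr$direction == "hypo"),
            dmc$n_hypo[dmc$context == "blocks"],
            dmc$n_hyper[dmc$context == "blocks"]))
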