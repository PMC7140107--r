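#!/usr/bin/env Rscript
# Stage 3: spatial association of the called blocks with the feature tracks
# (fold enrichment of midpoints in blocks; binomial projection test for the
# site-like uniform track, Jaccard permutation test for the span-like track).

suppressMessages(library(hypoblocks))

genome <- read_genome("results/data/genome.tsv")
blocks <- read_bed("results/blocks.bed", genome)
tracks <- list(LAD = read_bed("results/data/track_LAD.bed", genome),
               uniform = read_bed("results/data/track_uniform.bed", genome))

tab <- enrich_table(blocks, tracks, genome,
                    tests = c(LAD = "jaccard", uniform = "projection"),
                    cfg = permutation_config(1000, seed = 7))
write.table(tab, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (i in seq_len(nrow(tab))) {
  cat(sprintf("%-8s %5d/%5d midpoints in blocks (%.0f%%), fold %.2f, %s, %s p = %.3g\n",
              tab$feature[i], tab$n_in[i], tab$n_total[i],
              tab$pct_in_blocks[i], tab$fold[i], tab$direction[i],
              tab$test[i], tab$p[i]))
}
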