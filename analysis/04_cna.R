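#!/usr/bin/env Rscript
# Stage 4: per-sample CNA index (fraction of genome gained or lost), group
# comparison by Mann-Whitney, and coverage-normalized CNA density inside
# versus outside the called blocks (Wilcoxon signed-rank across samples).

suppressMessages(library(hypoblocks))

genome <- read_genome("results/data/genome.tsv")
blocks <- read_bed("results/blocks.bed", genome)
segs <- read_segments("results/data/segments.tsv", genome)
groups <- read_groups("results/data/groups.tsv")

idx <- cna_index(segs, genome)
write.table(idx, "results/cna_index.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cmp <- cna_compare_groups(idx, groups, ref = "ref", case = "case")
cat(sprintf("CNA index medians: ref %.3f, case %.3f (Mann-Whitney p = %.3g)\n",
            cmp$medians["ref"], cmp$medians["case"], cmp$p))

case_segs <- segs[groups[segs$sample] == "case", ]
ov <- cna_block_overlap(case_segs, blocks, genome)
jsonlite::write_json(
  list(density_in = ov$density_in, density_out = ov$density_out,
       density_ratio = ov$density_ratio, p = ov$p,
       bases_in_blocks = ov$bases_in_blocks, bases_outside = ov$bases_outside),
  "results/cna_overlap.json", auto_unbox = TRUE, digits = 10)
cat(sprintf("case CNA density: %.4f/bp in blocks vs %.4f/bp outside (ratio %.2f, p = %.3g)\n",
            ov$density_in, ov$density_out, ov$density_ratio, ov$p))
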