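# Brute-force per-base oracles, independent of the interval implementation.
# Only usable on small genomes (<= ~1e6 bp): every chromosome is materialized
# as a logical base vector.

bf_base_mask <- function(set, genome) {
  masks <- lapply(seq_len(nrow(genome)), function(i) {
    m <- logical(genome$length[i])
    rows <- which(set$chrom == genome$chrom[i])
    for (r in rows) m[(set$start[r] + 1):set$end[r]] <- TRUE
    m
  })
  names(masks) <- genome$chrom
  masks
}

bf_bases <- function(set, genome) {
  sum(vapply(bf_base_mask(set, genome), sum, 0))
}

bf_intersect_bases <- function(a, b, genome) {
  ma <- bf_base_mask(a, genome)
  mb <- bf_base_mask(b, genome)
  sum(vapply(genome$chrom, function(ch) sum(ma[[ch]] & mb[[ch]]), 0))
}

bf_setdiff_bases <- function(a, b, genome) {
  ma <- bf_base_mask(a, genome)
  mb <- bf_base_mask(b, genome)
  sum(vapply(genome$chrom, function(ch) sum(ma[[ch]] & !mb[[ch]]), 0))
}

# random interval fixture on a given genome
random_intervals <- function(n, genome, max_len = 1000) {
  ci <- sample.int(nrow(genome), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (genome$length[ci] - len))
  intervals(genome$chrom[ci], start, start + len)
}

withr_tempfile <- function(name) tempfile(fileext = paste0("_", name))

# tiny deterministic methylome: one row per CpG, explicit per-sample values
make_methylome <- function(chrom, pos, ref_vals, case_vals,
                           ref_names = paste0("r", seq_len(ncol(ref_vals))),
                           case_names = paste0("c", seq_len(ncol(case_vals)))) {
  df <- data.frame(chrom = chrom, pos = pos)
  for (j in seq_len(ncol(ref_vals))) df[[ref_names[j]]] <- ref_vals[, j]
  for (j in seq_len(ncol(case_vals))) df[[case_names[j]]] <- case_vals[, j]
  df
}
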