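#' Per-sample copy-number alteration index
#'
#' The CNA index of a sample is the fraction of the genome covered by the
#' union of its gain and loss segments (each base counted once even when
#' both calls touch it); `neutral` segments are ignored.
#'
#' @param segments segment `data.frame` (`sample`, `chrom`, `start`, `end`,
#'   `call`), per-sample non-overlapping (see [read_segments()]).
#' @param genome a `genome_model`.
#' @return `data.frame`: `sample`, `fraction_altered`, `bases_gain`,
#'   `bases_loss`, `bases_altered`.
#' @export
cna_index <- function(segments, genome) {
  samples <- unique(segments$sample)
  rows <- lapply(samples, function(s) {
    seg <- segments[segments$sample == s & segments$call != "neutral", ,
                    drop = FALSE]
    iv <- seg[, c("chrom", "start", "end")]
    data.frame(
      sample = s,
      fraction_altered = coverage_fraction(iv, genome),
      bases_gain = interval_bases(seg[seg$call == "gain",
                                      c("chrom", "start", "end")]),
      bases_loss = interval_bases(seg[seg$call == "loss",
                                      c("chrom", "start", "end")]),
      bases_altered = interval_bases(iv, genome),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare CNA indices between two sample groups (Mann-Whitney)
#'
#' @param indices `data.frame` from [cna_index()] (or any table with `sample`
#'   and `fraction_altered`).
#' @param groups named character vector mapping sample to group label; exactly
#'   the two labels present among `indices$sample` are compared.
#' @param ref,case optional explicit group labels (reference first).
#' @return List: `medians` (named per group), `U` (Mann-Whitney statistic for
#'   the case group), `p` (two-sided).
#' @export
cna_compare_groups <- function(indices, groups, ref = NULL, case = NULL) {
  g <- groups[indices$sample]
  if (anyNA(g)) stop("samples without group label: ",
                     paste(indices$sample[is.na(g)], collapse = ", "))
  labs <- unique(g)
  if (is.null(ref) || is.null(case)) {
    if (length(labs) != 2) stop("need exactly two groups, got: ",
                                paste(labs, collapse = ", "))
    ref <- labs[1]; case <- labs[2]
  }
  x_ref <- indices$fraction_altered[g == ref]
  x_case <- indices$fraction_altered[g == case]
  if (length(x_ref) == 0 || length(x_case) == 0) {
    stop("empty group in comparison (", ref, " vs ", case, ")")
  }
  wt <- suppressWarnings(stats::wilcox.test(x_case, x_ref,
                                            alternative = "two.sided"))
  list(medians = stats::setNames(c(stats::median(x_ref), stats::median(x_case)),
                                 c(ref, case)),
       U = unname(wt$statistic), p = wt$p.value)
}

#' Coverage-normalized CNA overlap with hypomethylated blocks
#'
#' Splits each sample's altered bases into the part inside and outside the
#' block compartment and normalizes each by that compartment's size, giving
#' comparable per-bp densities; the in- vs out-density difference across
#' samples is tested (default Wilcoxon signed-rank on the per-sample pairs; a
#' paired t-test is available).
#'
#' @param segments segment `data.frame` (gain and loss pooled; `neutral`
#'   ignored).
#' @param blocks interval `data.frame` of blocks covering neither 0 nor 100%
#'   of the genome.
#' @param genome a `genome_model`.
#' @param test `"wilcoxon"` (default) or `"ttest"`.
#' @return List: `per_sample` data.frame (`sample`, `bases_in`, `bases_out`,
#'   `density_in`, `density_out`), totals (`bases_in_blocks`,
#'   `bases_outside`), pooled `density_in`/`density_out`, `density_ratio`,
#'   and `p`.
#' @export
cna_block_overlap <- function(segments, blocks, genome,
                              test = c("wilcoxon", "ttest")) {
  test <- match.arg(test)
  bl <- normalize_intervals(blocks, genome)
  bb <- sum_w(bl)
  gs <- genome_size(genome)
  if (bb <= 0 || bb >= gs) {
    stop("degenerate block compartment: blocks cover ",
         round(100 * bb / gs, 1), "% of the genome")
  }
  nb <- gs - bb
  samples <- unique(segments$sample)
  rows <- lapply(samples, function(s) {
    iv <- normalize_intervals(
      segments[segments$sample == s & segments$call != "neutral",
               c("chrom", "start", "end")], genome)
    inb <- intersect_bases(iv, bl)
    tot <- sum_w(iv)
    data.frame(sample = s, bases_in = inb, bases_out = tot - inb,
               density_in = inb / bb, density_out = (tot - inb) / nb,
               stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  rownames(per_sample) <- NULL
  d_in <- sum(per_sample$bases_in) / (bb * nrow(per_sample))
  d_out <- sum(per_sample$bases_out) / (nb * nrow(per_sample))
  p <- if (nrow(per_sample) < 2 ||
           all(per_sample$density_in == per_sample$density_out)) {
    NA_real_
  } else if (test == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(per_sample$density_in,
                                        per_sample$density_out,
                                        paired = TRUE)$p.value)
  } else {
    stats::t.test(per_sample$density_in, per_sample$density_out,
                  paired = TRUE)$p.value
  }
  list(per_sample = per_sample,
       bases_in_blocks = sum(per_sample$bases_in),
       bases_outside = sum(per_sample$bases_out),
       density_in = d_in, density_out = d_out,
       density_ratio = if (d_out > 0) d_in / d_out else Inf,
       p = p)
}
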