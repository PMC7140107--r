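#' Block-calling configuration
#'
#' Defaults mirror the standard tiled-FDR block definition: 5 kb tiles at
#' FDR <= 0.05 with a >= 35% average methylation decrease, significant tiles
#' merged when <= 250 kb apart, and final blocks required to contain >= 5
#' CpGs.
#'
#' @param tile_size tile width, bp.
#' @param fdr_threshold BH q-value cutoff for a tile, in (0, 1).
#' @param min_delta minimum methylation-fraction decrease (positive number; a
#'   tile is kept when `delta <= -min_delta`), in (0, 1).
#' @param merge_gap maximum gap between kept tiles merged into one block, bp.
#' @param min_block_cpgs minimum summed CpG count for a final block.
#' @param min_tile_cpgs minimum observed CpGs for a tile to be testable.
#' @param use_fdr if `FALSE`, tiles are selected on delta alone (for
#'   delta-only tile statistics, e.g. two samples per group).
#' @return A list of class `block_config`.
#' @export
block_config <- function(tile_size = 5000, fdr_threshold = 0.05,
                         min_delta = 0.35, merge_gap = 250000,
                         min_block_cpgs = 5, min_tile_cpgs = 1,
                         use_fdr = TRUE) {
  stopifnot(tile_size > 0, fdr_threshold > 0, fdr_threshold < 1,
            min_delta > 0, min_delta < 1, merge_gap > 0,
            min_block_cpgs > 0, min_tile_cpgs > 0)
  structure(list(tile_size = tile_size, fdr_threshold = fdr_threshold,
                 min_delta = min_delta, merge_gap = merge_gap,
                 min_block_cpgs = min_block_cpgs,
                 min_tile_cpgs = min_tile_cpgs, use_fdr = use_fdr),
            class = "block_config")
}

#' Assemble hypomethylated blocks from tile statistics
#'
#' Keeps tiles with `q <= fdr_threshold` and `delta <= -min_delta`, merges
#' kept tiles on the same chromosome whose gap (end of one to start of the
#' next) is `<= merge_gap` into a single block spanning first start to last
#' end (intervening gaps included in the span), and drops blocks whose summed
#' CpG count is below `min_block_cpgs`. A block's `mean_delta` is the
#' CpG-count-weighted mean of its member tiles' deltas.
#'
#' @param tilestats output of [tile_differential()].
#' @param config a [block_config()].
#' @return `data.frame` of blocks: `chrom`, `start`, `end`, `n_cpgs`,
#'   `n_tiles`, `mean_delta`; empty input or no passing tiles give an empty
#'   set, not an error.
#' @export
call_hypo_blocks <- function(tilestats, config = block_config()) {
  stopifnot(inherits(config, "block_config"))
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_cpgs = numeric(), n_tiles = integer(),
                      mean_delta = numeric(), stringsAsFactors = FALSE)
  if (is.null(tilestats) || nrow(tilestats) == 0) return(empty)
  keep <- tilestats$delta <= -config$min_delta
  if (config$use_fdr) {
    if (all(is.na(tilestats$q))) {
      stop("tile statistics carry no q-values; rerun tile_differential with ",
           "test = \"welch\" or set use_fdr = FALSE in block_config")
    }
    keep <- keep & !is.na(tilestats$q) & tilestats$q <= config$fdr_threshold
  }
  keep[is.na(keep)] <- FALSE
  kept <- tilestats[keep, , drop = FALSE]
  if (nrow(kept) == 0) return(empty)

  kept <- kept[order(kept$chrom, kept$start), , drop = FALSE]
  new_block <- c(TRUE, kept$chrom[-1] != kept$chrom[-nrow(kept)] |
                   kept$start[-1] - kept$end[-nrow(kept)] > config$merge_gap)
  bid <- cumsum(new_block)
  agg <- function(f, x) as.vector(tapply(x, bid, f))
  blocks <- data.frame(
    chrom = agg(function(x) x[1], kept$chrom),
    start = agg(min, kept$start),
    end = agg(max, kept$end),
    n_cpgs = agg(sum, kept$n_cpgs),
    n_tiles = as.integer(agg(length, kept$start)),
    mean_delta = as.vector(tapply(seq_along(bid), bid, function(i) {
      stats::weighted.mean(kept$delta[i], kept$n_cpgs[i])
    })),
    stringsAsFactors = FALSE)
  blocks <- blocks[blocks$n_cpgs >= config$min_block_cpgs, , drop = FALSE]
  blocks <- blocks[order(blocks$chrom, blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

#' Summarize a block set against its genome
#' @param blocks block `data.frame` from [call_hypo_blocks()].
#' @param genome a `genome_model`.
#' @return List: `n_blocks`, `total_bases`, `genome_fraction`.
#' @export
summarize_blocks <- function(blocks, genome) {
  list(n_blocks = nrow(blocks),
       total_bases = interval_bases(blocks[, c("chrom", "start", "end")]),
       genome_fraction = coverage_fraction(blocks[, c("chrom", "start", "end")],
                                           genome))
}
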