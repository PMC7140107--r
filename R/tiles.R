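#' Tile a genome into fixed-width windows
#'
#' Non-overlapping tiles cover each chromosome exactly once; the last tile of
#' a chromosome is truncated at the chromosome end.
#'
#' @param genome a `genome_model`.
#' @param tile_size tile width in bp (> 0); default 5000.
#' @return Interval `data.frame` with columns `chrom`, `start`, `end`.
#' @export
tile_genome <- function(genome, tile_size = 5000) {
  stopifnot(inherits(genome, "genome_model"), tile_size > 0)
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq(0, len - 1, by = tile_size)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = pmin(starts + tile_size, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "tile_size") <- tile_size
  out
}

#' Tiled differential methylation between two sample groups
#'
#' Each sample's tile value is the mean of its observed CpG fractions in the
#' tile; the tile statistic compares per-sample tile means between groups with
#' a Welch t-test, and q-values are Benjamini-Hochberg adjusted over all
#' emitted tiles (tiles meeting `min_tile_cpgs`; untestable tiles carry no
#' evidence and do not enter the correction).
#'
#' @param methylome methylome `data.frame` (`chrom`, `pos`, sample columns).
#' @param ref_samples,case_samples character vectors of sample column names;
#'   `delta = mean(case) - mean(ref)`, so hypomethylation in the case group
#'   gives negative delta.
#' @param genome a `genome_model`.
#' @param tile_size tile width in bp.
#' @param min_tile_cpgs minimum CpGs observed in >= 1 sample for a tile to be
#'   emitted.
#' @param test `"welch"` (default; needs >= 2 samples per group) or `"none"`
#'   for delta-only mode (p and q are `NA`), the mode to use when a group has
#'   fewer than two samples.
#' @return `data.frame` with one row per emitted tile: `chrom`, `start`,
#'   `end`, `n_cpgs`, `mean_ref`, `mean_case`, `delta`, `p`, `q`.
#' @export
tile_differential <- function(methylome, ref_samples, case_samples, genome,
                              tile_size = 5000, min_tile_cpgs = 1,
                              test = c("welch", "none")) {
  test <- match.arg(test)
  samples <- c(ref_samples, case_samples)
  missing_s <- setdiff(samples, names(methylome))
  if (length(missing_s)) {
    stop("sample(s) not in methylome: ", paste(missing_s, collapse = ", "))
  }
  if (test == "welch" && (length(ref_samples) < 2 || length(case_samples) < 2)) {
    stop("Welch p-values need >= 2 samples per group; use test = \"none\" ",
         "(delta-only mode) for smaller groups")
  }
  dt <- data.table::as.data.table(methylome[, c("chrom", "pos", samples)])
  long <- data.table::melt(dt, id.vars = c("chrom", "pos"),
                           variable.name = "sample_id", value.name = "value",
                           variable.factor = FALSE)
  long <- long[!is.na(value)]
  long[, tile_idx := pos %/% tile_size]
  long[, grp := data.table::fifelse(sample_id %in% ref_samples, "ref", "case")]

  # per-sample tile means
  sm <- long[, .(tile_mean = mean(value)), by = .(chrom, tile_idx, sample_id, grp)]
  # per-tile group summaries over per-sample tile means
  gs <- sm[, .(n_obs = .N, m = mean(tile_mean),
               v = if (.N > 1) stats::var(tile_mean) else NA_real_),
           by = .(chrom, tile_idx, grp)]
  wide <- data.table::dcast(gs, chrom + tile_idx ~ grp,
                            value.var = c("n_obs", "m", "v"))
  for (col in c("n_obs_ref", "n_obs_case", "m_ref", "m_case", "v_ref", "v_case")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide$n_obs_ref[is.na(wide$n_obs_ref)] <- 0
  wide$n_obs_case[is.na(wide$n_obs_case)] <- 0

  # CpGs observed in >= 1 sample, per tile
  ncp <- long[, .(n_cpgs = data.table::uniqueN(pos)), by = .(chrom, tile_idx)]
  res <- merge(wide, ncp, by = c("chrom", "tile_idx"))
  res <- res[res$n_cpgs >= min_tile_cpgs, ]

  chrom_len <- .chrom_lengths(res$chrom, genome)
  out <- data.frame(chrom = res$chrom,
                    start = res$tile_idx * tile_size,
                    end = pmin((res$tile_idx + 1) * tile_size, chrom_len),
                    n_cpgs = res$n_cpgs,
                    mean_ref = res$m_ref, mean_case = res$m_case,
                    delta = res$m_case - res$m_ref,
                    stringsAsFactors = FALSE)
  if (test == "welch") {
    out$p <- welch_p(res$m_ref, res$v_ref, res$n_obs_ref,
                     res$m_case, res$v_case, res$n_obs_case)
  } else {
    out$p <- NA_real_
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(match(out$chrom, genome$chrom), out$start), ]
  rownames(out) <- NULL
  out
}

# vectorized Welch two-sample t-test p-value; NA when a group has < 2 values;
# zero-variance ties resolved by the mean difference (p = 1 if equal, 0 if not)
welch_p <- function(m1, v1, n1, m2, v2, n2) {
  p <- rep(NA_real_, length(m1))
  ok <- !is.na(n1) & !is.na(n2) & n1 >= 2 & n2 >= 2 &
    !is.na(v1) & !is.na(v2)
  se2 <- v1[ok] / n1[ok] + v2[ok] / n2[ok]
  d <- m2[ok] - m1[ok]
  tt <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1[ok] / n1[ok])^2 / (n1[ok] - 1) +
                          (v2[ok] / n2[ok])^2 / (n2[ok] - 1)),
               n1[ok] + n2[ok] - 2)
  p[ok] <- ifelse(is.finite(tt), 2 * stats::pt(-abs(tt), df),
                  ifelse(tt == 0, 1, 0))
  p[ok][!is.finite(tt)] <- 0
  p[ok][tt == 0 & se2 == 0] <- 1
  p
}
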