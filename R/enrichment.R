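#' Count features falling in blocks
#'
#' A feature is assigned to the block set by containment of its midpoint
#' (default: one unambiguous assignment per feature); `mode = "any"` counts a
#' feature when it overlaps a block by >= 1 bp.
#'
#' @param features interval `data.frame` of features (sites, peaks, repeats).
#' @param blocks interval `data.frame` of reference blocks.
#' @param mode `"midpoint"` (default) or `"any"`.
#' @return List with `n_total` and `n_in`.
#' @export
count_in_blocks <- function(features, blocks, mode = c("midpoint", "any")) {
  mode <- match.arg(mode)
  validate_intervals(features)
  bl <- normalize_intervals(blocks)
  n_total <- nrow(features)
  if (n_total == 0 || nrow(bl) == 0) return(list(n_total = n_total, n_in = 0L))
  if (mode == "midpoint") {
    mp <- interval_midpoints(features)
    n_in <- sum(.points_in_set(mp$chrom, mp$pos, bl))
  } else {
    g <- .harmonize(.as_granges(features), .as_granges(bl))
    n_in <- sum(IRanges::overlapsAny(g[[1]], g[[2]]))
  }
  list(n_total = n_total, n_in = as.integer(n_in))
}

#' Fold enrichment of features in blocks
#'
#' The fraction of features in blocks divided by the genome fraction the
#' blocks cover. The unrounded feature fraction is used; `fold_rounded` gives
#' the 2-decimal reporting value.
#'
#' @param n_in features in blocks.
#' @param n_total all features (> 0).
#' @param genome_fraction block genome coverage, in (0, 1].
#' @return List: `fold` (exact), `fold_rounded` (2 dp), `pct_in_blocks`
#'   (exact percent), `pct_rounded` (integer percent).
#' @export
fold_enrichment <- function(n_in, n_total, genome_fraction) {
  if (n_total <= 0) stop("fold enrichment undefined for n_total = 0")
  stopifnot(n_in >= 0, n_in <= n_total,
            genome_fraction > 0, genome_fraction <= 1)
  frac <- n_in / n_total
  fold <- frac / genome_fraction
  list(fold = fold, fold_rounded = round(fold, 2),
       pct_in_blocks = 100 * frac, pct_rounded = round(100 * frac))
}

#' Binomial projection test for point features in blocks
#'
#' Projects each feature to its midpoint and tests the number of midpoints
#' inside the block set against the blocks' genome coverage fraction with an
#' exact two-sided binomial test.
#'
#' @inheritParams count_in_blocks
#' @param genome a `genome_model`.
#' @return List: `k` (midpoints in blocks), `n`, `p0` (block coverage
#'   fraction), `p` (two-sided).
#' @export
projection_test <- function(features, blocks, genome) {
  bl <- normalize_intervals(blocks, genome)
  cnt <- count_in_blocks(features, bl, mode = "midpoint")
  k <- cnt$n_in; n <- cnt$n_total
  p0 <- coverage_fraction(bl, genome)
  if (p0 %in% c(0, 1)) {
    consistent <- (p0 == 0 && k == 0) || (p0 == 1 && k == n)
    p <- if (consistent) 1 else 0
  } else {
    p <- stats::binom.test(k, n, p = p0, alternative = "two.sided")$p.value
  }
  list(k = k, n = n, p0 = p0, p = p)
}

#' Permutation configuration for interval tests
#' @param n_permutations number of relocations (>= 100).
#' @param seed integer RNG seed.
#' @return List of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 1000, seed = 1) {
  stopifnot(n_permutations >= 100)
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)), class = "permutation_config")
}

#' Jaccard permutation test between two interval sets
#'
#' The observed statistic is the base-pair Jaccard index
#' `J = |query n reference| / |query u reference|`. The null relocates each
#' query interval uniformly within its own chromosome, preserving its length
#' and allowing overlap among relocated intervals; the permutation p-value is
#' `(1 + #(J_perm >= J_obs)) / (n_perm + 1)` for enrichment ("Direct") and the
#' analogous left tail for depletion ("Indirect"); the reported direction is
#' the sign of `J_obs - median(J_perm)`.
#'
#' @param query,reference interval `data.frame`s (both non-empty).
#' @param genome a `genome_model`.
#' @param cfg a [permutation_config()].
#' @return List: `j_obs`, `perm_p` (tail matching `direction`), `p_direct`,
#'   `p_indirect`, `direction` (`"Direct"`/`"Indirect"`/`"Neutral"`),
#'   `j_perm_median`.
#' @export
jaccard_test <- function(query, reference, genome, cfg = permutation_config()) {
  stopifnot(inherits(cfg, "permutation_config"))
  validate_intervals(query, genome)
  r <- normalize_intervals(reference, genome)
  if (nrow(query) == 0 || nrow(r) == 0) {
    stop("jaccard_test needs non-empty query and reference sets")
  }
  j_obs <- jaccard_index(query, r)
  # relocate the query intervals as supplied (not their merged union), so the
  # null reproduces the observed set's generative granularity
  j_perm <- jaccard_null(query[, c("chrom", "start", "end")], r, genome,
                         cfg$n_permutations, cfg$seed)
  n_ge <- sum(j_perm >= j_obs)
  n_le <- sum(j_perm <= j_obs)
  p_direct <- (1 + n_ge) / (cfg$n_permutations + 1)
  p_indirect <- (1 + n_le) / (cfg$n_permutations + 1)
  med <- stats::median(j_perm)
  direction <- if (j_obs > med) "Direct" else if (j_obs < med) "Indirect" else "Neutral"
  perm_p <- switch(direction, Direct = p_direct, Indirect = p_indirect,
                   Neutral = min(1, 2 * min(p_direct, p_indirect)))
  list(j_obs = j_obs, perm_p = perm_p, p_direct = p_direct,
       p_indirect = p_indirect, direction = direction, j_perm_median = med)
}

#' Base-pair Jaccard index of two interval sets
#' @inheritParams intersect_bases
#' @return `intersection / union` in base pairs (0 when both empty).
#' @export
jaccard_index <- function(a, b, genome = NULL) {
  a <- normalize_intervals(a, genome)
  b <- normalize_intervals(b, genome)
  inter <- intersect_bases(a, b)
  uni <- sum_w(a) + sum_w(b) - inter
  if (uni == 0) 0 else inter / uni
}

# vectorized null: relocate all query intervals for all permutations at once,
# flatten per permutation, intersect with the (pre-flattened) reference
jaccard_null <- function(q, r, genome, n_perm, seed) {
  withr_seed(seed, {
    qlen <- q$end - q$start
    chrom_len <- .chrom_lengths(q$chrom, genome)
    nq <- nrow(q)
    dt <- data.table::data.table(
      perm = rep(seq_len(n_perm), each = nq),
      chrom = rep(q$chrom, n_perm),
      w = rep(qlen, n_perm))
    maxs <- rep(chrom_len - qlen, n_perm)
    dt[, start := floor(stats::runif(.N) * (maxs + 1))]
    dt[, end := start + w]
    data.table::setkey(dt, perm, chrom, start)
    # flatten per permutation: new run when the running max end (within this
    # perm and chromosome) does not reach the next start
    dt[, grp := {
      ce <- cummax(end)
      cumsum(c(1L, as.integer(ce[-.N] < start[-1])))
    }, by = .(perm, chrom)]
    flat <- dt[, .(start = min(start), end = max(end)), by = .(perm, chrom, grp)]
    rdt <- data.table::as.data.table(r)
    data.table::setkey(rdt, chrom, start, end)
    ov <- data.table::foverlaps(flat, rdt, by.x = c("chrom", "start", "end"),
                                type = "any", nomatch = NULL)
    ov[, inter := pmin(end, i.end) - pmax(start, i.start)]
    inter_by_perm <- ov[, .(inter = sum(inter)), by = perm]
    qb <- flat[, .(qb = sum(end - start)), by = perm]
    res <- merge(qb, inter_by_perm, by = "perm", all.x = TRUE)
    res$inter[is.na(res$inter)] <- 0
    rb <- sum_w(r)
    res$inter / (res$qb + rb - res$inter)
  })
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Enrichment table across feature tracks
#'
#' One row per track mirroring block/feature-correlation tables: feature
#' counts in blocks, percent, fold enrichment against the blocks' genome
#' fraction, direction, and a spatial test p-value — the binomial projection
#' test for site-like tracks, the Jaccard permutation test for span-like
#' tracks.
#'
#' @param blocks interval `data.frame` of reference blocks.
#' @param tracks named list of feature interval `data.frame`s.
#' @param genome a `genome_model`.
#' @param tests named character vector mapping track names to `"projection"`
#'   or `"jaccard"`; unnamed tracks default to `"projection"`.
#' @param cfg a [permutation_config()] for Jaccard tracks.
#' @return `data.frame` with one row per track: `feature`, `n_total`, `n_in`,
#'   `pct_in_blocks`, `genome_fraction`, `fold`, `direction`, `test`, `p`.
#' @export
enrich_table <- function(blocks, tracks, genome, tests = NULL,
                         cfg = permutation_config()) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  bl <- normalize_intervals(blocks, genome)
  gf <- coverage_fraction(bl, genome)
  rows <- lapply(names(tracks), function(nm) {
    tr <- tracks[[nm]]
    test <- if (!is.null(tests) && nm %in% names(tests)) tests[[nm]] else "projection"
    cnt <- count_in_blocks(tr, bl)
    fe <- fold_enrichment(cnt$n_in, cnt$n_total, gf)
    if (test == "projection") {
      p <- projection_test(tr, bl, genome)$p
    } else if (test == "jaccard") {
      p <- jaccard_test(tr, bl, genome, cfg)$perm_p
    } else stop("unknown test '", test, "' for track ", nm)
    direction <- if (fe$fold > 1) "Direct" else if (fe$fold < 1) "Indirect" else "Neutral"
    data.frame(feature = nm, n_total = cnt$n_total, n_in = cnt$n_in,
               pct_in_blocks = fe$pct_in_blocks, genome_fraction = gf,
               fold = fe$fold, direction = direction, test = test, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
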