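#' Per-CpG differential methylation statistics
#'
#' Group means, delta (case - ref) and a Welch t-test p-value per CpG site,
#' across samples with the site observed. Sites with fewer than two observed
#' samples in either group get `p = NA`; sites with no observed samples in a
#' group are dropped (no delta is defined for them).
#'
#' @inheritParams tile_differential
#' @return `data.frame`: `chrom`, `pos`, `n_ref`, `n_case`, `mean_ref`,
#'   `mean_case`, `delta`, `p`.
#' @export
cpg_differential <- function(methylome, ref_samples, case_samples) {
  rs <- as.matrix(methylome[, ref_samples, drop = FALSE])
  cs <- as.matrix(methylome[, case_samples, drop = FALSE])
  n1 <- rowSums(!is.na(rs)); n2 <- rowSums(!is.na(cs))
  m1 <- rowMeans(rs, na.rm = TRUE); m2 <- rowMeans(cs, na.rm = TRUE)
  v1 <- row_var(rs); v2 <- row_var(cs)
  out <- data.frame(chrom = methylome$chrom, pos = methylome$pos,
                    n_ref = n1, n_case = n2, mean_ref = m1, mean_case = m2,
                    delta = m2 - m1,
                    p = welch_p(m1, v1, n1, m2, v2, n2),
                    stringsAsFactors = FALSE)
  out <- out[n1 > 0 & n2 > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

row_var <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  ifelse(n > 1, ss / (n - 1), NA_real_)
}

#' DMR-calling configuration
#'
#' A differentially methylated region is a run of >= 3 consecutive same-sign
#' CpGs in which at least one CpG shows a methylation change > 20% at
#' p <= 0.05 (the defaults).
#'
#' @param min_region_cpgs minimum CpGs per region.
#' @param per_cpg_delta per-CpG |delta| threshold, fraction in (0, 1).
#' @param per_cpg_p per-CpG p-value threshold (for DMC calling this acts on
#'   the BH q-value).
#' @param max_cpg_gap maximum bp between consecutive CpGs within one region.
#' @return List of class `dmr_config`.
#' @export
dmr_config <- function(min_region_cpgs = 3, per_cpg_delta = 0.20,
                       per_cpg_p = 0.05, max_cpg_gap = 1000) {
  stopifnot(min_region_cpgs > 0, per_cpg_delta > 0, per_cpg_delta < 1,
            per_cpg_p > 0, per_cpg_p < 1, max_cpg_gap > 0)
  structure(list(min_region_cpgs = min_region_cpgs,
                 per_cpg_delta = per_cpg_delta, per_cpg_p = per_cpg_p,
                 max_cpg_gap = max_cpg_gap), class = "dmr_config")
}

#' Call differentially methylated regions (DMR)
#'
#' Candidate regions are maximal runs of consecutive CpGs with inter-CpG gap
#' `<= max_cpg_gap` and same-sign group difference (delta of zero breaks a
#' run). A candidate is emitted when it has `>= min_region_cpgs` CpGs and at
#' least one CpG with `|delta| > per_cpg_delta` at `p <= per_cpg_p`.
#'
#' @inheritParams tile_differential
#' @param config a [dmr_config()].
#' @return `data.frame`: `chrom`, `start`, `end` (half-open span covering the
#'   member CpG sites), `n_cpgs`, `n_passing`, `mean_delta`, `direction`
#'   (`"hyper"`/`"hypo"`).
#' @export
call_dmr <- function(methylome, ref_samples, case_samples,
                     config = dmr_config()) {
  stopifnot(inherits(config, "dmr_config"))
  st <- cpg_differential(methylome, ref_samples, case_samples)
  st <- st[st$delta != 0, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_cpgs = integer(), n_passing = integer(),
                      mean_delta = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  if (nrow(st) == 0) return(empty)
  st <- st[order(st$chrom, st$pos), , drop = FALSE]
  brk <- c(TRUE, st$chrom[-1] != st$chrom[-nrow(st)] |
             st$pos[-1] - st$pos[-nrow(st)] > config$max_cpg_gap |
             sign(st$delta[-1]) != sign(st$delta[-nrow(st)]))
  rid <- cumsum(brk)
  pass <- abs(st$delta) > config$per_cpg_delta &
    !is.na(st$p) & st$p <= config$per_cpg_p
  regions <- do.call(rbind, lapply(split(seq_len(nrow(st)), rid), function(i) {
    data.frame(chrom = st$chrom[i[1]], start = min(st$pos[i]),
               end = max(st$pos[i]) + 1, n_cpgs = length(i),
               n_passing = sum(pass[i]), mean_delta = mean(st$delta[i]),
               direction = if (st$delta[i[1]] < 0) "hypo" else "hyper",
               stringsAsFactors = FALSE)
  }))
  regions <- regions[regions$n_cpgs >= config$min_region_cpgs &
                       regions$n_passing >= 1, , drop = FALSE]
  rownames(regions) <- NULL
  regions
}

#' Count differentially methylated CpGs (DMC) per genomic context
#'
#' Within each context track (e.g. CpG islands, shores, shelves, open seas,
#' genes) independently: BH-adjust the per-CpG p-values of the CpGs falling in
#' that context, and count sites with `|delta| > per_cpg_delta` and
#' `q <= per_cpg_p`, split into hyper- (delta > 0) and hypomethylated
#' (delta < 0). A CpG may belong to several contexts.
#'
#' @inheritParams call_dmr
#' @param context_tracks named list of interval `data.frame`s.
#' @param which optional character vector of context names to evaluate;
#'   unknown names error.
#' @return `data.frame`: `context`, `n_cpgs`, `n_hyper`, `n_hypo`.
#' @export
call_dmc <- function(methylome, ref_samples, case_samples, context_tracks,
                     config = dmr_config(), which = NULL) {
  stopifnot(inherits(config, "dmr_config"), is.list(context_tracks),
            !is.null(names(context_tracks)))
  if (is.null(which)) which <- names(context_tracks)
  unknown <- setdiff(which, names(context_tracks))
  if (length(unknown)) {
    stop("unknown context name(s): ", paste(unknown, collapse = ", "),
         " (available: ", paste(names(context_tracks), collapse = ", "), ")")
  }
  st <- cpg_differential(methylome, ref_samples, case_samples)
  out <- lapply(which, function(ctx) {
    set <- normalize_intervals(context_tracks[[ctx]])
    inside <- .points_in_set(st$chrom, st$pos, set)
    s <- st[inside, , drop = FALSE]
    q <- stats::p.adjust(s$p, method = "BH")
    dmc <- abs(s$delta) > config$per_cpg_delta & !is.na(q) &
      q <= config$per_cpg_p
    data.frame(context = ctx, n_cpgs = nrow(s),
               n_hyper = sum(dmc & s$delta > 0),
               n_hypo = sum(dmc & s$delta < 0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
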