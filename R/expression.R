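#' Regularized (shrunken-variance) two-sample t-test
#'
#' For each gene, the pooled two-sample variance is shrunk toward a background
#' variance estimated from the `window` genes nearest in average intensity
#' (genes ranked by mean log2 expression over both groups; windows truncate at
#' the rank extremes):
#' `s2_reg = (prior_df * s2_background + (n - 2) * s2_gene) / (prior_df + n - 2)`,
#' with the t statistic on the shrunk pooled variance and
#' `prior_df + n - 2` degrees of freedom. `prior_df = 0` reduces exactly to the
#' ordinary equal-variance two-sample t-test.
#'
#' @param expr numeric log2 expression matrix (genes x samples).
#' @param ref_samples,case_samples column names of the two groups (>= 2 each).
#' @param window count of intensity-ranked neighbours for the background
#'   variance (odd, >= 3).
#' @param prior_df pseudo-observations of the background prior (>= 0).
#' @return `data.frame`: `gene`, `mean_ref`, `mean_case`, `mean_diff`
#'   (case - ref), `s2_gene`, `s2_background`, `t_reg`, `df`, `p`, `q` (BH).
#'   Genes constant in both groups under `prior_df = 0` get `t_reg = NA`.
#' @export
regularized_t <- function(expr, ref_samples, case_samples,
                          window = 101, prior_df = 10) {
  stopifnot(is.matrix(expr), window >= 3, window %% 2 == 1, prior_df >= 0)
  check_log2_scale(expr)
  miss <- setdiff(c(ref_samples, case_samples), colnames(expr))
  if (length(miss)) stop("sample(s) not in matrix: ", paste(miss, collapse = ", "))
  n1 <- length(ref_samples); n2 <- length(case_samples)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  n <- n1 + n2
  x1 <- expr[, ref_samples, drop = FALSE]
  x2 <- expr[, case_samples, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- row_var(x1); v2 <- row_var(x2)
  s2_gene <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2)

  # background: running mean of s2_gene over the intensity-ranked neighbourhood
  intensity <- rowMeans(cbind(x1, x2))
  ord <- order(intensity)
  s2_bg <- numeric(length(s2_gene))
  s2_bg[ord] <- running_mean(s2_gene[ord], window)

  s2_reg <- (prior_df * s2_bg + (n - 2) * s2_gene) / (prior_df + n - 2)
  se <- sqrt(s2_reg * (1 / n1 + 1 / n2))
  t_reg <- ifelse(se > 0, (m2 - m1) / se, NA_real_)
  if (any(!is.finite(t_reg))) {
    warning(sum(!is.finite(t_reg)),
            " gene(s) with zero regularized variance: t undefined")
    t_reg[!is.finite(t_reg)] <- NA_real_
  }
  df <- prior_df + n - 2
  p <- 2 * stats::pt(-abs(t_reg), df)
  data.frame(gene = rownames(expr), mean_ref = m1, mean_case = m2,
             mean_diff = m2 - m1, s2_gene = s2_gene, s2_background = s2_bg,
             t_reg = t_reg, df = df, p = p,
             q = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# mean of x over a centered window of up to `window` elements, truncated at
# the ends (cumulative-sum implementation)
running_mean <- function(x, window) {
  h <- (window - 1) / 2
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Differentially expressed gene share
#'
#' @param n_deg number of differentially expressed genes (> 0).
#' @param n_up number up-regulated in the case group, `0 <= n_up <= n_deg`.
#' @return List: `n_deg`, `n_up`, `pct_exact`, `pct` (integer-rounded percent
#'   for reporting).
#' @export
deg_share <- function(n_deg, n_up) {
  if (n_deg <= 0) stop("deg_share undefined for n_deg = 0")
  stopifnot(n_up >= 0, n_up <= n_deg)
  pct <- 100 * n_up / n_deg
  list(n_deg = n_deg, n_up = n_up, pct_exact = pct, pct = round(pct))
}

#' Proliferation-normalized expression ratio
#'
#' Per-sample log2 ratio of a gene to a proliferation marker (e.g. MKI67,
#' PLK1, BUB1): `log2(gene) - log2(marker)` on log2-scale input. Normalizing
#' to proliferation makes the ratio a readout of maintenance-methylation
#' capacity rather than raw abundance. Groups are compared by Mann-Whitney.
#'
#' @param expr log2 expression matrix.
#' @param gene,marker row names; a missing one errors by name.
#' @param ref_samples,case_samples sample groups to compare.
#' @return List: `ratios` (named per-sample vector), `median_ref`,
#'   `median_case`, `p` (two-sided Mann-Whitney; `NA` if a group is empty).
#' @export
proliferation_normalize <- function(expr, gene, marker,
                                    ref_samples = NULL, case_samples = NULL) {
  for (g in c(gene, marker)) {
    if (!g %in% rownames(expr)) stop("gene not in expression matrix: ", g)
  }
  ratios <- expr[gene, ] - expr[marker, ]
  out <- list(ratios = ratios, median_ref = NA_real_, median_case = NA_real_,
              p = NA_real_)
  if (!is.null(ref_samples) && !is.null(case_samples)) {
    r <- ratios[ref_samples]; cse <- ratios[case_samples]
    out$median_ref <- stats::median(r)
    out$median_case <- stats::median(cse)
    out$p <- suppressWarnings(
      stats::wilcox.test(cse, r, alternative = "two.sided")$p.value)
  }
  out
}

#' In-block versus out-of-block expression variability (MAD)
#'
#' Per-gene variability across the case samples is the raw median absolute
#' deviation `median(|x - median(x)|)`. Genes are placed in or out of the
#' block compartment by midpoint, and the two MAD distributions are compared
#' (default unpaired Mann-Whitney; `test = "paired"` matches each in-block
#' gene to the out-block gene closest in mean expression and applies a paired
#' t-test).
#'
#' @param expr log2 expression matrix.
#' @param gene_coords interval `data.frame` with a `name` column mapping genes
#'   to coordinates.
#' @param blocks interval `data.frame` of blocks.
#' @param case_samples samples over which the MAD is computed.
#' @param test `"mannwhitney"` (default) or `"paired"`.
#' @return List: `per_gene` data.frame (`gene`, `mad`, `in_block`),
#'   `median_in`, `median_out`, `p`.
#' @export
mad_in_blocks <- function(expr, gene_coords, blocks, case_samples,
                          test = c("mannwhitney", "paired")) {
  test <- match.arg(test)
  stopifnot("name" %in% names(gene_coords))
  genes <- intersect(rownames(expr), gene_coords$name)
  if (length(genes) == 0) stop("no genes shared between matrix and coordinates")
  gc <- gene_coords[match(genes, gene_coords$name), , drop = FALSE]
  mp <- interval_midpoints(gc)
  in_block <- .points_in_set(mp$chrom, mp$pos, normalize_intervals(blocks))
  if (!any(in_block)) stop("no genes fall inside blocks")
  x <- expr[genes, case_samples, drop = FALSE]
  mads <- apply(x, 1, function(v) stats::median(abs(v - stats::median(v))))
  per_gene <- data.frame(gene = genes, mad = unname(mads), in_block = in_block,
                         stringsAsFactors = FALSE)
  mi <- per_gene$mad[in_block]; mo <- per_gene$mad[!in_block]
  if (test == "mannwhitney") {
    p <- if (length(mo)) suppressWarnings(
      stats::wilcox.test(mi, mo, alternative = "two.sided")$p.value) else NA_real_
  } else {
    if (!length(mo)) stop("paired mode needs out-of-block genes")
    mean_in <- rowMeans(x[in_block, , drop = FALSE])
    mean_out <- rowMeans(x[!in_block, , drop = FALSE])
    match_idx <- vapply(mean_in, function(v) which.min(abs(mean_out - v)), 1L)
    p <- stats::t.test(mi, mo[match_idx], paired = TRUE)$p.value
  }
  list(per_gene = per_gene, median_in = stats::median(mi),
       median_out = if (length(mo)) stats::median(mo) else NA_real_, p = p)
}

#' Chromosomal-instability signature score (e.g. CIN25)
#'
#' Per-signature-gene case-vs-reference log2 fold change with regularized-t
#' p-values; the score is the mean log2 fold change over the signature genes
#' present in the matrix. The signature gene list is an input, never
#' hard-coded.
#'
#' @param expr log2 expression matrix.
#' @param signature_genes character vector of signature gene names.
#' @param ref_samples,case_samples sample groups.
#' @param ... passed to [regularized_t()].
#' @return List: `per_gene` data.frame (`gene`, `log2fc`, `p`), `score`,
#'   `n_significant` (p < 0.05), `missing` (genes absent from the matrix).
#' @export
cin_score <- function(expr, signature_genes, ref_samples, case_samples, ...) {
  present <- intersect(signature_genes, rownames(expr))
  missing <- setdiff(signature_genes, rownames(expr))
  if (length(present) == 0) {
    stop("none of the signature genes are in the expression matrix")
  }
  if (length(missing)) {
    warning("signature gene(s) missing from matrix: ",
            paste(missing, collapse = ", "))
  }
  rt <- regularized_t(expr, ref_samples, case_samples, ...)
  rt <- rt[match(present, rt$gene), , drop = FALSE]
  per_gene <- data.frame(gene = present, log2fc = rt$mean_diff, p = rt$p,
                         stringsAsFactors = FALSE)
  list(per_gene = per_gene, score = mean(per_gene$log2fc),
       n_significant = sum(!is.na(per_gene$p) & per_gene$p < 0.05),
       missing = missing)
}

#' Repeat-family expression-versus-methylation summary
#'
#' Joins per-family log2 expression change with per-family mean methylation
#' change (percentage points), counts families in the
#' up-regulated-and-hypomethylated quadrant, and reports the Spearman
#' correlation of the two changes.
#'
#' @param re_expr `data.frame` with columns `family`, `dexpr` (log2 change).
#' @param re_meth `data.frame` with columns `family`, `dmeth` (methylation
#'   change, negative = loss).
#' @return List: `table` (joined per-family), `n_up_hypo` (dexpr > 0 and
#'   dmeth < 0), `spearman_rho`, `spearman_p`.
#' @export
re_expression_summary <- function(re_expr, re_meth) {
  stopifnot(all(c("family", "dexpr") %in% names(re_expr)),
            all(c("family", "dmeth") %in% names(re_meth)))
  tab <- merge(re_expr[, c("family", "dexpr")], re_meth[, c("family", "dmeth")],
               by = "family")
  if (nrow(tab) == 0) stop("no repeat families shared between the two tables")
  ct <- if (nrow(tab) >= 3 && stats::sd(tab$dexpr) > 0 && stats::sd(tab$dmeth) > 0) {
    suppressWarnings(stats::cor.test(tab$dexpr, tab$dmeth, method = "spearman"))
  } else NULL
  list(table = tab, n_up_hypo = sum(tab$dexpr > 0 & tab$dmeth < 0),
       spearman_rho = if (is.null(ct)) NA_real_ else unname(ct$estimate),
       spearman_p = if (is.null(ct)) NA_real_ else ct$p.value)
}
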