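#' Read a per-CpG methylome table
#'
#' Expected layout: TSV with header `chrom`, `pos`, then one column per sample
#' holding methylation fractions in \[0, 1\] or `NA` for unobserved CpGs.
#' Positions must be strictly increasing within each chromosome. Every parse
#' error names the file, line and offending field.
#'
#' @param path file path.
#' @param genome optional `genome_model`; positions beyond chromosome ends are
#'   rejected.
#' @return `data.frame` with columns `chrom`, `pos` and one numeric column per
#'   sample.
#' @export
read_methylome <- function(path, genome = NULL) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         na.strings = "NA", stringsAsFactors = FALSE)
  if (ncol(x) < 3 || !identical(names(x)[1:2], c("chrom", "pos"))) {
    stop(sprintf("%s: expected header starting 'chrom\tpos' plus >=1 sample",
                 path))
  }
  x$chrom <- as.character(x$chrom)
  samples <- names(x)[-(1:2)]
  for (s in samples) {
    v <- x[[s]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("%s line %d: non-numeric methylation fraction '%s' in %s",
                   path, bad + 1L, v[bad], s))
    }
    bad <- which(!is.na(v) & (v < 0 | v > 1))[1]
    if (!is.na(bad)) {
      stop(sprintf("%s line %d: methylation fraction %g outside [0,1] in %s",
                   path, bad + 1L, v[bad], s))
    }
  }
  ord_bad <- which(unlist(tapply(x$pos, factor(x$chrom, unique(x$chrom)),
                                 function(p) c(FALSE, diff(p) <= 0),
                                 simplify = FALSE), use.names = FALSE))[1]
  if (!is.na(ord_bad)) {
    stop(sprintf("%s line %d: positions not strictly increasing within %s",
                 path, ord_bad + 1L, x$chrom[ord_bad]))
  }
  if (!is.null(genome)) {
    len <- .chrom_lengths(x$chrom, genome)
    bad <- which(x$pos < 0 | x$pos >= len)[1]
    if (!is.na(bad)) {
      stop(sprintf("%s line %d: position %g outside %s (length %g)",
                   path, bad + 1L, x$pos[bad], x$chrom[bad], len[bad]))
    }
  }
  x
}

#' @rdname read_methylome
#' @param x methylome `data.frame` as returned by [read_methylome()].
#' @param digits decimal places for the canonical on-disk formatting.
#' @export
write_methylome <- function(x, path, digits = 6) {
  out <- x
  for (s in names(out)[-(1:2)]) {
    out[[s]] <- ifelse(is.na(out[[s]]), "NA",
                       formatC(out[[s]], digits = digits, format = "f"))
  }
  out$pos <- format(out$pos, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read copy-number segment calls (SEG-like TSV)
#'
#' Expected header: `sample`, `chrom`, `start`, `end`, `call` with call one of
#' `gain`, `loss`, `neutral`. Overlapping same-sample segments with conflicting
#' calls are resolved deterministically: the later-read segment wins on the
#' overlap and a warning is emitted.
#'
#' @param path file path.
#' @param genome optional `genome_model` for bounds validation.
#' @return `data.frame` with columns `sample`, `chrom`, `start`, `end`, `call`;
#'   per-sample segments non-overlapping.
#' @export
read_segments <- function(path, genome = NULL) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  req <- c("sample", "chrom", "start", "end", "call")
  if (!all(req %in% names(x))) {
    stop(sprintf("%s: expected columns %s", path, paste(req, collapse = ", ")))
  }
  if (nrow(x) == 0) return(x[, req])
  allowed <- c("gain", "loss", "neutral")
  bad <- which(!x$call %in% allowed)[1]
  if (!is.na(bad)) {
    stop(sprintf("%s line %d: unknown call '%s' (allowed: %s)",
                 path, bad + 1L, x$call[bad], paste(allowed, collapse = ", ")))
  }
  validate_intervals(x, genome)
  normalize_segments(x[, req])
}

#' Resolve overlapping same-sample segments (latest-read call wins)
#' @param x segment `data.frame` (`sample`, `chrom`, `start`, `end`, `call`).
#' @return Segment `data.frame` with per-sample non-overlapping segments.
#' @export
normalize_segments <- function(x) {
  pieces <- list()
  warned <- FALSE
  for (s in unique(x$sample)) {
    xs <- x[x$sample == s, , drop = FALSE]
    kept <- list()
    # later rows take precedence: subtract each later segment from earlier ones
    for (i in seq_len(nrow(xs))) {
      seg <- intervals(xs$chrom[i], xs$start[i], xs$end[i])
      if (i < nrow(xs)) {
        later <- xs[(i + 1):nrow(xs), , drop = FALSE]
        ov <- intersect_bases(seg, later[, c("chrom", "start", "end")])
        if (ov > 0) {
          warned <- TRUE
          seg <- interval_setdiff(seg, later[, c("chrom", "start", "end")])
        }
      }
      if (nrow(seg)) {
        seg$sample <- s
        seg$call <- xs$call[i]
        kept[[length(kept) + 1]] <- seg
      }
    }
    pieces[[s]] <- do.call(rbind, kept)
  }
  if (warned) warning("overlapping same-sample segments trimmed; later call kept")
  out <- do.call(rbind, pieces)
  out <- out[order(out$sample, out$chrom, out$start), c("sample", "chrom",
                                                        "start", "end", "call")]
  rownames(out) <- NULL
  out
}

#' @rdname read_segments
#' @export
write_segments <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a log2 expression matrix
#'
#' TSV with header: first column `gene`, then one column per sample. Values
#' must be finite log2-scale expression; gene identifiers must be unique.
#' Input that looks linear-scale (any value > 30) is rejected rather than
#' silently transformed.
#'
#' @param path file path.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (names(x)[1] != "gene") stop(sprintf("%s: first column must be 'gene'", path))
  if (anyDuplicated(x$gene)) {
    stop(sprintf("%s: duplicate gene identifiers (e.g. '%s')",
                 path, x$gene[duplicated(x$gene)][1]))
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop(sprintf("%s: expression values must be finite numerics", path))
  }
  rownames(m) <- x$gene
  check_log2_scale(m)
  m
}

#' @rdname read_expression
#' @param m expression matrix with gene rownames.
#' @export
write_expression <- function(m, path) {
  out <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# reject obviously linear-scale expression (log2 microarray data tops out ~16)
check_log2_scale <- function(m) {
  if (any(m > 30, na.rm = TRUE)) {
    stop("expression values > 30 look linear-scale; supply log2 data")
  }
  invisible(m)
}

#' Read a sample-to-group assignment table (TSV: sample, group)
#' @param path file path.
#' @return Named character vector mapping sample name to group label.
#' @export
read_groups <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(x))) {
    stop(sprintf("%s: expected columns sample, group", path))
  }
  stats::setNames(x$group, x$sample)
}
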