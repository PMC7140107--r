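#' Genomic interval sets
#'
#' Interval sets are plain `data.frame`s with columns `chrom`, `start`, `end`
#' in 0-based half-open coordinates (BED convention); extra columns are carried
#' along where meaningful. The interval algebra (merge, intersect, difference)
#' is delegated to GenomicRanges/IRanges behind this surface.
#'
#' @param chrom character vector.
#' @param start,end numeric vectors, `0 <= start < end`.
#' @param ... extra columns (e.g. `name`, `score`) recycled to length.
#' @return A `data.frame` of intervals.
#' @examples
#' intervals("chr1", c(0, 50), c(100, 150))
#' @export
intervals <- function(chrom, start, end, ...) {
  x <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), ..., stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

#' Validate an interval data.frame
#'
#' Checks column presence, `0 <= start < end`, and (when a genome is supplied)
#' that every interval lies within its chromosome.
#'
#' @param x interval `data.frame`.
#' @param genome optional `genome_model` for bounds checking.
#' @return `x` invisibly; errors name the offending chromosome/coordinates.
#' @export
validate_intervals <- function(x, genome = NULL) {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x))) {
    stop("interval set must have columns chrom, start, end")
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
    stop("non-finite interval coordinates")
  }
  if (any(x$start < 0)) stop("interval start < 0")
  bad <- which(x$end <= x$start)
  if (length(bad)) {
    stop(sprintf("interval with end <= start at %s:%g-%g",
                 x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  }
  if (!is.null(genome)) {
    len <- .chrom_lengths(x$chrom, genome)
    bad <- which(x$end > len)
    if (length(bad)) {
      stop(sprintf("interval beyond chromosome bounds: %s:%g-%g (length %g)",
                   x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]], len[bad[1]]))
    }
  }
  invisible(x)
}

# internal: interval data.frame <-> GRanges (1-based closed internally)
.as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

# put two GRanges on a shared seqlevel universe before set operations
.harmonize <- function(ga, gb) {
  lev <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lev
  GenomeInfoDb::seqlevels(gb) <- lev
  list(ga, gb)
}

.from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             stringsAsFactors = FALSE)
}

#' Normalize an interval set
#'
#' Sorts by (chrom, start) and merges overlapping and adjacent touching
#' intervals (`[0,5)` + `[5,9)` becomes `[0,9)`), so covered bases are
#' invariant under re-normalization. Extra columns are dropped.
#'
#' @inheritParams validate_intervals
#' @return Normalized interval `data.frame`.
#' @export
normalize_intervals <- function(x, genome = NULL) {
  validate_intervals(x, genome)
  if (nrow(x) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  out <- .from_granges(GenomicRanges::reduce(.as_granges(x)))
  if (!is.null(genome)) {
    out <- out[order(match(out$chrom, genome$chrom), out$start), , drop = FALSE]
  } else {
    out <- out[order(out$chrom, out$start), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Total bases covered by an interval set
#'
#' Overlap within the set is counted once (the set is flattened first).
#'
#' @inheritParams validate_intervals
#' @return Numeric scalar, covered bases.
#' @export
interval_bases <- function(x, genome = NULL) {
  x <- normalize_intervals(x, genome)
  sum(x$end - x$start)
}

#' Base-pair intersection and difference of two interval sets
#'
#' @param a,b interval `data.frame`s on the same genome.
#' @param genome optional `genome_model`; both sets are validated against it,
#'   so sets on different genomes error.
#' @return `intersect_bases`: numeric bp count. `interval_intersect` /
#'   `interval_setdiff`: normalized interval `data.frame`s.
#' @export
intersect_bases <- function(a, b, genome = NULL) {
  sum_w(interval_intersect(a, b, genome))
}

sum_w <- function(x) if (nrow(x) == 0) 0 else sum(x$end - x$start)

#' @rdname intersect_bases
#' @export
interval_intersect <- function(a, b, genome = NULL) {
  a <- normalize_intervals(a, genome)
  b <- normalize_intervals(b, genome)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(normalize_intervals(intervals(character(), numeric(), numeric())))
  }
  g <- .harmonize(.as_granges(a), .as_granges(b))
  .from_granges(GenomicRanges::intersect(g[[1]], g[[2]]))
}

#' @rdname intersect_bases
#' @export
interval_setdiff <- function(a, b, genome = NULL) {
  a <- normalize_intervals(a, genome)
  b <- normalize_intervals(b, genome)
  if (nrow(a) == 0) return(a)
  if (nrow(b) == 0) return(a)
  g <- .harmonize(.as_granges(a), .as_granges(b))
  .from_granges(GenomicRanges::setdiff(g[[1]], g[[2]]))
}

#' Complement of an interval set within its genome
#' @inheritParams validate_intervals
#' @return Normalized interval `data.frame` covering every base not in `x`.
#' @export
interval_complement <- function(x, genome) {
  stopifnot(inherits(genome, "genome_model"))
  whole <- intervals(genome$chrom, 0, genome$length)
  interval_setdiff(whole, x, genome)
}

#' Fraction of the genome covered by an interval set
#'
#' @inheritParams validate_intervals
#' @param genome a `genome_model` (required: supplies the denominator).
#' @return Fraction in \[0, 1\]: covered bases / genome size. The genome size
#'   always comes from the genome model, never from a constant.
#' @export
coverage_fraction <- function(x, genome) {
  stopifnot(inherits(genome, "genome_model"))
  interval_bases(x, genome) / genome_size(genome)
}

#' Interval midpoints
#'
#' One point per interval at `floor((start + end) / 2)`; used to assign
#' site-like features to blocks unambiguously.
#'
#' @inheritParams validate_intervals
#' @return `data.frame` with columns `chrom`, `pos`.
#' @export
interval_midpoints <- function(x) {
  validate_intervals(x)
  data.frame(chrom = x$chrom, pos = floor((x$start + x$end) / 2),
             stringsAsFactors = FALSE)
}

#' Read / write BED3 or BED6
#'
#' Tab-separated, no header; `track`/`browser`/`#` lines are ignored on read.
#' Columns beyond the third are kept as `name`, `score`, `strand` when present.
#'
#' @param path file path.
#' @param genome optional `genome_model` for bounds validation.
#' @return `read_bed`: interval `data.frame`. `write_bed`: `path`, invisibly.
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  if (!any(keep)) {
    return(intervals(character(), numeric(), numeric()))
  }
  x <- utils::read.table(text = lines[keep], sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- nm[seq_len(min(ncol(x), 6))]
  validate_intervals(x, genome)
  x
}

#' @rdname read_bed
#' @param x interval `data.frame`; `name` and `score` columns are written when
#'   present (BED6 with `.` strand), otherwise BED3.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- c("chrom", "start", "end")
  if (all(c("name", "score") %in% names(x))) {
    x$strand <- if ("strand" %in% names(x)) x$strand else "."
    cols <- c(cols, "name", "score", "strand")
  } else if ("name" %in% names(x)) {
    cols <- c(cols, "name")  # BED4
  }
  out <- x[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# internal: which of the points (chrom, pos) fall inside a normalized set
.points_in_set <- function(chrom, pos, set) {
  if (nrow(set) == 0 || length(pos) == 0) return(rep(FALSE, length(pos)))
  pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, pos + 1))
  g <- .harmonize(pts, .as_granges(set))
  IRanges::overlapsAny(g[[1]], g[[2]])
}
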