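#' Construct a genome model
#'
#' A genome model is the ordered set of chromosomes (name, length in bp) that
#' every interval operation validates against. All coordinates in this package
#' are 0-based, half-open (BED convention).
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer-like vector of chromosome lengths in bp, all > 0.
#' @return A `data.frame` with columns `chrom`, `length` and class
#'   `genome_model`.
#' @examples
#' g <- genome_model(c("chr1", "chr2"), c(1e6, 5e5))
#' genome_size(g)
#' @export
genome_model <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome names: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be finite and > 0")
  }
  g <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  class(g) <- c("genome_model", "data.frame")
  g
}

#' Total genome size in bp
#' @param genome a `genome_model`.
#' @return Numeric scalar, sum of chromosome lengths.
#' @export
genome_size <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  sum(genome$length)
}

#' Read / write a genome model as a two-column TSV (name, length; no header)
#' @param path file path.
#' @return `read_genome` returns a `genome_model`; `write_genome` returns
#'   `path` invisibly.
#' @export
read_genome <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  genome_model(x$chrom, x$length)
}

#' @rdname read_genome
#' @param genome a `genome_model`.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "genome_model"))
  utils::write.table(genome, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# chromosome length lookup with a clear error for unknown chromosomes
.chrom_lengths <- function(chrom, genome) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) {
    stop("chromosome(s) not in genome model: ",
         paste(unique(chrom[is.na(i)]), collapse = ", "))
  }
  genome$length[i]
}
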