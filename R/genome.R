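#' Genome description: chromosome sizes plus excluded regions
#'
#' Lightweight stand-in for a reference genome build: named chromosome
#' lengths and an optional set of excluded intervals (assembly gaps,
#' blacklist regions) that placement operations such as [shuffle_intervals()]
#' must avoid.
#'
#' @param chrom_sizes named integer vector of chromosome lengths in bp.
#' @param excluded `GRanges` of regions to exclude from random placement
#'   (may be `NULL` for none). Must lie within chromosome bounds.
#' @return An object of class `genome_spec`: a list with elements
#'   `chrom_sizes` (named integer vector) and `excluded` (`GRanges`).
#' @examples
#' gs <- genome_spec(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_spec <- function(chrom_sizes, excluded = NULL) {
  if (is.null(names(chrom_sizes)) || anyDuplicated(names(chrom_sizes)))
    stopf("chrom_sizes must have unique names")
  if (any(chrom_sizes <= 0)) stopf("chromosome sizes must be > 0")
  sizes <- structure(as.numeric(chrom_sizes), names = names(chrom_sizes))
  if (is.null(excluded)) {
    excluded <- GenomicRanges::GRanges(seqinfo = genome_seqinfo(sizes))
  } else {
    excluded <- as_genome_granges(excluded, sizes)
  }
  structure(list(chrom_sizes = sizes, excluded = excluded),
            class = "genome_spec")
}

#' @noRd
genome_seqinfo <- function(chrom_sizes) {
  GenomeInfoDb::Seqinfo(seqnames = names(chrom_sizes),
                        seqlengths = as.integer(chrom_sizes))
}

# Bind a GRanges to a genome: validate chromosome membership and bounds,
# attach seqinfo.
#' @noRd
as_genome_granges <- function(gr, chrom_sizes) {
  bad <- setdiff(as.character(unique(GenomicRanges::seqnames(gr))),
                 names(chrom_sizes))
  if (length(bad))
    stopf("chromosome(s) not in genome: %s", paste(bad, collapse = ", "))
  # out-of-bound ranges are re-checked below with a clearer error
  gr2 <- suppressWarnings(GenomicRanges::GRanges(
    seqnames = factor(as.character(GenomicRanges::seqnames(gr)),
                      levels = names(chrom_sizes)),
    ranges = IRanges::IRanges(GenomicRanges::start(gr),
                              GenomicRanges::end(gr)),
    strand = GenomicRanges::strand(gr),
    seqinfo = genome_seqinfo(chrom_sizes)))
  S4Vectors::mcols(gr2) <- S4Vectors::mcols(gr)
  over <- GenomicRanges::end(gr2) >
    chrom_sizes[as.character(GenomicRanges::seqnames(gr2))] |
    GenomicRanges::start(gr2) < 1
  if (any(over))
    stopf("%d interval(s) outside chromosome bounds", sum(over))
  gr2
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x$chrom_sizes), "chromosome(s),",
      format(sum(x$chrom_sizes), big.mark = ","), "bp;",
      length(x$excluded), "excluded region(s)\n")
  invisible(x)
}

#' Read and write two-column chrom.sizes tables
#'
#' The standard UCSC `chrom.sizes` dialect: chromosome name and length,
#' tab-separated, no header.
#'
#' @param path file path.
#' @return `read_chrom_sizes()` returns a named numeric vector;
#'   `write_chrom_sizes()` returns `path` invisibly.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
  if (any(is.na(tab$size)) || any(tab$size <= 0))
    stopf("invalid chromosome size in %s", path)
  structure(tab$size, names = tab$chrom)
}

#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @rdname read_chrom_sizes
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(
    data.frame(names(chrom_sizes), format(chrom_sizes, scientific = FALSE,
                                          trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
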