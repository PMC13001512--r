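#' Gene models with exon structure
#'
#' A `gene_models` object is a data frame with one row per gene and list
#' columns holding exon coordinates. Coordinates are 1-based closed
#' (GRanges convention); BED/GTF conversion happens at the I/O boundary.
#' The TSS is the 5'-most transcribed base: `start` for a "+" gene and
#' `end` (the last covered base) for a "-" gene. The CDS span
#' (`cds_start`..`cds_end`, genomic) delimits the 5' and 3' UTRs within the
#' exon structure.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param exon_starts,exon_ends lists of integer vectors (genomic order,
#'   ascending, non-overlapping), one vector per gene.
#' @param cds_start,cds_end genomic CDS bounds per gene; default to the gene
#'   span (no UTRs).
#' @return A data frame of class `gene_models` with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `tss`, `cds_start`, `cds_end`,
#'   `exon_starts`, `exon_ends`.
#' @examples
#' gm <- gene_models("g1", "chr1", "+",
#'                   exon_starts = list(c(1001, 2001)),
#'                   exon_ends = list(c(1500, 3000)))
#' gm$tss  # 1001
#' @export
gene_models <- function(gene_id, chrom, strand, exon_starts, exon_ends,
                        cds_start = NULL, cds_end = NULL) {
  n <- length(gene_id)
  stopifnot(length(chrom) == n, length(strand) == n,
            length(exon_starts) == n, length(exon_ends) == n)
  if (anyDuplicated(gene_id)) stopf("gene_id values must be unique")
  if (!all(strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  for (i in seq_len(n)) {
    es <- exon_starts[[i]]; ee <- exon_ends[[i]]
    if (length(es) < 1L || length(es) != length(ee) || any(es > ee) ||
        is.unsorted(es, strictly = TRUE) ||
        (length(es) > 1L && any(es[-1] <= ee[-length(ee)])))
      stopf("gene %s: exons must be ordered, non-overlapping", gene_id[i])
  }
  start <- vapply(exon_starts, min, numeric(1))
  end <- vapply(exon_ends, max, numeric(1))
  if (is.null(cds_start)) cds_start <- start
  if (is.null(cds_end)) cds_end <- end
  tss <- ifelse(strand == "+", start, end)
  out <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    start = start, end = end,
                    strand = as.character(strand), tss = tss,
                    cds_start = as.numeric(cds_start),
                    cds_end = as.numeric(cds_end),
                    stringsAsFactors = FALSE)
  out$exon_starts <- lapply(exon_starts, as.numeric)
  out$exon_ends <- lapply(exon_ends, as.numeric)
  class(out) <- c("gene_models", "data.frame")
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x), "gene(s) on",
      length(unique(x$chrom)), "chromosome(s)\n")
  print.data.frame(utils::head(as.data.frame(
    x[, c("gene_id", "chrom", "start", "end", "strand", "tss")]), 6))
  invisible(x)
}

#' TSS positions of gene models as single-base GRanges
#'
#' @param genes a [gene_models()] object.
#' @param genome optional [genome_spec()] used to attach seqinfo.
#' @return `GRanges` of width-1 ranges at each TSS, carrying `gene_id`.
#' @export
tss_sites <- function(genes, genome = NULL) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$tss, genes$tss),
                               strand = genes$strand)
  gr$gene_id <- genes$gene_id
  if (!is.null(genome)) gr <- as_genome_granges(gr, genome$chrom_sizes)
  gr
}

# exon ranges in transcription order for one gene row
#' @noRd
gene_exons_tx <- function(genes, i) {
  es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
  if (genes$strand[i] == "-") { es <- rev(es); ee <- rev(ee) }
  list(starts = es, ends = ee)
}
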