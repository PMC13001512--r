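# File-format boundary: BED (3/6/12), GTF genes/exons, CNV segment TSV.
# All parsing/formatting of BED and GTF is delegated to rtracklayer, which
# performs the 0-based half-open <-> 1-based closed conversion.

#' Read and write BED interval files
#'
#' Thin wrappers around [rtracklayer::import()] / [rtracklayer::export()]
#' for BED3/BED6. Coordinates on disk are 0-based half-open; in memory they
#' are 1-based closed `GRanges`.
#'
#' @param path file path.
#' @param genome optional [genome_spec()]; when given, intervals are
#'   validated against it and carry its seqinfo.
#' @return `read_bed()` returns a `GRanges`.
#' @export
read_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!is.null(genome)) gr <- as_genome_granges(gr, genome$chrom_sizes)
  gr
}

#' @param gr `GRanges` to write; `name`, `score` and strand are emitted when
#'   present (BED6), otherwise BED3.
#' @rdname read_bed
#' @export
write_bed <- function(gr, path) {
  if (is.null(gr$score)) gr$score <- 0L
  if (is.null(gr$name)) gr$name <- paste0("iv_", seq_along(gr))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read and write gene models as BED12
#'
#' BED12 blocks store the exon structure; the thick range stores the CDS
#' span, from which UTRs are recovered.
#'
#' @param path file path.
#' @return `read_genes_bed12()` returns a [gene_models()] object.
#' @export
read_genes_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks))
    stopf("%s is not BED12 (no block structure)", path)
  starts <- GenomicRanges::start(gr)
  blocks <- gr$blocks
  exon_starts <- lapply(seq_along(gr), function(i)
    GenomicRanges::start(blocks[[i]]) + starts[i] - 1)
  exon_ends <- lapply(seq_along(gr), function(i)
    GenomicRanges::end(blocks[[i]]) + starts[i] - 1)
  gene_models(gene_id = gr$name,
              chrom = as.character(GenomicRanges::seqnames(gr)),
              strand = as.character(GenomicRanges::strand(gr)),
              exon_starts = exon_starts, exon_ends = exon_ends,
              cds_start = GenomicRanges::start(gr$thick),
              cds_end = GenomicRanges::end(gr$thick))
}

#' @param genes a [gene_models()] object.
#' @rdname read_genes_bed12
#' @export
write_genes_bed12 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = genes$strand)
  gr$name <- genes$gene_id
  gr$score <- 0L
  gr$thick <- IRanges::IRanges(genes$cds_start, genes$cds_end)
  gr$blocks <- IRanges::IRangesList(lapply(seq_len(nrow(genes)), function(i)
    IRanges::IRanges(genes$exon_starts[[i]] - genes$start[i] + 1,
                     genes$exon_ends[[i]] - genes$start[i] + 1)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read gene models from a GTF annotation
#'
#' Uses the `exon` records of a GTF file (gene and transcript rows are
#' ignored); one model per `gene_id`, with the union of its exons. The CDS
#' span, when CDS records are present, delimits the UTRs; otherwise the
#' gene span is used (no UTRs).
#'
#' @param path GTF file path.
#' @return A [gene_models()] object.
#' @export
read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stopf("no exon records in %s", path)
  ids <- as.character(ex$gene_id)
  uid <- unique(ids)
  exon_starts <- vector("list", length(uid))
  exon_ends <- vector("list", length(uid))
  chrom <- character(length(uid)); strd <- character(length(uid))
  cds <- gr[gr$type == "CDS"]
  cds_ids <- as.character(cds$gene_id)
  cds_start <- rep(NA_real_, length(uid)); cds_end <- rep(NA_real_, length(uid))
  for (k in seq_along(uid)) {
    sub <- GenomicRanges::reduce(ex[ids == uid[k]], ignore.strand = TRUE)
    exon_starts[[k]] <- GenomicRanges::start(sub)
    exon_ends[[k]] <- GenomicRanges::end(sub)
    chrom[k] <- as.character(GenomicRanges::seqnames(ex[ids == uid[k]]))[1]
    strd[k] <- as.character(GenomicRanges::strand(ex[ids == uid[k]]))[1]
    if (any(cds_ids == uid[k])) {
      cs <- cds[cds_ids == uid[k]]
      cds_start[k] <- min(GenomicRanges::start(cs))
      cds_end[k] <- max(GenomicRanges::end(cs))
    }
  }
  span_start <- vapply(exon_starts, min, numeric(1))
  span_end <- vapply(exon_ends, max, numeric(1))
  gene_models(uid, chrom, strd, exon_starts, exon_ends,
              cds_start = ifelse(is.na(cds_start), span_start, cds_start),
              cds_end = ifelse(is.na(cds_end), span_end, cds_end))
}

#' Read copy-number segments from a TSV table
#'
#' Accepts the CNVkit `.cns` dialect: a header line with at least
#' `chromosome`, `start`, `end` and `log2` columns; extra columns are
#' ignored. Starts on disk are 0-based half-open (BED-like) and converted
#' on read.
#'
#' @param path file path.
#' @param genome optional [genome_spec()] for validation.
#' @return A `GRanges` with metadata columns `log2_ratio` and `cnr`
#'   (`cnr = 2^log2_ratio`), as produced by [cnv_segments()].
#' @export
read_cnv_segments <- function(path, genome = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("chromosome", "start", "end", "log2")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("segment table %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  cnv_segments(chrom = tab$chromosome, start = tab$start + 1, end = tab$end,
               log2_ratio = tab$log2, genome = genome)
}

#' @param segments a `GRanges` from [cnv_segments()].
#' @rdname read_cnv_segments
#' @export
write_cnv_segments <- function(segments, path) {
  tab <- data.frame(
    chromosome = as.character(GenomicRanges::seqnames(segments)),
    start = GenomicRanges::start(segments) - 1,
    end = GenomicRanges::end(segments),
    log2 = segments$log2_ratio)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
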