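# Strandedness of unstranded G4 ChIP peaks, inferred from strand-resolved
# G4-seq hits, and template/non-template classification relative to a
# peak's linked gene.

#' Infer G4 peak strandedness from stranded G4-seq hits
#'
#' A peak is called `watson` when it intersects G4-seq hits on the Watson
#' (plus) strand only, `crick` when it intersects Crick-strand hits only,
#' `ambiguous` when it intersects hits on both strands, and `unassigned`
#' when it intersects none.
#'
#' @param g4_peaks `GRanges` of (unstranded) G4 ChIP peaks.
#' @param hits_watson,hits_crick `GRanges` of G4-seq hits on the Watson and
#'   Crick strands. A single stranded `GRanges` can be split with
#'   [split_stranded_hits()].
#' @param min_overlap minimum intersection in bp to count a hit (default 1).
#' @return data frame with columns `peak_index`, `call` (factor: `watson`,
#'   `crick`, `ambiguous`, `unassigned`), `n_watson`, `n_crick`.
#' @export
infer_strand <- function(g4_peaks, hits_watson, hits_crick, min_overlap = 1) {
  nw <- GenomicRanges::countOverlaps(g4_peaks, hits_watson,
                                     ignore.strand = TRUE,
                                     minoverlap = as.integer(min_overlap))
  nc <- GenomicRanges::countOverlaps(g4_peaks, hits_crick,
                                     ignore.strand = TRUE,
                                     minoverlap = as.integer(min_overlap))
  call <- ifelse(nw > 0 & nc == 0, "watson",
          ifelse(nc > 0 & nw == 0, "crick",
          ifelse(nw > 0 & nc > 0, "ambiguous", "unassigned")))
  data.frame(peak_index = seq_along(g4_peaks),
             call = factor(call, levels = c("watson", "crick", "ambiguous",
                                            "unassigned")),
             n_watson = as.integer(nw), n_crick = as.integer(nc))
}

#' Split a stranded hit set into Watson and Crick subsets
#'
#' @param hits stranded `GRanges` (strand `+` = Watson, `-` = Crick).
#' @return list with elements `watson` and `crick`.
#' @export
split_stranded_hits <- function(hits) {
  s <- as.character(GenomicRanges::strand(hits))
  if (any(s == "*"))
    warnf("%d unstranded hit(s) dropped", sum(s == "*"))
  list(watson = hits[s == "+"], crick = hits[s == "-"])
}

#' Classify G4 peaks as template or non-template relative to linked genes
#'
#' The template ("transcribing") strand is the strand read by RNA
#' polymerase: the Crick strand for a "+" gene and the Watson strand for a
#' "-" gene. A peak with a definite strand call and a linked gene is
#' `transcribing` when its G4 forms on the template strand and
#' `non-transcribing` otherwise; ambiguous/unassigned peaks and peaks
#' without a gene link are `not-callable`.
#'
#' @param calls data frame from [infer_strand()].
#' @param links data frame from [link_peaks_to_genes()] (needs
#'   `peak_index`, `gene_id`).
#' @param genes a [gene_models()] object (for gene strands).
#' @return data frame with columns `peak_index`, `gene_id`, `relation`
#'   (factor: `transcribing`, `non-transcribing`, `not-callable`).
#' @export
classify_template <- function(calls, links, genes) {
  gene_id <- links$gene_id[match(calls$peak_index, links$peak_index)]
  gene_strand <- genes$strand[match(gene_id, genes$gene_id)]
  g4_strand <- ifelse(calls$call == "watson", "+",
               ifelse(calls$call == "crick", "-", NA))
  template <- ifelse(gene_strand == "+", "-", "+")
  relation <- ifelse(is.na(g4_strand) | is.na(gene_strand), "not-callable",
              ifelse(g4_strand == template, "transcribing",
                     "non-transcribing"))
  data.frame(peak_index = calls$peak_index, gene_id = gene_id,
             relation = factor(relation,
                               levels = c("transcribing", "non-transcribing",
                                          "not-callable")),
             stringsAsFactors = FALSE)
}
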