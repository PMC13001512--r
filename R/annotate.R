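#' Assign one genomic feature category to each interval
#'
#' Each interval receives exactly one category, resolved by fixed
#' precedence when several apply:
#' promoter/TSS > 5'UTR > 1st-Ex-Int junction > first exon > first intron >
#' other exon > other intron > 3'UTR > intergenic.
#' "First" is in transcription order, so the first exon of a "-" gene is
#' its 3'-most genomic exon. An interval carries the "1st-Ex-Int junction"
#' label only when it covers both bases flanking the boundary between the
#' first exon and the first intron. UTRs are the exonic regions outside the
#' CDS span of the gene model.
#'
#' @param x `GRanges` to annotate.
#' @param genes a [gene_models()] object.
#' @param flank promoter half-width in bp (default 3000).
#' @return data frame with columns `index`, `category` (factor with the
#'   levels above plus `intergenic`), `gene_id` (`NA` for intergenic).
#' @export
annotate_features <- function(x, genes, flank = 3000) {
  categories <- c("promoter/TSS", "5'UTR", "1st-Ex-Int junction",
                  "first exon", "first intron", "other exon", "other intron",
                  "3'UTR", "intergenic")
  n <- length(x)
  cat_out <- rep("intergenic", n)
  gene_out <- rep(NA_character_, n)
  feats <- build_feature_sets(genes, flank)
  assigned <- rep(FALSE, n)
  for (cat_name in setdiff(categories, "intergenic")) {
    f <- feats[[cat_name]]
    if (is.null(f) || !length(f$gr)) next
    hits <- GenomicRanges::findOverlaps(x, f$gr, ignore.strand = TRUE,
                                        minoverlap = f$minov)
    qi <- S4Vectors::queryHits(hits)
    keep <- !assigned[qi]
    if (!any(keep)) next
    qi <- qi[keep]; si <- S4Vectors::subjectHits(hits)[keep]
    # ties across genes within one category: lowest gene_id wins
    ord <- order(qi, f$gr$gene_id[si])
    first <- !duplicated(qi[ord])
    idx <- qi[ord][first]
    cat_out[idx] <- cat_name
    gene_out[idx] <- f$gr$gene_id[si][ord][first]
    assigned[idx] <- TRUE
  }
  data.frame(index = seq_len(n),
             category = factor(cat_out, levels = categories),
             gene_id = gene_out, stringsAsFactors = FALSE)
}

# Per-category GRanges (with gene_id) and the minimum overlap needed for a
# hit: 2 bp for the junction (both flanking bases), 1 bp otherwise.
#' @noRd
build_feature_sets <- function(genes, flank) {
  mk <- function(chrom, start, end, gene_id) {
    keep <- !is.na(start) & !is.na(end) & start <= end
    gr <- GenomicRanges::GRanges(chrom[keep],
                                 IRanges::IRanges(start[keep], end[keep]))
    gr$gene_id <- gene_id[keep]
    gr
  }
  ng <- nrow(genes)
  utr5 <- utr3 <- fex <- fint <- junc <- list()
  oex <- oint <- list()
  for (i in seq_len(ng)) {
    tx <- gene_exons_tx(genes, i)
    es <- tx$starts; ee <- tx$ends
    k <- length(es)
    ch <- genes$chrom[i]; id <- genes$gene_id[i]
    plus <- genes$strand[i] == "+"
    # exon categories cover the CDS-clipped exon portions; the UTR ends of
    # terminal exons keep their own (lower-precedence) categories
    clip <- function(lo, hi) c(max(lo, genes$cds_start[i]),
                               min(hi, genes$cds_end[i]))
    # first exon / first intron / junction (transcription order)
    fex[[i]] <- c(ch, clip(es[1], ee[1]), id)
    if (k >= 2) {
      if (plus) {
        fint[[i]] <- c(ch, ee[1] + 1, es[2] - 1, id)
        junc[[i]] <- c(ch, ee[1], ee[1] + 1, id)
      } else {
        fint[[i]] <- c(ch, ee[2] + 1, es[1] - 1, id)
        junc[[i]] <- c(ch, es[1] - 1, es[1], id)
      }
      for (j in 2:k) oex[[length(oex) + 1]] <- c(ch, clip(es[j], ee[j]), id)
      if (k >= 3) for (j in 2:(k - 1)) {
        if (plus) oint[[length(oint) + 1]] <- c(ch, ee[j] + 1, es[j + 1] - 1, id)
        else oint[[length(oint) + 1]] <- c(ch, ee[j + 1] + 1, es[j] - 1, id)
      }
    }
    # UTRs: exonic regions outside the CDS span, by genomic position
    ges <- genes$exon_starts[[i]]; gee <- genes$exon_ends[[i]]
    pre <- cbind(pmax(ges, genes$start[i]), pmin(gee, genes$cds_start[i] - 1))
    post <- cbind(pmax(ges, genes$cds_end[i] + 1), pmin(gee, genes$end[i]))
    add_utr <- function(mat) {
      ok <- mat[, 1] <= mat[, 2]
      lapply(which(ok), function(j) c(ch, mat[j, 1], mat[j, 2], id))
    }
    if (plus) {
      utr5 <- c(utr5, add_utr(pre)); utr3 <- c(utr3, add_utr(post))
    } else {
      utr5 <- c(utr5, add_utr(post)); utr3 <- c(utr3, add_utr(pre))
    }
  }
  to_gr <- function(lst) {
    lst <- Filter(Negate(is.null), lst)
    if (!length(lst))
      return(mk(character(0), numeric(0), numeric(0), character(0)))
    m <- do.call(rbind, lst)
    mk(m[, 1], as.numeric(m[, 2]), as.numeric(m[, 3]), m[, 4])
  }
  prom <- promoter_windows(genes, flank = flank)
  list(`promoter/TSS` = list(gr = prom, minov = 1L),
       `5'UTR` = list(gr = to_gr(utr5), minov = 1L),
       `1st-Ex-Int junction` = list(gr = to_gr(junc), minov = 2L),
       `first exon` = list(gr = to_gr(fex), minov = 1L),
       `first intron` = list(gr = to_gr(fint), minov = 1L),
       `other exon` = list(gr = to_gr(oex), minov = 1L),
       `other intron` = list(gr = to_gr(oint), minov = 1L),
       `3'UTR` = list(gr = to_gr(utr3), minov = 1L))
}
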