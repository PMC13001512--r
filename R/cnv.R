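# Copy-number normalization: assign peaks to copy-number segments and scale
# case/control counts by the segment copy-number ratio (CNR) before
# differential testing.

#' Construct copy-number segments
#'
#' @param chrom,start,end segment coordinates (1-based closed).
#' @param log2_ratio log2 copy-number ratio (case/control) per segment.
#' @param genome optional [genome_spec()] for validation.
#' @return `GRanges` with metadata columns `log2_ratio` and
#'   `cnr = 2^log2_ratio`.
#' @export
cnv_segments <- function(chrom, start, end, log2_ratio, genome = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  gr$log2_ratio <- as.numeric(log2_ratio)
  gr$cnr <- 2^gr$log2_ratio
  if (!is.null(genome)) gr <- as_genome_granges(gr, genome$chrom_sizes)
  gr
}

#' Assign each peak to a copy-number segment
#'
#' Overlap is preferred over proximity; a peak overlapping several segments
#' goes to the one with the largest overlap; a peak in a gap goes to the
#' closest segment by edge distance (ties: lower start). Peaks on
#' chromosomes without segments are flagged unassigned and fall back to
#' CNR = 1 downstream, with a warning.
#'
#' @param peaks `GRanges`.
#' @param segments `GRanges` from [cnv_segments()]; must be non-overlapping
#'   within each chromosome.
#' @return data frame with columns `peak_index`, `segment_index`, `relation`
#'   (`"overlap"`, `"closest"` or `"unassigned"`), `cnr`.
#' @export
assign_segments <- function(peaks, segments) {
  if (is.null(segments$cnr)) stopf("segments must carry a 'cnr' column")
  self <- GenomicRanges::findOverlaps(segments, ignore.strand = TRUE,
                                      drop.self = TRUE)
  if (length(self)) stopf("segments overlap each other; expected a tiling")
  n <- length(peaks)
  out <- data.frame(peak_index = seq_len(n),
                    segment_index = rep(NA_integer_, n),
                    relation = rep("unassigned", n),
                    cnr = rep(1, n), stringsAsFactors = FALSE)
  oj <- overlap_join(peaks, segments)
  if (nrow(oj)) {
    ord <- order(oj$a_index, -oj$overlap_bp, oj$b_index)
    best <- oj[ord, ][!duplicated(oj$a_index[ord]), ]
    out$segment_index[best$a_index] <- best$b_index
    out$relation[best$a_index] <- "overlap"
  }
  rest <- which(is.na(out$segment_index))
  if (length(rest)) {
    cl <- closest_intervals(peaks[rest], segments)
    hit <- !is.na(cl$subject_index)
    out$segment_index[rest[hit]] <- cl$subject_index[hit]
    out$relation[rest[hit]] <- "closest"
  }
  ok <- !is.na(out$segment_index)
  out$cnr[ok] <- segments$cnr[out$segment_index[ok]]
  if (any(!ok))
    warnf("%d peak(s) on chromosomes without segments; treated as CNR = 1",
          sum(!ok))
  out
}

#' Scale a count matrix by per-peak copy-number ratios
#'
#' Per feature: when its CNR >= 1, the counts of the case samples are
#' divided by the CNR; when CNR < 1, the counts of the control samples are
#' multiplied by the CNR. Either way the scaling shrinks the condition with
#' the (relative) copy-number excess toward the other, and CNR = 1 leaves
#' the matrix unchanged. Scaled values are rounded half-up so downstream
#' count-based tests keep an integer contract.
#'
#' @param counts integer matrix, features x samples, with column names.
#' @param cnr numeric vector of per-feature CNRs (e.g. the `cnr` column of
#'   [assign_segments()] output), or that output data frame itself.
#' @param condition factor/character per sample with two levels; the second
#'   level is the case condition (see `case`).
#' @param case label of the case condition; default the second level.
#' @return matrix of the same shape, integer-valued.
#' @examples
#' m <- matrix(c(100L, 100L, 100L, 100L), 1,
#'             dimnames = list("p1", c("wt1", "wt2", "bs1", "bs2")))
#' scale_counts(m, cnr = 2, condition = c("wt", "wt", "bs", "bs"))
#' @export
scale_counts <- function(counts, cnr, condition, case = NULL) {
  if (is.data.frame(cnr)) cnr <- cnr$cnr
  if (length(cnr) == 1L) cnr <- rep(cnr, nrow(counts))
  if (length(cnr) != nrow(counts))
    stopf("need one CNR per feature (%d given, %d features)",
          length(cnr), nrow(counts))
  if (any(cnr <= 0)) stopf("CNR must be > 0")
  condition <- as.factor(condition)
  if (length(condition) != ncol(counts))
    stopf("condition has %d labels for %d samples",
          length(condition), ncol(counts))
  if (nlevels(condition) != 2L) stopf("condition must have exactly 2 levels")
  if (is.null(case)) case <- levels(condition)[2]
  if (!case %in% levels(condition))
    stopf("case label '%s' not among condition levels", case)
  is_case <- condition == case
  out <- counts
  hi <- cnr >= 1
  if (any(hi & cnr != 1))
    out[hi, is_case] <- round_half_up(counts[hi, is_case, drop = FALSE] /
                                        cnr[hi])
  if (any(!hi))
    out[!hi, !is_case] <- round_half_up(counts[!hi, !is_case, drop = FALSE] *
                                          cnr[!hi])
  storage.mode(out) <- "integer"
  out
}
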