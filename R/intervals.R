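# Interval engine: overlap joins, nearest neighbours, local density,
# randomization (genome shuffle and universe resampling), promoter windows.
# Overlap/nearest primitives stand on GenomicRanges/IRanges; all operations
# here are strand-agnostic (G4 ChIP peaks are unstranded) -- strand matters
# only in strand inference and promoter orientation.

#' Overlap join between two interval sets
#'
#' Returns every pair of intervals whose intersection is at least
#' `min_overlap` bp long. The published ATAC/G4 pairing rule "overlap larger
#' than 150 bp" corresponds to `min_overlap = 151`.
#'
#' @param a,b `GRanges`.
#' @param min_overlap minimum intersection length in bp (>= 1).
#' @return data frame with columns `a_index`, `b_index`, `overlap_bp`,
#'   ordered by (`a_index`, `b_index`).
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 400))
#' overlap_join(a, b)           # one pair, 100 bp
#' overlap_join(a, b, 151)      # empty
#' @export
overlap_join <- function(a, b, min_overlap = 1) {
  if (min_overlap < 1) stopf("min_overlap must be >= 1")
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = as.integer(min_overlap),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    GenomicRanges::granges(a)[qi], GenomicRanges::granges(b)[si]))
  ord <- order(qi, si)
  data.frame(a_index = qi[ord], b_index = si[ord], overlap_bp = ov[ord])
}

#' Closest subject interval for each query interval
#'
#' Distance is the gap between nearest edges (0 for overlapping or
#' book-ended intervals). Equidistant subjects are resolved in favour of
#' the lower start coordinate, making the result deterministic. Queries on
#' chromosomes absent from `subject` are reported with `subject_index = NA`
#' and `distance_bp = Inf`.
#'
#' @param query,subject `GRanges`; `subject` should be non-empty on each
#'   queried chromosome.
#' @return data frame with columns `query_index`, `subject_index`,
#'   `distance_bp`.
#' @export
closest_intervals <- function(query, subject) {
  n <- length(query)
  out <- data.frame(query_index = seq_len(n),
                    subject_index = rep(NA_integer_, n),
                    distance_bp = rep(Inf, n))
  if (!length(subject) || !n) return(out)
  qc <- as.character(GenomicRanges::seqnames(query))
  sc <- as.character(GenomicRanges::seqnames(subject))
  qs <- GenomicRanges::start(query); qe <- GenomicRanges::end(query)
  ss <- GenomicRanges::start(subject); se <- GenomicRanges::end(subject)
  for (ch in unique(qc)) {
    qi <- which(qc == ch); si <- which(sc == ch)
    if (!length(si)) next
    for (i in qi) {
      gap <- pmax(ss[si] - qe[i] - 1, qs[i] - se[si] - 1, 0)
      dmin <- min(gap)
      cand <- si[gap == dmin]
      best <- cand[which.min(ss[cand])]
      out$subject_index[i] <- best
      out$distance_bp[i] <- dmin
    }
  }
  out
}

#' Local peak density within a flanking window
#'
#' For each interval, the number of *other* intervals of the same set
#' overlapping the window `[start - flank, end + flank]`.
#'
#' @param x `GRanges`.
#' @param flank window extension in bp (default 10 kb, the published ATAC
#'   peak-density window).
#' @return integer vector, one count per interval of `x`.
#' @export
peak_density <- function(x, flank = 10000) {
  if (!length(x)) return(integer(0))
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(x),
    IRanges::IRanges(pmax(1, GenomicRanges::start(x) - flank),
                     GenomicRanges::end(x) + flank))
  GenomicRanges::countOverlaps(win, x, ignore.strand = TRUE) - 1L
}

#' Randomly relocate intervals across a genome
#'
#' One output interval per input, of identical length, placed uniformly at
#' random among positions that lie within chromosome bounds and do not
#' overlap the genome's excluded regions (rejection sampling, at most
#' `max_attempts` rounds per interval). By default each interval stays on
#' its original chromosome; with `same_chrom = FALSE` a chromosome is first
#' drawn with probability proportional to the number of legal start
#' positions for that interval length.
#'
#' @param x `GRanges` to relocate.
#' @param genome [genome_spec()] providing bounds and excluded regions.
#' @param excluded optional `GRanges` overriding `genome$excluded`.
#' @param same_chrom keep each interval on its own chromosome (default).
#' @param seed optional integer; when given the shuffle is reproducible and
#'   the caller's RNG state is untouched.
#' @param max_attempts rejection-sampling cap per interval.
#' @return `GRanges` of the same length and widths as `x`.
#' @export
shuffle_intervals <- function(x, genome, excluded = NULL, same_chrom = TRUE,
                              seed = NULL, max_attempts = 10000) {
  if (is.null(excluded)) excluded <- genome$excluded
  sizes <- genome$chrom_sizes
  w <- GenomicRanges::width(x)
  xc <- as.character(GenomicRanges::seqnames(x))
  bad <- setdiff(unique(xc), names(sizes))
  if (length(bad)) stopf("chromosome(s) not in genome: %s",
                         paste(bad, collapse = ", "))
  with_seed_maybe(seed, {
    if (same_chrom) {
      chroms <- xc
      if (any(w > sizes[chroms]))
        stopf("interval %d longer than its chromosome",
              which(w > sizes[chroms])[1])
    } else {
      # legal start positions per (interval, chromosome)
      chroms <- character(length(x))
      for (i in seq_along(x)) {
        room <- pmax(sizes - w[i] + 1, 0)
        if (all(room == 0))
          stopf("interval %d longer than every chromosome", i)
        chroms[i] <- sample(names(sizes), 1, prob = room)
      }
    }
    starts <- rep(NA_real_, length(x))
    todo <- seq_along(x)
    for (round in seq_len(max_attempts)) {
      if (!length(todo)) break
      cand <- floor(runif(length(todo)) * (sizes[chroms[todo]] - w[todo] + 1)) + 1
      gr <- GenomicRanges::GRanges(chroms[todo],
                                   IRanges::IRanges(cand, width = w[todo]))
      ok <- !IRanges::overlapsAny(gr, excluded, ignore.strand = TRUE)
      starts[todo[ok]] <- cand[ok]
      todo <- todo[!ok]
    }
    if (length(todo))
      stopf("no legal placement found for interval %d after %d attempts",
            todo[1], max_attempts)
    out <- GenomicRanges::GRanges(chroms, IRanges::IRanges(starts, width = w),
                                  seqinfo = genome_seqinfo(sizes))
    S4Vectors::mcols(out) <- S4Vectors::mcols(x)
    out
  })
}

#' Resample a query set within a fixed universe
#'
#' Draws `length(query)` elements uniformly without replacement from
#' `universe`. This is the randomization used when the null should respect
#' a constrained feature space, e.g. permuting the TSSs of differential
#' genes within the TSSs of all expressed genes.
#'
#' @param query,universe `GRanges`; `length(query) <= length(universe)`.
#' @param seed optional integer for reproducibility.
#' @return `GRanges`: a size-`length(query)` subset of `universe`.
#' @export
resample_within_universe <- function(query, universe, seed = NULL) {
  if (length(query) > length(universe))
    stopf("query (%d) larger than universe (%d)",
          length(query), length(universe))
  with_seed_maybe(seed,
    universe[sample(length(universe), length(query), replace = FALSE)])
}

#' Promoter windows around gene TSSs
#'
#' Per gene, the symmetric window `TSS +/- flank` (clipped to chromosome
#' bounds when a genome is supplied), carrying `gene_id` and strand. The
#' window of a "-"-strand gene is centred on its TSS, i.e. the 3' genomic
#' coordinate of the span.
#'
#' @param genes a [gene_models()] object.
#' @param flank half-width in bp (default 3000, the promoter definition
#'   used throughout).
#' @param genome optional [genome_spec()] for clipping and seqinfo.
#' @return `GRanges` of promoter windows with `gene_id` metadata.
#' @export
promoter_windows <- function(genes, flank = 3000, genome = NULL) {
  start <- pmax(1, genes$tss - flank)
  end <- genes$tss + flank - 1
  if (!is.null(genome))
    end <- pmin(end, genome$chrom_sizes[genes$chrom])
  gr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(start, end),
                               strand = genes$strand)
  gr$gene_id <- genes$gene_id
  if (!is.null(genome)) gr <- as_genome_granges(gr, genome$chrom_sizes)
  gr
}
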