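# Synthetic two-condition study generator with planted ground truth.
# Emulates the interval/count structure of a G4 ChIP-seq + ATAC-seq +
# RNA-seq disease-vs-control study at desk scale: a small multi-chromosome
# genome with excluded regions, gene models with exon structure, G4 peaks
# concentrated in promoters, ATAC peaks overlapping most G4 peaks,
# strand-resolved G4-seq hits, copy-number segments, and NB-distributed
# count matrices per modality. Every planted parameter is recorded in the
# bundle's ground-truth tables so downstream stages can be tested for
# recovery. One top-level seed; each generator consumes its own derived
# stream, so adding a generator leaves the others' draws unchanged.

#' Configuration for the synthetic study generator
#'
#' Defaults describe a small but realistic two-condition study: a 2 x 5 Mb
#' genome, 200 spliced genes, 1500 ATAC peaks and 500 G4 peaks of which
#' 80% are planted in promoter (TSS +/- 3 kb) windows -- the promoter
#' share reported for endogenous G4 peaks -- and 75% are covered by an
#' ATAC peak. G4-overlapping ATAC peaks default to a 988 bp width and
#' background ATAC peaks to 347 bp, the published median widths of the two
#' classes. Counts are negative binomial with variance `mu + alpha mu^2`.
#'
#' @param seed top-level integer seed.
#' @param n_chrom,chrom_size chromosome count and size in bp (>= 1e5).
#' @param excluded_frac fraction of each chromosome covered by excluded
#'   (gap/blacklist-like) regions.
#' @param n_genes,gene_length_range,n_exon_range gene placement controls.
#' @param n_atac_peaks,n_g4_peaks peak counts per set.
#' @param g4_width,atac_width_g4,atac_width_bg,g4seq_hit_width interval
#'   widths in bp (each jittered +/- 30%).
#' @param frac_g4_in_promoter fraction of G4 peaks planted inside promoter
#'   windows.
#' @param frac_g4_with_atac fraction of G4 peaks covered by an ATAC peak.
#' @param g4seq_coverage fraction of G4 peaks covered by a same-strand
#'   G4-seq hit.
#' @param g4seq_background number of background G4-seq hits (random
#'   position and strand).
#' @param strand_frac_watson probability a G4 peak's true strand is Watson.
#' @param frac_differential named vector (`atac`, `g4`, `rna`): fraction of
#'   features with a planted differential effect per modality.
#' @param lfc_mean,lfc_sd mean and sd of planted log2 fold changes.
#' @param concordance_rho planted pairwise correlation of log2 fold changes
#'   across modalities for promoter-linked G4/ATAC/gene trios.
#' @param nb_dispersion NB dispersion alpha (> 0) shared by all modalities.
#' @param baseline_log_mean,baseline_log_sd per-feature baseline mean
#'   counts are drawn lognormally with these (natural-log) parameters.
#' @param library_size_range range of per-sample relative depth factors.
#' @param n_replicates replicates per condition (>= 2).
#' @param cnv data frame with columns `frac` and `log2`: fraction of each
#'   chromosome assigned to segments of the given case/control log2
#'   copy-number ratio (remainder is neutral).
#' @param promoter_flank promoter half-width in bp.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 2, chrom_size = 5e6, excluded_frac = 0.02,
                       n_genes = 200, gene_length_range = c(5000, 20000),
                       n_exon_range = c(2, 6),
                       n_atac_peaks = 1500, n_g4_peaks = 500,
                       g4_width = 200, atac_width_g4 = 988,
                       atac_width_bg = 347, g4seq_hit_width = 100,
                       frac_g4_in_promoter = 0.8, frac_g4_with_atac = 0.75,
                       g4seq_coverage = 0.8, g4seq_background = 300,
                       strand_frac_watson = 0.5,
                       frac_differential = c(atac = 0.3, g4 = 0.15,
                                             rna = 0.3),
                       lfc_mean = 0, lfc_sd = 1, concordance_rho = 0.6,
                       nb_dispersion = 0.05,
                       baseline_log_mean = log(150), baseline_log_sd = 1,
                       library_size_range = c(0.7, 1.3), n_replicates = 3,
                       cnv = data.frame(frac = c(0.05, 0.05),
                                        log2 = c(1, -1)),
                       promoter_flank = 3000) {
  cfg <- as.list(environment())
  fracs <- c(excluded_frac, frac_g4_in_promoter, frac_g4_with_atac,
             g4seq_coverage, strand_frac_watson, frac_differential,
             concordance_rho, if (nrow(cnv)) cnv$frac)
  if (any(fracs < 0 | fracs > 1)) stopf("all fractions must lie in [0, 1]")
  if (nrow(cnv) && sum(cnv$frac) > 1)
    stopf("cnv segment fractions sum to more than 1")
  if (n_chrom < 1) stopf("need at least one chromosome")
  if (chrom_size < 1e5) stopf("chrom_size must be >= 1e5 bp")
  if (n_replicates < 2) stopf("n_replicates must be >= 2")
  if (nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  if (!all(c("atac", "g4", "rna") %in% names(frac_differential)))
    stopf("frac_differential needs entries atac, g4, rna")
  structure(cfg, class = "sim_config")
}

#' Generate the synthetic genome
#'
#' @param config a [sim_config()].
#' @return a [genome_spec()] with `n_chrom` chromosomes of `chrom_size` bp
#'   and non-overlapping excluded regions covering about `excluded_frac`
#'   of each.
#' @export
generate_genome <- function(config) {
  sizes <- setNames(rep(config$chrom_size, config$n_chrom),
                    paste0("chr", seq_len(config$n_chrom)))
  if (config$excluded_frac == 0)
    return(genome_spec(sizes))
  if (config$excluded_frac >= 0.1)
    stopf("excluded_frac must be < 0.1")
  withr::with_seed(child_seed(config$seed, "genome"), {
    exc <- list()
    for (ch in names(sizes)) {
      n_blk <- 5L
      w <- floor(sizes[[ch]] * config$excluded_frac / n_blk)
      placed <- GenomicRanges::GRanges(seqinfo = genome_seqinfo(sizes))
      for (b in seq_len(n_blk)) {
        for (att in seq_len(1000)) {
          s <- floor(runif(1) * (sizes[[ch]] - w + 1)) + 1
          cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, s + w - 1))
          if (!IRanges::overlapsAny(cand, placed)) {
            placed <- c(placed, cand); break
          }
        }
      }
      exc[[ch]] <- placed
    }
    genome_spec(sizes, excluded = sort(do.call(c, unname(exc))))
  })
}

#' Generate non-overlapping spliced gene models
#'
#' Genes are placed by rejection sampling: spans never overlap one another
#' or excluded regions, roughly half on each strand, each with at least two
#' exons so a first exon-intron junction exists. Placement stops with a
#' capacity error when a gene cannot be placed within 1e4 attempts.
#'
#' @param genome a [genome_spec()].
#' @param config a [sim_config()].
#' @return a [gene_models()] object.
#' @export
generate_genes <- function(genome, config) {
  n <- config$n_genes
  if (n == 0)
    return(gene_models(character(0), character(0), character(0),
                       list(), list()))
  sizes <- genome$chrom_sizes
  withr::with_seed(child_seed(config$seed, "genes"), {
    placed <- GenomicRanges::GRanges(seqinfo = genome_seqinfo(sizes))
    chrom <- character(n); start <- numeric(n); len <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (att in seq_len(10000)) {
        li <- round(runif(1, config$gene_length_range[1],
                          config$gene_length_range[2]))
        ch <- sample(names(sizes), 1, prob = sizes)
        if (sizes[[ch]] < li) next
        s <- floor(runif(1) * (sizes[[ch]] - li + 1)) + 1
        cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, s + li - 1))
        if (IRanges::overlapsAny(cand, placed) ||
            IRanges::overlapsAny(cand, genome$excluded)) next
        placed <- c(placed, cand)
        chrom[i] <- ch; start[i] <- s; len[i] <- li
        ok <- TRUE; break
      }
      if (!ok)
        stopf("could not place gene %d of %d: genome too crowded", i, n)
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    exon_starts <- vector("list", n); exon_ends <- vector("list", n)
    cds_start <- cds_end <- numeric(n)
    for (i in seq_len(n)) {
      k <- sample(seq(config$n_exon_range[1], config$n_exon_range[2]), 1)
      s <- start[i]; e <- start[i] + len[i] - 1
      brk <- sort(sample(seq(s + 1, e - 1), 2 * (k - 1)))
      bnd <- c(s, brk, e)
      es <- bnd[seq(1, length(bnd), by = 2)]
      ee <- bnd[seq(2, length(bnd), by = 2)]
      ee[length(ee)] <- e
      # exon boundaries from sampled breakpoints: exon j = [es_j, ee_j]
      es <- bnd[2 * seq_len(k) - 1]
      ee <- bnd[2 * seq_len(k)]
      es[1] <- s; ee[k] <- e
      es[-1] <- es[-1] + 1  # introns are (ee_j, es_{j+1})
      exon_starts[[i]] <- es; exon_ends[[i]] <- ee
      # CDS from mid-first-exon to mid-last-exon so both UTRs exist
      cds_start[i] <- es[1] + max(1, floor((ee[1] - es[1]) / 2))
      cds_end[i] <- es[k] + max(0, floor((ee[k] - es[k]) / 2))
      if (cds_end[i] <= cds_start[i]) {
        cds_start[i] <- s + 1; cds_end[i] <- e - 1
      }
    }
    gene_models(sprintf("gene_%04d", seq_len(n)), chrom, strand,
                exon_starts, exon_ends, cds_start, cds_end)
  })
}

#' Generate peak and hit interval sets
#'
#' Plants `frac_g4_in_promoter` of the G4 peaks uniformly inside promoter
#' windows (the rest uniformly over the allowed genome), assigns each G4
#' peak a true strand, covers `frac_g4_with_atac` of them with an ATAC peak
#' centred on the G4, places the remaining ATAC peaks uniformly, and
#' generates G4-seq hits on the true strand inside a `g4seq_coverage`
#' fraction of G4 peaks plus uniform background hits of random strand.
#'
#' @param genome a [genome_spec()].
#' @param genes a [gene_models()] object.
#' @param config a [sim_config()].
#' @return list with `atac_peaks`, `g4_peaks`, `g4seq_hits` (`GRanges`; G4
#'   peaks carry `true_strand`, `planted_promoter`, `gene_id`, `atac_id`
#'   metadata) .
#' @export
generate_interval_data <- function(genome, genes, config) {
  sizes <- genome$chrom_sizes
  flank <- config$promoter_flank
  withr::with_seed(child_seed(config$seed, "peaks"), {
    jitter_w <- function(w, n) pmax(20, round(runif(n, 0.7, 1.3) * w))
    ng4 <- config$n_g4_peaks
    g4_w <- jitter_w(config$g4_width, ng4)
    n_prom <- round(config$frac_g4_in_promoter * ng4)
    if (n_prom > 0 && nrow(genes) == 0)
      stopf("no promoter space: frac_g4_in_promoter > 0 but no genes")
    g4_chrom <- character(ng4); g4_start <- numeric(ng4)
    gene_id <- rep(NA_character_, ng4)
    if (n_prom > 0) {
      gi <- sample(nrow(genes), n_prom, replace = TRUE)
      for (j in seq_len(n_prom)) {
        g <- gi[j]
        lo <- max(1, genes$tss[g] - flank)
        hi <- min(sizes[[genes$chrom[g]]], genes$tss[g] + flank - 1) -
          g4_w[j] + 1
        if (hi < lo)
          stopf("promoter window of %s too small for a %d bp peak",
                genes$gene_id[g], g4_w[j])
        g4_chrom[j] <- genes$chrom[g]
        g4_start[j] <- floor(runif(1) * (hi - lo + 1)) + lo
        gene_id[j] <- genes$gene_id[g]
      }
    }
    if (ng4 > n_prom) {
      idx <- seq(n_prom + 1, ng4)
      tmpl <- GenomicRanges::GRanges(
        sample(names(sizes), length(idx), replace = TRUE, prob = sizes),
        IRanges::IRanges(1, width = g4_w[idx]))
      bg <- shuffle_intervals(tmpl, genome, same_chrom = TRUE)
      g4_chrom[idx] <- as.character(GenomicRanges::seqnames(bg))
      g4_start[idx] <- GenomicRanges::start(bg)
    }
    g4 <- GenomicRanges::GRanges(g4_chrom,
                                 IRanges::IRanges(g4_start, width = g4_w),
                                 seqinfo = genome_seqinfo(sizes))
    g4$name <- sprintf("g4_%04d", seq_len(ng4))
    g4$true_strand <- ifelse(
      runif(ng4) < config$strand_frac_watson, "+", "-")
    g4$planted_promoter <- seq_len(ng4) <= n_prom
    g4$gene_id <- gene_id

    # ATAC peaks: covering peaks centred on a G4 subset, rest uniform
    n_cov <- round(config$frac_g4_with_atac * ng4)
    if (n_cov > config$n_atac_peaks)
      stopf("n_atac_peaks too small for frac_g4_with_atac")
    cov_idx <- if (n_cov > 0) sample(ng4, n_cov) else integer(0)
    atac_id <- rep(NA_character_, ng4)
    atac_chrom <- character(0); atac_start <- numeric(0); atac_w <- numeric(0)
    if (n_cov > 0) {
      wcov <- jitter_w(config$atac_width_g4, n_cov)
      mid <- floor((GenomicRanges::start(g4[cov_idx]) +
                      GenomicRanges::end(g4[cov_idx])) / 2)
      s <- pmax(1, mid - floor(wcov / 2))
      s <- pmin(s, sizes[as.character(GenomicRanges::seqnames(g4[cov_idx]))] -
                  wcov + 1)
      atac_chrom <- as.character(GenomicRanges::seqnames(g4[cov_idx]))
      atac_start <- s; atac_w <- wcov
      atac_id[cov_idx] <- sprintf("atac_%04d", seq_len(n_cov))
    }
    n_bg <- config$n_atac_peaks - n_cov
    if (n_bg > 0) {
      wbg <- jitter_w(config$atac_width_bg, n_bg)
      tmpl <- GenomicRanges::GRanges(
        sample(names(sizes), n_bg, replace = TRUE, prob = sizes),
        IRanges::IRanges(1, width = wbg))
      bg <- shuffle_intervals(tmpl, genome, same_chrom = TRUE)
      atac_chrom <- c(atac_chrom, as.character(GenomicRanges::seqnames(bg)))
      atac_start <- c(atac_start, GenomicRanges::start(bg))
      atac_w <- c(atac_w, wbg)
    }
    atac <- GenomicRanges::GRanges(atac_chrom,
                                   IRanges::IRanges(atac_start,
                                                    width = atac_w),
                                   seqinfo = genome_seqinfo(sizes))
    atac$name <- sprintf("atac_%04d", seq_along(atac))
    g4$atac_id <- atac_id

    # G4-seq hits: one on-strand hit inside covered peaks, plus background
    n_hit <- round(config$g4seq_coverage * ng4)
    hit_idx <- if (n_hit > 0) sample(ng4, n_hit) else integer(0)
    hits <- GenomicRanges::GRanges(seqinfo = genome_seqinfo(sizes))
    if (n_hit > 0) {
      hw <- pmin(jitter_w(config$g4seq_hit_width, n_hit),
                 GenomicRanges::width(g4[hit_idx]))
      off <- floor(runif(n_hit) *
                     (GenomicRanges::width(g4[hit_idx]) - hw + 1))
      hits <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(g4[hit_idx]),
        IRanges::IRanges(GenomicRanges::start(g4[hit_idx]) + off,
                         width = hw),
        strand = g4$true_strand[hit_idx],
        seqinfo = genome_seqinfo(sizes))
    }
    if (config$g4seq_background > 0) {
      nb <- config$g4seq_background
      tmpl <- GenomicRanges::GRanges(
        sample(names(sizes), nb, replace = TRUE, prob = sizes),
        IRanges::IRanges(1, width = jitter_w(config$g4seq_hit_width, nb)))
      bg <- shuffle_intervals(tmpl, genome, same_chrom = TRUE)
      GenomicRanges::strand(bg) <- sample(c("+", "-"), nb, replace = TRUE)
      hits <- c(hits, bg)
    }
    if (length(hits)) hits$name <- sprintf("hit_%05d", seq_along(hits))
    list(atac_peaks = atac, g4_peaks = g4, g4seq_hits = hits)
  })
}

#' Generate copy-number segments tiling the genome
#'
#' Each chromosome is tiled completely and without overlap: for each row of
#' `config$cnv`, a contiguous segment covering that fraction of the
#' chromosome at that log2 ratio, placed in random order among neutral
#' (log2 = 0) filler segments.
#'
#' @param genome a [genome_spec()].
#' @param config a [sim_config()].
#' @return `GRanges` from [cnv_segments()] tiling every chromosome.
#' @export
generate_cnv_segments <- function(genome, config) {
  sizes <- genome$chrom_sizes
  withr::with_seed(child_seed(config$seed, "cnv"), {
    out <- list()
    for (ch in names(sizes)) {
      size <- sizes[[ch]]
      alt_w <- floor(size * config$cnv$frac)
      alt_l2 <- config$cnv$log2
      rem <- size - sum(alt_w)
      n_fill <- length(alt_w) + 1
      cuts <- sort(runif(n_fill - 1))
      fill_w <- floor(diff(c(0, cuts, 1)) * rem)
      fill_w[n_fill] <- rem - sum(fill_w[-n_fill])
      # interleave filler and altered pieces in random altered order
      ord <- sample(length(alt_w))
      widths <- numeric(0); l2 <- numeric(0)
      for (j in seq_len(n_fill)) {
        widths <- c(widths, fill_w[j]); l2 <- c(l2, 0)
        if (j <= length(ord)) {
          widths <- c(widths, alt_w[ord[j]]); l2 <- c(l2, alt_l2[ord[j]])
        }
      }
      keep <- widths > 0
      widths <- widths[keep]; l2 <- l2[keep]
      ends <- cumsum(widths)
      starts <- c(1, utils::head(ends, -1) + 1)
      out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                              log2 = l2)
    }
    tab <- do.call(rbind, out)
    cnv_segments(tab$chrom, tab$start, tab$end, tab$log2, genome = genome)
  })
}

#' Simulate a negative-binomial count matrix for one modality
#'
#' Per feature i and sample j,
#' `counts_ij ~ NB(mean = baseline_i * s_j * 2^(lfc_i * case_j) *
#' cnr_i^case_j, dispersion alpha)` with variance `mu + alpha mu^2`.
#' Copy-number ratios act multiplicatively on the case condition only,
#' emulating counts collected from a case genome with altered copy number.
#'
#' @param true_log2fc per-feature planted log2 fold change (case vs
#'   control).
#' @param cnr per-feature copy-number ratio (default 1).
#' @param n_replicates replicates per condition.
#' @param dispersion NB dispersion alpha (> 0).
#' @param baseline per-feature baseline means; drawn lognormally when
#'   `NULL`.
#' @param baseline_log_mean,baseline_log_sd lognormal parameters used when
#'   `baseline` is `NULL`.
#' @param library_size_range range for per-sample depth factors.
#' @param feature_ids row names.
#' @param seed optional integer seed.
#' @return list with `counts` (integer matrix), `condition` (factor,
#'   levels control/case), `size_factors`, `baseline`.
#' @export
generate_counts <- function(true_log2fc, cnr = 1, n_replicates = 3,
                            dispersion = 0.05, baseline = NULL,
                            baseline_log_mean = log(150),
                            baseline_log_sd = 1,
                            library_size_range = c(0.7, 1.3),
                            feature_ids = NULL, seed = NULL) {
  if (dispersion <= 0) stopf("dispersion must be > 0")
  n <- length(true_log2fc)
  if (length(cnr) == 1) cnr <- rep(cnr, n)
  stopifnot(length(cnr) == n)
  with_seed_maybe(seed, {
    if (is.null(baseline))
      baseline <- exp(rnorm(n, baseline_log_mean, baseline_log_sd))
    m <- 2 * n_replicates
    sf <- runif(m, library_size_range[1], library_size_range[2])
    condition <- factor(rep(c("control", "case"), each = n_replicates),
                        levels = c("control", "case"))
    mu <- outer(baseline, sf)
    case_cols <- which(condition == "case")
    mu[, case_cols] <- mu[, case_cols] * (2^true_log2fc * cnr)
    counts <- matrix(rnbinom(n * m, size = 1 / dispersion, mu = mu), n, m)
    storage.mode(counts) <- "integer"
    if (is.null(feature_ids)) feature_ids <- sprintf("f%05d", seq_len(n))
    dimnames(counts) <- list(feature_ids,
                             paste0(condition, "_",
                                    rep(seq_len(n_replicates), 2)))
    list(counts = counts, condition = condition, size_factors = sf,
         baseline = baseline)
  })
}

#' The planted promoter fraction that yields a target enrichment fold
#'
#' With a fraction p of peaks planted inside promoter windows and the rest
#' uniform over the allowed genome, the expected shuffle-null fold
#' enrichment of peak-promoter overlaps is `(p + (1-p) q0) / q0`, where
#' `q0` is the probability that a uniformly placed peak overlaps a
#' promoter window. Solving for p gives the planting fraction needed for a
#' target fold.
#'
#' @param fold target fold enrichment (> 1).
#' @param genome a [genome_spec()].
#' @param genes a [gene_models()] object.
#' @param peak_width typical peak width in bp.
#' @param flank promoter half-width in bp.
#' @return list with `frac` (planting fraction, in \[0, 1\]) and `q0`.
#' @export
promoter_fraction_for_fold <- function(fold, genome, genes,
                                       peak_width = 200, flank = 3000) {
  q0 <- promoter_hit_prob(genome, genes, peak_width, flank)
  frac <- q0 * (fold - 1) / (1 - q0)
  if (frac > 1)
    stopf("fold %.2f not reachable (max %.2f at full planting)",
          fold, (1 + q0 * 0) / q0)
  list(frac = frac, q0 = q0)
}

# probability a uniformly placed peak of the given width overlaps a
# promoter window (edge effects at chromosome ends ignored)
#' @noRd
promoter_hit_prob <- function(genome, genes, peak_width, flank) {
  prom <- GenomicRanges::reduce(promoter_windows(genes, flank = flank,
                                                 genome = genome),
                                ignore.strand = TRUE)
  widened <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(prom),
    IRanges::IRanges(pmax(1, GenomicRanges::start(prom) - peak_width + 1),
                     GenomicRanges::end(prom)))
  widened <- GenomicRanges::reduce(widened)
  hit_bp <- sum(GenomicRanges::width(widened))
  allowed_bp <- sum(genome$chrom_sizes) -
    sum(GenomicRanges::width(GenomicRanges::reduce(genome$excluded)))
  hit_bp / allowed_bp
}

#' Generate a complete synthetic study with planted ground truth
#'
#' Composes [generate_genome()], [generate_genes()],
#' [generate_interval_data()], [generate_cnv_segments()] and
#' [generate_counts()] into a study bundle. Planted differential effects
#' are correlated across modalities for promoter-linked trios (gene, its
#' promoter G4 peak, the ATAC peak covering that G4): each trio shares one
#' differential indicator and its log2 fold changes have pairwise
#' correlation `concordance_rho`; unlinked features draw independent
#' effects at the per-modality differential fraction. Copy-number ratios
#' apply to the ATAC and G4 count matrices (the modalities that are
#' copy-number normalized downstream), not to RNA.
#'
#' @param config a [sim_config()].
#' @return object of class `study_bundle`: list with `genome`, `genes`,
#'   `atac_peaks`, `g4_peaks`, `g4seq_hits`, `cnv_segments`, `counts`
#'   (per-modality lists from [generate_counts()]), `truth` (per-modality
#'   truth tables plus planted scalars) and `config`.
#' @export
generate_study <- function(config) {
  genome <- generate_genome(config)
  genes <- generate_genes(genome, config)
  iv <- generate_interval_data(genome, genes, config)
  segments <- generate_cnv_segments(genome, config)
  g4 <- iv$g4_peaks; atac <- iv$atac_peaks
  ng4 <- length(g4); natac <- length(atac); ngene <- nrow(genes)

  rho <- config$concordance_rho
  fd <- config$frac_differential
  lfc <- withr::with_seed(child_seed(config$seed, "effects"), {
    g4_lfc <- numeric(ng4); atac_lfc <- numeric(natac)
    rna_lfc <- numeric(ngene)
    # Linked trios are grouped per gene (several promoter G4 peaks can
    # share a promoter): each gene draws one differential indicator and
    # one latent effect b; every lfc in the group is
    # lfc_mean + sqrt(rho) b + sqrt(1 - rho) e, giving pairwise
    # cross-modality correlation rho among differential trios.
    mix <- function(b) config$lfc_mean + sqrt(rho) * b +
      sqrt(1 - rho) * rnorm(length(b), 0, config$lfc_sd)
    linked <- which(g4$planted_promoter & !is.na(g4$gene_id))
    link_gene <- g4$gene_id[linked]
    genes_linked <- unique(link_gene)
    gene_diff <- setNames(runif(length(genes_linked)) < fd[["g4"]],
                          genes_linked)
    gene_b <- setNames(rnorm(length(genes_linked), 0, config$lfc_sd),
                       genes_linked)
    diff_gene_ids <- genes_linked[gene_diff[genes_linked]]
    rna_lfc[match(diff_gene_ids, genes$gene_id)] <-
      mix(gene_b[diff_gene_ids])
    trio_diff <- gene_diff[link_gene]
    g4_lfc[linked[trio_diff]] <- mix(gene_b[link_gene[trio_diff]])
    aid <- g4$atac_id[linked]
    with_atac <- trio_diff & !is.na(aid)
    atac_lfc[match(aid[with_atac], atac$name)] <-
      mix(gene_b[link_gene[with_atac]])
    # unlinked features: independent effects at per-modality fractions
    un_g4 <- setdiff(seq_len(ng4), linked)
    d <- runif(length(un_g4)) < fd[["g4"]]
    g4_lfc[un_g4[d]] <- rnorm(sum(d), config$lfc_mean, config$lfc_sd)
    un_atac <- which(!(atac$name %in% aid[with_atac]))
    d <- runif(length(un_atac)) < fd[["atac"]]
    atac_lfc[un_atac[d]] <- rnorm(sum(d), config$lfc_mean, config$lfc_sd)
    un_rna <- setdiff(seq_len(ngene),
                      match(diff_gene_ids, genes$gene_id))
    d <- runif(length(un_rna)) < fd[["rna"]]
    rna_lfc[un_rna[d]] <- rnorm(sum(d), config$lfc_mean, config$lfc_sd)
    list(g4 = g4_lfc, atac = atac_lfc, rna = rna_lfc)
  })

  atac_cnr <- assign_segments(atac, segments)$cnr
  g4_cnr <- assign_segments(g4, segments)$cnr

  counts <- list(
    atac = generate_counts(lfc$atac, cnr = atac_cnr,
                           n_replicates = config$n_replicates,
                           dispersion = config$nb_dispersion,
                           baseline_log_mean = config$baseline_log_mean,
                           baseline_log_sd = config$baseline_log_sd,
                           library_size_range = config$library_size_range,
                           feature_ids = atac$name,
                           seed = child_seed(config$seed, "counts_atac")),
    g4 = generate_counts(lfc$g4, cnr = g4_cnr,
                         n_replicates = config$n_replicates,
                         dispersion = config$nb_dispersion,
                         baseline_log_mean = config$baseline_log_mean,
                         baseline_log_sd = config$baseline_log_sd,
                         library_size_range = config$library_size_range,
                         feature_ids = g4$name,
                         seed = child_seed(config$seed, "counts_g4")),
    rna = generate_counts(lfc$rna, cnr = 1,
                          n_replicates = config$n_replicates,
                          dispersion = config$nb_dispersion,
                          baseline_log_mean = config$baseline_log_mean,
                          baseline_log_sd = config$baseline_log_sd,
                          library_size_range = config$library_size_range,
                          feature_ids = genes$gene_id,
                          seed = child_seed(config$seed, "counts_rna")))

  status_of <- function(x) factor(ifelse(x > 0, "up",
                                  ifelse(x < 0, "down", "nd")),
                                  levels = c("up", "down", "nd"))
  q0 <- promoter_hit_prob(genome, genes, config$g4_width,
                          config$promoter_flank)
  p <- config$frac_g4_in_promoter
  truth <- list(
    atac = data.frame(feature_id = atac$name, true_log2fc = lfc$atac,
                      true_status = status_of(lfc$atac), cnr = atac_cnr,
                      stringsAsFactors = FALSE),
    g4 = data.frame(feature_id = g4$name, true_log2fc = lfc$g4,
                    true_status = status_of(lfc$g4), cnr = g4_cnr,
                    true_strand = g4$true_strand,
                    planted_promoter = g4$planted_promoter,
                    gene_id = g4$gene_id, atac_id = g4$atac_id,
                    stringsAsFactors = FALSE),
    rna = data.frame(feature_id = genes$gene_id, true_log2fc = lfc$rna,
                     true_status = status_of(lfc$rna),
                     stringsAsFactors = FALSE),
    promoter_enrichment_fold = (p + (1 - p) * q0) / q0,
    promoter_hit_prob = q0,
    concordance_rho = rho)

  structure(list(genome = genome, genes = genes, atac_peaks = atac,
                 g4_peaks = g4, g4seq_hits = iv$g4seq_hits,
                 cnv_segments = segments, counts = counts, truth = truth,
                 config = config),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("study_bundle:",
      length(x$genome$chrom_sizes), "chromosomes;",
      nrow(x$genes), "genes;",
      length(x$atac_peaks), "ATAC peaks;",
      length(x$g4_peaks), "G4 peaks;",
      length(x$g4seq_hits), "G4-seq hits;",
      length(x$cnv_segments), "CNV segments\n")
  cat(sprintf("  planted promoter enrichment fold: %.2f; concordance rho: %.2f\n",
              x$truth$promoter_enrichment_fold, x$truth$concordance_rho))
  invisible(x)
}

#' Validate a study bundle's structural invariants
#'
#' Checks interval bounds, count-matrix shapes, ground-truth coverage and
#' status/log2fc consistency; errors on the first violation.
#'
#' @param bundle a [generate_study()] result.
#' @return `TRUE` invisibly.
#' @export
validate_study <- function(bundle) {
  gs <- bundle$genome
  for (nm in c("atac_peaks", "g4_peaks", "g4seq_hits")) {
    gr <- bundle[[nm]]
    if (length(gr)) as_genome_granges(gr, gs$chrom_sizes)
  }
  cov <- sum(GenomicRanges::width(bundle$cnv_segments))
  if (cov != sum(gs$chrom_sizes))
    stopf("CNV segments do not tile the genome")
  for (mod in names(bundle$counts)) {
    cm <- bundle$counts[[mod]]
    if (any(cm$counts < 0) || any(cm$counts != floor(cm$counts)))
      stopf("counts for %s are not non-negative integers", mod)
    tt <- bundle$truth[[mod]]
    if (!identical(rownames(cm$counts), tt$feature_id))
      stopf("truth rows do not match count rows for %s", mod)
    bad <- (tt$true_log2fc > 0 & tt$true_status != "up") |
      (tt$true_log2fc < 0 & tt$true_status != "down") |
      (tt$true_log2fc == 0 & tt$true_status != "nd")
    if (any(bad)) stopf("truth status inconsistent with log2fc for %s", mod)
  }
  invisible(TRUE)
}
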