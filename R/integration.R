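# Tri-modal integration: promoter peak-to-gene linking, expression
# normalization and zFPKM activity calls, cross-modal correlation of
# differential signals, proximity-decay analysis, additive stratification
# and the type-III interaction model.

#' Link peaks to genes by promoter proximity
#'
#' A peak is linked to a gene when its nearest edge is less than `flank` bp
#' from the gene's TSS (distance 0 when the peak covers the TSS). A peak
#' within reach of several TSSs goes to the nearest one; exact ties go to
#' the lexicographically smallest `gene_id`.
#'
#' @param peaks `GRanges`.
#' @param genes a [gene_models()] object.
#' @param flank linking threshold in bp, exclusive (default 3000: "less
#'   than 3 kb from the TSS").
#' @param measure `"edge"` (default; nearest peak edge to TSS) or
#'   `"center"` (peak midpoint to TSS).
#' @return data frame with columns `peak_index`, `gene_id`, `distance_bp`,
#'   one row per linked peak.
#' @export
link_peaks_to_genes <- function(peaks, genes, flank = 3000,
                                measure = c("edge", "center")) {
  measure <- match.arg(measure)
  if (!length(peaks) || !nrow(genes))
    return(data.frame(peak_index = integer(0), gene_id = character(0),
                      distance_bp = numeric(0)))
  tss <- tss_sites(genes)
  x <- peaks
  if (measure == "center") {
    mid <- floor((GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2)
    x <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                IRanges::IRanges(mid, mid))
  }
  pc <- as.character(GenomicRanges::seqnames(x))
  tc <- as.character(GenomicRanges::seqnames(tss))
  ps <- GenomicRanges::start(x); pe <- GenomicRanges::end(x)
  tpos <- GenomicRanges::start(tss)
  out <- vector("list", length(x))
  for (ch in unique(pc)) {
    ti <- which(tc == ch)
    if (!length(ti)) next
    for (i in which(pc == ch)) {
      d <- pmax(tpos[ti] - pe[i] - 1, ps[i] - tpos[ti] - 1, 0)
      dmin <- min(d)
      if (dmin >= flank) next
      cand <- ti[d == dmin]
      best <- cand[order(tss$gene_id[cand])][1]
      out[[i]] <- data.frame(peak_index = i, gene_id = tss$gene_id[best],
                             distance_bp = dmin, stringsAsFactors = FALSE)
    }
  }
  out <- Filter(Negate(is.null), out)
  if (!length(out))
    return(data.frame(peak_index = integer(0), gene_id = character(0),
                      distance_bp = numeric(0)))
  do.call(rbind, out)
}

#' TPM and RPKM normalization of feature counts
#'
#' `rpkm_i = count_i * 1e9 / (length_i * sum(counts))`, with the total
#' count over the quantified features as the library size, and
#' `tpm_i = rate_i * 1e6 / sum(rates)` with `rate_i = count_i / length_i`;
#' TPM columns sum to 1e6 exactly.
#'
#' @param counts non-negative vector or matrix (features x samples).
#' @param lengths feature lengths in bp (> 0), one per feature.
#' @return list with elements `tpm` and `rpkm`, shaped like `counts`.
#' @export
normalize_expression <- function(counts, lengths) {
  vec <- is.null(dim(counts))
  m <- if (vec) matrix(counts, ncol = 1) else as.matrix(counts)
  if (length(lengths) != nrow(m))
    stopf("need one length per feature")
  if (any(lengths <= 0)) stopf("feature lengths must be > 0")
  lib <- colSums(m)
  rpkm <- sweep(m * 1e9 / lengths, 2, lib, "/")
  rate <- m / lengths
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  if (vec) list(tpm = drop(tpm), rpkm = drop(rpkm))
  else list(tpm = tpm, rpkm = rpkm)
}

#' zFPKM standardization of log2 expression values
#'
#' Fits a half-Gaussian to the main (active) mode of a log2 expression
#' distribution: the mode `mu` is located from a kernel density estimate
#' (Silverman's bandwidth, 4096-point grid), refined as the vertex of a
#' quadratic fitted to the density around the peak -- the raw argmax of a
#' KDE is a noisy location estimator and the refinement stabilizes it
#' without bias for a locally symmetric peak. Then
#' `sigma = mean(x[x > mu] - mu) * sqrt(pi/2)` from the upper half, and
#' `z = (x - mu)/sigma`; genes with `z <= threshold` (default -3) are
#' called inactive.
#'
#' @param log2_values numeric vector of log2 expression (e.g. log2 TPM);
#'   non-finite values get `z = NA` and `active = FALSE`.
#' @param threshold activity threshold on z (default -3).
#' @return list with `mu`, `sigma`, `z` (per input value), `active`
#'   (logical per input value).
#' @export
zfpkm <- function(log2_values, threshold = -3) {
  x <- log2_values[is.finite(log2_values)]
  if (length(x) < 50)
    stopf("need >= 50 finite values to fit the expression mode")
  if (sd(x) == 0)
    stopf("degenerate expression distribution (zero variance)")
  d <- density(x, bw = "nrd0", n = 4096)
  mu <- d$x[which.max(d$y)]
  win <- abs(d$x - mu) < 0.75 * sd(x)
  if (sum(win) >= 5) {
    co <- coef(lm(y ~ x + I(x^2), data.frame(x = d$x[win], y = d$y[win])))
    vertex <- -co[[2]] / (2 * co[[3]])
    if (is.finite(vertex) && co[[3]] < 0 &&
        abs(vertex - mu) < 0.75 * sd(x)) mu <- vertex
  }
  upper <- x[x > mu]
  if (!length(upper)) stopf("no values above the fitted mode")
  sigma <- mean(upper - mu) * sqrt(pi / 2)
  if (!is.finite(sigma) || sigma <= 0)
    stopf("degenerate expression distribution (sigma <= 0)")
  z <- (log2_values - mu) / sigma
  z[!is.finite(log2_values)] <- NA_real_
  active <- !is.na(z) & z > threshold
  list(mu = mu, sigma = sigma, z = z, active = active)
}

#' Pearson correlation between two differential-signal vectors
#'
#' Pairs with an `NA` in either vector are dropped listwise; the p-value is
#' the two-sided t-reference of `cor.test`.
#'
#' @param x,y numeric vectors of matched log2 fold changes.
#' @return list with `r`, `p`, `n` (complete pairs used).
#' @export
correlate_differentials <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stopf("need >= 3 complete pairs")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
    stopf("zero variance in one of the vectors")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Correlation decay with distance from G4 sites
#'
#' ATAC peaks are indexed relative to each G4 site by signed rank: 0 for
#' overlapping peaks, +k for the k-th non-overlapping peak at increasing
#' genomic coordinate, -k for the k-th at decreasing coordinate (the
#' biological readout, decay with |offset|, is symmetric in this
#' convention). Per offset, the Pearson correlation between the G4 and
#' ATAC log2 fold changes over all contributing pairs; offsets with fewer
#' than 3 pairs are reported as `NA`. When `distance_bins` is given the
#' same correlation is also computed per physical edge-distance bin.
#'
#' @param g4_sites `GRanges` of G4 sites.
#' @param atac_peaks `GRanges` of ATAC peaks.
#' @param g4_lfc,atac_lfc numeric log2 fold changes parallel to the two
#'   sets.
#' @param max_rank largest |rank| to report (default 3).
#' @param distance_bins optional numeric vector of bin breakpoints in bp
#'   (edge distances; 0 = overlap gets its own bin).
#' @return list with `rank_table` (columns `offset`, `n`, `r`, `p`) and
#'   `distance_table` (or `NULL`).
#' @export
proximity_decay <- function(g4_sites, atac_peaks, g4_lfc, atac_lfc,
                            max_rank = 3, distance_bins = NULL) {
  stopifnot(length(g4_lfc) == length(g4_sites),
            length(atac_lfc) == length(atac_peaks))
  offsets <- seq(-max_rank, max_rank)
  pairs <- list()
  gc <- as.character(GenomicRanges::seqnames(g4_sites))
  ac <- as.character(GenomicRanges::seqnames(atac_peaks))
  gs <- GenomicRanges::start(g4_sites); ge <- GenomicRanges::end(g4_sites)
  as_ <- GenomicRanges::start(atac_peaks); ae <- GenomicRanges::end(atac_peaks)
  for (ch in unique(gc)) {
    ai <- which(ac == ch)
    if (!length(ai)) next
    a_by_start <- ai[order(as_[ai])]
    a_by_end <- ai[order(ae[ai])]
    for (i in which(gc == ch)) {
      ov <- ai[as_[ai] <= ge[i] & ae[ai] >= gs[i]]
      if (length(ov))
        pairs[[length(pairs) + 1]] <- data.frame(
          offset = 0L, g4 = i, atac = ov,
          dist = 0)
      right <- a_by_start[as_[a_by_start] > ge[i]]
      if (length(right)) {
        k <- seq_len(min(max_rank, length(right)))
        pairs[[length(pairs) + 1]] <- data.frame(
          offset = k, g4 = i, atac = right[k],
          dist = as_[right[k]] - ge[i] - 1)
      }
      left <- rev(a_by_end[ae[a_by_end] < gs[i]])
      if (length(left)) {
        k <- seq_len(min(max_rank, length(left)))
        pairs[[length(pairs) + 1]] <- data.frame(
          offset = -k, g4 = i, atac = left[k],
          dist = gs[i] - ae[left[k]] - 1)
      }
    }
  }
  per_group_cor <- function(df, key, levels_out) {
    do.call(rbind, lapply(levels_out, function(lv) {
      sub <- df[df[[key]] == lv, , drop = FALSE]
      x <- g4_lfc[sub$g4]; y <- atac_lfc[sub$atac]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) >= 3 && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
        ct <- cor.test(x[ok], y[ok])
        data.frame(group = lv, n = sum(ok), r = unname(ct$estimate),
                   p = ct$p.value, stringsAsFactors = FALSE)
      } else {
        data.frame(group = lv, n = sum(ok), r = NA_real_, p = NA_real_,
                   stringsAsFactors = FALSE)
      }
    }))
  }
  if (!length(pairs)) {
    rank_table <- data.frame(offset = offsets, n = 0L, r = NA_real_,
                             p = NA_real_)
    return(list(rank_table = rank_table, distance_table = NULL))
  }
  df <- do.call(rbind, pairs)
  rank_table <- per_group_cor(df, "offset", offsets)
  names(rank_table)[1] <- "offset"
  distance_table <- NULL
  if (!is.null(distance_bins)) {
    df$bin <- as.character(cut(df$dist, breaks = unique(c(-1, distance_bins)),
                               include.lowest = FALSE))
    df$bin[df$offset == 0] <- "overlap"
    lv <- c("overlap", setdiff(sort(unique(df$bin)), "overlap"))
    distance_table <- per_group_cor(df[!is.na(df$bin), ], "bin", lv)
    names(distance_table)[1] <- "distance_bin"
  }
  list(rank_table = rank_table, distance_table = distance_table)
}

#' Stratify expression change by accessibility and G4 status
#'
#' Genes are bucketed by the differential status of their linked ATAC peak
#' and G4 peak; per cell, the median RNA log2 fold change and a two-sided
#' rank-sum (Wilcoxon) test against the doubly-non-differential reference
#' cell. Empty cells are reported with `n = 0` and no test.
#'
#' @param trimodal data frame with columns `rna_log2fc`, `atac_status`,
#'   `g4_status` (statuses in `up`/`down`/`nd`).
#' @return data frame with one row per occupied cell: `atac_status`,
#'   `g4_status`, `n`, `median_rna_log2fc`, `p_vs_reference` (`NA` for the
#'   reference cell itself).
#' @export
stratify_additive <- function(trimodal) {
  lv <- c("nd", "up", "down")
  a <- factor(as.character(trimodal$atac_status), levels = lv)
  g <- factor(as.character(trimodal$g4_status), levels = lv)
  ref <- trimodal$rna_log2fc[a == "nd" & g == "nd"]
  grid <- expand.grid(atac_status = lv, g4_status = lv,
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- a == grid$atac_status[i] & g == grid$g4_status[i]
    vals <- trimodal$rna_log2fc[sel]
    p <- NA_real_
    if (length(vals) > 0 && length(ref) > 0 &&
        !(grid$atac_status[i] == "nd" && grid$g4_status[i] == "nd"))
      p <- suppressWarnings(wilcox.test(vals, ref)$p.value)
    data.frame(atac_status = grid$atac_status[i],
               g4_status = grid$g4_status[i], n = length(vals),
               median_rna_log2fc = if (length(vals)) median(vals) else NA_real_,
               p_vs_reference = p, stringsAsFactors = FALSE)
  }))
}

#' Type-III interaction model of expression change
#'
#' Fits `rna_log2fc ~ atac_status * g4_status` with both statuses as
#' 3-level factors (nd/up/down) under sum-to-zero contrasts and performs
#' type-III F tests per term (main effects remain testable in the presence
#' of the interaction), the standard multifactor ANOVA for asking whether
#' accessibility and G4 changes act cooperatively on expression. When
#' empty cells make the design rank deficient, the interaction row is
#' flagged: its F is then computed on the estimable subspace (the full
#' model with aliased interaction columns dropped, against the additive
#' model, with correspondingly reduced degrees of freedom) and main
#' effects come from the additive model.
#'
#' @param trimodal data frame with columns `rna_log2fc`, `atac_status`,
#'   `g4_status`.
#' @return data frame with columns `term`, `df`, `F`, `p`, `flagged`.
#' @export
anova_interaction <- function(trimodal) {
  lv <- c("nd", "up", "down")
  d <- data.frame(
    rna = trimodal$rna_log2fc,
    atac = factor(as.character(trimodal$atac_status), levels = lv),
    g4 = factor(as.character(trimodal$g4_status), levels = lv))
  d <- d[complete.cases(d), ]
  d$atac <- droplevels(d$atac)
  d$g4 <- droplevels(d$g4)
  if (nlevels(d$atac) < 2 || nlevels(d$g4) < 2)
    stopf("each factor needs >= 2 observed levels")
  cells <- table(d$atac, d$g4)
  full_rank <- all(cells > 0)
  ctr <- list(atac = "contr.sum", g4 = "contr.sum")
  terms_out <- c("atac", "g4", "atac:g4")
  if (full_rank) {
    fit <- lm(rna ~ atac * g4, data = d, contrasts = ctr)
    an <- car::Anova(fit, type = "III")
    rows <- match(c("atac", "g4", "atac:g4"), rownames(an))
    data.frame(term = terms_out, df = an$Df[rows], F = an$`F value`[rows],
               p = an$`Pr(>F)`[rows], flagged = FALSE,
               stringsAsFactors = FALSE)
  } else {
    fit_add <- lm(rna ~ atac + g4, data = d, contrasts = ctr)
    an <- car::Anova(fit_add, type = "III")
    rows <- match(c("atac", "g4"), rownames(an))
    # interaction tested on its estimable subspace: aliased columns of
    # the full model are dropped by lm(); compare against the additive fit
    fit_full <- lm(rna ~ atac * g4, data = d, contrasts = ctr)
    rss_full <- sum(fit_full$residuals^2)
    rss_add <- sum(fit_add$residuals^2)
    df_int <- fit_add$df.residual - fit_full$df.residual
    out <- data.frame(term = terms_out,
                      df = c(an$Df[rows], df_int),
                      F = c(an$`F value`[rows], NA),
                      p = c(an$`Pr(>F)`[rows], NA),
                      flagged = c(FALSE, FALSE, TRUE),
                      stringsAsFactors = FALSE)
    if (df_int > 0) {
      F_int <- ((rss_add - rss_full) / df_int) /
        (rss_full / fit_full$df.residual)
      out$F[3] <- F_int
      out$p[3] <- pf(F_int, df_int, fit_full$df.residual,
                     lower.tail = FALSE)
    }
    warnf(paste("empty design cells: interaction tested on its estimable",
                "subspace and flagged"))
    out
  }
}
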