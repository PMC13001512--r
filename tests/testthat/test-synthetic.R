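test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(frac_g4_in_promoter = 1.2), "fractions")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(chrom_size = 1e4), "chrom_size")
  expect_error(sim_config(cnv = data.frame(frac = c(0.6, 0.6),
                                           log2 = c(1, -1))), "sum")
})

test_that("genome generation honours the config and seed", {
  cfg <- sim_config(seed = 3, n_chrom = 2, chrom_size = 1e6,
                    excluded_frac = 0.02)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_equal(g1$chrom_sizes, c(chr1 = 1e6, chr2 = 1e6))
  expect_identical(GenomicRanges::start(g1$excluded),
                   GenomicRanges::start(g2$excluded))
  frac <- sum(GenomicRanges::width(g1$excluded)) / sum(g1$chrom_sizes)
  expect_lt(frac, 0.1)
  expect_gt(frac, 0.005)
  # no excluded regions when the fraction is zero
  g0 <- generate_genome(sim_config(excluded_frac = 0))
  expect_equal(length(g0$excluded), 0L)
})

test_that("genes are non-overlapping, spliced and strand-balanced", {
  cfg <- fast_config(seed = 5)
  genome <- generate_genome(cfg)
  genes <- generate_genes(genome, cfg)
  expect_equal(nrow(genes), cfg$n_genes)
  span <- gr(genes$chrom, genes$start, genes$end)
  hits <- GenomicRanges::findOverlaps(span, drop.self = TRUE)
  expect_equal(length(hits), 0L)
  expect_false(any(IRanges::overlapsAny(span, genome$excluded)))
  expect_true(all(vapply(genes$exon_starts, length, integer(1)) >= 2))
  expect_gt(mean(genes$strand == "+"), 0.3)
  expect_lt(mean(genes$strand == "+"), 0.7)
  # strand conventions for the TSS
  plus <- genes$strand == "+"
  expect_equal(genes$tss[plus], genes$start[plus])
  expect_equal(genes$tss[!plus], genes$end[!plus])
  # n_genes = 0 -> empty model set
  empty <- generate_genes(genome, fast_config(n_genes = 0))
  expect_equal(nrow(empty), 0L)
})

test_that("planted promoter fraction is honoured within binomial error", {
  cfg <- fast_config(seed = 9, n_g4_peaks = 1000, n_atac_peaks = 1200,
                     frac_g4_in_promoter = 0.8)
  genome <- generate_genome(cfg)
  genes <- generate_genes(genome, cfg)
  iv <- generate_interval_data(genome, genes, cfg)
  prom <- promoter_windows(genes, genome = genome)
  in_prom <- IRanges::overlapsAny(iv$g4_peaks, prom, ignore.strand = TRUE)
  # planted 80% plus uniform strays; 99% binomial CI half-width ~ 3.3%
  expect_gt(mean(in_prom), 0.77)
  # frac 1 -> every peak in a promoter
  cfg1 <- fast_config(seed = 9, frac_g4_in_promoter = 1)
  iv1 <- generate_interval_data(genome, generate_genes(genome, cfg1), cfg1)
  prom1 <- promoter_windows(generate_genes(genome, cfg1), genome = genome)
  expect_true(all(IRanges::overlapsAny(iv1$g4_peaks, prom1,
                                       ignore.strand = TRUE)))
  # zero hit coverage -> only background hits remain
  cfg0 <- fast_config(seed = 9, g4seq_coverage = 0, g4seq_background = 50)
  iv0 <- generate_interval_data(genome, generate_genes(genome, cfg0), cfg0)
  expect_equal(length(iv0$g4seq_hits), 50L)
})

test_that("CNV segments tile every chromosome at the requested ratios", {
  cfg <- fast_config(seed = 13,
                     cnv = data.frame(frac = 0.1, log2 = 1))
  genome <- generate_genome(cfg)
  seg <- generate_cnv_segments(genome, cfg)
  for (ch in names(genome$chrom_sizes)) {
    sub <- seg[as.character(GenomicRanges::seqnames(seg)) == ch]
    sub <- sort(sub)
    expect_equal(GenomicRanges::start(sub)[1], 1)
    expect_equal(GenomicRanges::end(sub)[length(sub)],
                 unname(genome$chrom_sizes[ch]))
    # contiguous tiling: next start = previous end + 1
    if (length(sub) > 1)
      expect_equal(GenomicRanges::start(sub)[-1],
                   GenomicRanges::end(sub)[-length(sub)] + 1)
    amp <- sum(GenomicRanges::width(sub[sub$log2_ratio == 1]))
    expect_equal(amp / genome$chrom_sizes[[ch]], 0.1, tolerance = 0.01)
  }
  expect_true(all(seg$cnr == 2^seg$log2_ratio))
  # single neutral segment covers everything
  cfg0 <- fast_config(cnv = data.frame(frac = numeric(0),
                                       log2 = numeric(0)))
  seg0 <- generate_cnv_segments(generate_genome(cfg0), cfg0)
  expect_true(all(seg0$cnr == 1))
})

test_that("simulated counts match their negative-binomial contract", {
  # near-Poisson limit, no effects: column means track size factors
  sim <- generate_counts(rep(0, 5000), n_replicates = 3,
                         dispersion = 1e-6, seed = 21)
  ratio <- colMeans(sim$counts) / mean(sim$baseline)
  expect_equal(unname(ratio), unname(sim$size_factors), tolerance = 0.03)
  # null effects: per-feature empirical log2 ratios centred at 0
  sim0 <- generate_counts(rep(0, 5000), n_replicates = 6,
                          dispersion = 0.02, library_size_range = c(1, 1),
                          baseline_log_mean = log(500), seed = 22)
  cond <- sim0$condition
  l2r <- log2(rowMeans(sim0$counts[, cond == "case"]) /
                rowMeans(sim0$counts[, cond == "control"]))
  expect_lt(abs(mean(l2r, na.rm = TRUE)), 0.02)
  # determinism
  a <- generate_counts(rep(0, 100), n_replicates = 2, seed = 5)
  b <- generate_counts(rep(0, 100), n_replicates = 2, seed = 5)
  expect_identical(a$counts, b$counts)
  expect_error(generate_counts(0, dispersion = 0), "dispersion")
})

test_that("study bundles are deterministic, valid and concordant", {
  cfg <- fast_config(seed = 29, concordance_rho = 0.9,
                     n_g4_peaks = 400, frac_differential =
                       c(atac = 0.3, g4 = 0.5, rna = 0.3))
  b1 <- generate_study(cfg)
  b2 <- generate_study(cfg)
  expect_identical(b1$counts$atac$counts, b2$counts$atac$counts)
  expect_identical(GenomicRanges::start(b1$g4_peaks),
                   GenomicRanges::start(b2$g4_peaks))
  expect_true(validate_study(b1))
  # planted cross-modality correlation among linked pairs approaches rho
  tg <- b1$truth$g4
  linked <- tg[tg$planted_promoter & !is.na(tg$atac_id), ]
  atac_lfc <- b1$truth$atac$true_log2fc[match(linked$atac_id,
                                              b1$truth$atac$feature_id)]
  r <- naive_pearson(linked$true_log2fc, atac_lfc)
  expect_gt(r, 0.8)
  rna_lfc <- b1$truth$rna$true_log2fc[match(linked$gene_id,
                                            b1$truth$rna$feature_id)]
  expect_gt(naive_pearson(linked$true_log2fc, rna_lfc), 0.8)
})

test_that("study bundles round-trip through the plain-text serialization", {
  cfg <- fast_config(seed = 33, n_genes = 40, n_atac_peaks = 120,
                     n_g4_peaks = 60, g4seq_background = 30)
  b <- generate_study(cfg)
  tmp <- withr::local_tempdir()
  write_study(b, tmp)
  back <- read_study(tmp)
  expect_equal(back$genome$chrom_sizes, b$genome$chrom_sizes)
  expect_equal(GenomicRanges::start(back$genome$excluded),
               GenomicRanges::start(b$genome$excluded))
  expect_equal(back$genes$gene_id, b$genes$gene_id)
  expect_equal(back$genes$exon_starts, b$genes$exon_starts)
  expect_equal(back$genes$tss, b$genes$tss)
  for (nm in c("atac_peaks", "g4_peaks", "g4seq_hits")) {
    expect_equal(GenomicRanges::start(back[[nm]]),
                 GenomicRanges::start(b[[nm]]))
    expect_equal(GenomicRanges::width(back[[nm]]),
                 GenomicRanges::width(b[[nm]]))
  }
  expect_equal(as.character(GenomicRanges::strand(back$g4seq_hits)),
               as.character(GenomicRanges::strand(b$g4seq_hits)))
  expect_equal(back$cnv_segments$log2_ratio, b$cnv_segments$log2_ratio)
  for (mod in c("atac", "g4", "rna")) {
    expect_identical(back$counts[[mod]]$counts, b$counts[[mod]]$counts)
    expect_equal(back$counts[[mod]]$condition, b$counts[[mod]]$condition)
    expect_equal(back$counts[[mod]]$size_factors,
                 b$counts[[mod]]$size_factors, tolerance = 1e-6)
    expect_equal(back$truth[[mod]]$true_log2fc, b$truth[[mod]]$true_log2fc,
                 tolerance = 1e-6)
    expect_equal(back$truth[[mod]]$true_status, b$truth[[mod]]$true_status)
  }
  expect_equal(back$truth$promoter_enrichment_fold,
               b$truth$promoter_enrichment_fold, tolerance = 1e-6)
  expect_equal(back$config$seed, b$config$seed)
  expect_equal(back$config$frac_differential, b$config$frac_differential)
})
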