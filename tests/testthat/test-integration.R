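test_that("peak-to-gene links use edge distance with a strict threshold", {
  gm <- gene_models(c("g600", "g900"), c("chrA", "chrA"), c("+", "+"),
                    exon_starts = list(c(5001, 7001), c(30001, 32001)),
                    exon_ends = list(c(6000, 9000), c(31000, 35000)))
  # peak [4000,4500) (0-based), TSS at 5000 -> edge distance 500
  l <- link_peaks_to_genes(gr("chrA", 4001, 4500), gm)
  expect_equal(l$gene_id, "g600")
  expect_equal(l$distance_bp, 500)
  # peak covering the TSS -> distance 0
  l0 <- link_peaks_to_genes(gr("chrA", 4901, 5101), gm)
  expect_equal(l0$distance_bp, 0)
  # edge exactly 3000 bp away is NOT linked ("less than 3 kb")
  lx <- link_peaks_to_genes(gr("chrA", 1001, 2000), gm)  # end0 2000, TSS0 5000
  expect_equal(nrow(lx), 0L)
  l29 <- link_peaks_to_genes(gr("chrA", 1002, 2001), gm)
  expect_equal(l29$distance_bp, 2999)
  # nearest TSS wins
  gm2 <- gene_models(c("near", "far"), c("chrA", "chrA"), c("+", "+"),
                     exon_starts = list(c(10601, 12001), c(10901, 12501)),
                     exon_ends = list(c(11000, 13000), c(11200, 13500)))
  ln <- link_peaks_to_genes(gr("chrA", 9001, 10000), gm2)
  expect_equal(ln$gene_id, "near")
  # links are stable under peak reordering
  peaks <- gr("chrA", c(4001, 4901, 29001), c(4500, 5101, 29500))
  fwd <- link_peaks_to_genes(peaks, gm)
  rev_ <- link_peaks_to_genes(rev(peaks), gm)
  expect_equal(fwd$gene_id[order(fwd$peak_index)],
               rev_$gene_id[order(3 - rev_$peak_index + 1)])
  expect_true(all(fwd$distance_bp < 3000))
})

test_that("TPM and RPKM follow their closed forms", {
  ne <- normalize_expression(c(10, 90), c(1000, 1000))
  expect_equal(ne$tpm, c(1e5, 9e5))
  expect_equal(sum(ne$tpm), 1e6)
  # rpkm: count 10, length 1000, library 1e6 -> 10
  ne2 <- normalize_expression(c(10, 999990), c(1000, 50000))
  expect_equal(ne2$rpkm[1], 10)
  # matrix form: per-sample TPM sums are exact
  withr::local_seed(71)
  m <- matrix(rpois(300, 50), 100, 3)
  lens <- sample(200:5000, 100)
  nm <- normalize_expression(m, lens)
  expect_equal(unname(colSums(nm$tpm)), rep(1e6, 3))
  expect_error(normalize_expression(c(1, 2), c(0, 10)), "lengths")
})

test_that("zFPKM recovers a planted half-Gaussian and applies z > -3", {
  withr::local_seed(72)
  x <- rnorm(10000, 5, 2)
  fit <- zfpkm(x)
  expect_lt(abs(fit$mu - 5), 0.2)
  expect_lt(abs(fit$sigma - 2), 0.2)
  # a value 4 sigma below the mode is inactive
  fit2 <- zfpkm(c(x, fit$mu - 4 * fit$sigma))
  expect_false(fit2$active[length(fit2$active)])
  expect_true(all(fit$active == (fit$z > -3)))
  # non-finite values (log2 of zero expression) -> inactive, z = NA
  fit3 <- zfpkm(c(x, -Inf))
  expect_true(is.na(fit3$z[length(fit3$z)]))
  expect_false(fit3$active[length(fit3$active)])
  expect_error(zfpkm(rnorm(20)), ">= 50")
  expect_error(zfpkm(rep(1, 100)), "")
})

test_that("differential correlations match the closed-form Pearson r", {
  expect_equal(correlate_differentials(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(correlate_differentials(1:10, -(1:10))$r, -1)
  # hand-computed toy: x=(1,2,3,4), y=(2,1,4,3) -> r = 0.6
  expect_equal(correlate_differentials(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6)
  withr::local_seed(73)
  for (i in 1:20) {
    x <- rnorm(50); y <- 0.5 * x + rnorm(50)
    y[sample(50, 5)] <- NA
    ok <- !is.na(y)
    got <- correlate_differentials(x, y)
    expect_equal(got$r, naive_pearson(x[ok], y[ok]))
    expect_equal(got$n, sum(ok))
  }
  expect_error(correlate_differentials(1:2, 2:3), "pairs")
  expect_error(correlate_differentials(rep(1, 10), rnorm(10)), "variance")
})

test_that("proximity ranks match a hand-built layout", {
  # one G4 site, five ATAC peaks: two overlapping, neighbours either side
  g4 <- gr("chrA", 10001, 10400)
  atac <- gr("chrA",
             c(9901, 10301,   # overlap -> rank 0
               11001, 12001,  # to the right -> +1, +2
               8001),         # to the left -> -1
             c(10100, 10500, 11100, 12100, 8600))
  pd <- proximity_decay(g4, atac, g4_lfc = 1,
                        atac_lfc = c(1, 2, 3, 4, 5), max_rank = 2)
  rt <- pd$rank_table
  expect_equal(rt$offset, -2:2)
  expect_equal(rt$n[rt$offset == 0], 2L)
  expect_equal(rt$n[rt$offset == 1], 1L)
  expect_equal(rt$n[rt$offset == 2], 1L)
  expect_equal(rt$n[rt$offset == -1], 1L)
  expect_equal(rt$n[rt$offset == -2], 0L)
  # empty ATAC set -> all-NA table
  pd0 <- proximity_decay(g4, atac[0], 1, numeric(0))
  expect_true(all(is.na(pd0$rank_table$r)))
})

test_that("correlation decays off the overlap rank when coupling is local", {
  withr::local_seed(74)
  n <- 300
  starts <- seq(10001, by = 12000, length.out = n)
  g4 <- gr("chrA", starts, starts + 300)
  # one overlapping ATAC peak per G4 plus one ~2 kb to the right
  atac_ov <- gr("chrA", starts - 200, starts + 500)
  atac_nb <- gr("chrA", starts + 2001, starts + 2500)
  atac <- c(atac_ov, atac_nb)
  g4_lfc <- rnorm(n)
  # coupling only for the overlapping peak
  atac_lfc <- c(0.9 * g4_lfc + 0.3 * rnorm(n), rnorm(n))
  pd <- proximity_decay(g4, atac, g4_lfc, atac_lfc, max_rank = 1)
  rt <- pd$rank_table
  r0 <- rt$r[rt$offset == 0]
  expect_gt(r0, 0.8)
  expect_gt(r0, rt$r[rt$offset == 1] + 0.5)
  # distance binning keeps the overlap class separate
  pd2 <- proximity_decay(g4, atac, g4_lfc, atac_lfc, max_rank = 1,
                         distance_bins = c(1000, 5000))
  expect_equal(pd2$distance_table$distance_bin[1], "overlap")
  expect_gt(pd2$distance_table$r[1], 0.8)
})

test_that("additive stratification finds the doubly-changed cell strongest", {
  withr::local_seed(75)
  n <- 3000
  atac <- sample(c("nd", "up", "down"), n, TRUE, prob = c(0.6, 0.2, 0.2))
  g4 <- sample(c("nd", "up", "down"), n, TRUE, prob = c(0.6, 0.2, 0.2))
  eff <- function(s) ifelse(s == "up", 0.8, ifelse(s == "down", -0.8, 0))
  tri <- data.frame(rna_log2fc = eff(atac) + eff(g4) + rnorm(n, 0, 0.4),
                    atac_status = atac, g4_status = g4)
  st <- stratify_additive(tri)
  upup <- st[st$atac_status == "up" & st$g4_status == "up", ]
  ref <- st[st$atac_status == "nd" & st$g4_status == "nd", ]
  expect_equal(max(abs(st$median_rna_log2fc)),
               max(abs(st$median_rna_log2fc[
                 (st$atac_status != "nd") & (st$g4_status != "nd") &
                   (st$atac_status == st$g4_status)])))
  expect_lt(upup$p_vs_reference, 1e-10)
  expect_true(is.na(ref$p_vs_reference))
  # all-nd input: single occupied cell, no tests
  allnd <- stratify_additive(data.frame(rna_log2fc = rnorm(20),
                                        atac_status = "nd",
                                        g4_status = "nd"))
  expect_equal(sum(allnd$n > 0), 1L)
  expect_true(all(is.na(allnd$p_vs_reference)))
  # identical groups give p near 1
  same <- data.frame(rna_log2fc = rep(c(1, 2, 3, 4), 10),
                     atac_status = rep(c("nd", "up"), each = 20),
                     g4_status = "nd")
  sts <- stratify_additive(same)
  expect_gt(sts$p_vs_reference[sts$atac_status == "up" &
                                 sts$g4_status == "nd"], 0.95)
})

test_that("type-III F matches a full-vs-reduced RSS oracle", {
  withr::local_seed(76)
  n <- 400
  d <- data.frame(
    atac_status = sample(c("nd", "up", "down"), n, TRUE),
    g4_status = sample(c("nd", "up", "down"), n, TRUE))
  d$rna_log2fc <- rnorm(n) + 0.5 * (d$atac_status == "up")
  got <- anova_interaction(d)
  # oracle: drop each term's columns from the sum-contrast model matrix
  lv <- c("nd", "up", "down")
  fd <- data.frame(rna = d$rna_log2fc,
                   a = factor(d$atac_status, lv),
                   g = factor(d$g4_status, lv))
  X <- model.matrix(~ a * g, fd,
                    contrasts.arg = list(a = "contr.sum", g = "contr.sum"))
  rss <- function(X) sum(lm.fit(X, fd$rna)$residuals^2)
  rss_full <- rss(X)
  df_res <- n - ncol(X)
  asgn <- attr(X, "assign")
  for (i in seq_len(3)) {
    Xr <- X[, asgn != i, drop = FALSE]
    df_t <- sum(asgn == i)
    F_or <- ((rss(Xr) - rss_full) / df_t) / (rss_full / df_res)
    expect_equal(got$F[i], F_or, tolerance = 1e-10)
    expect_equal(got$p[i], pf(F_or, df_t, df_res, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("the interaction test is calibrated and powered", {
  withr::local_seed(77)
  sim_tri <- function(n, interaction = 0) {
    a <- sample(c("nd", "up", "down"), n, TRUE, prob = c(0.6, 0.2, 0.2))
    g <- sample(c("nd", "up", "down"), n, TRUE, prob = c(0.6, 0.2, 0.2))
    eff <- function(s) ifelse(s == "up", 0.5, ifelse(s == "down", -0.5, 0))
    y <- eff(a) + eff(g) + interaction * (a == "up" & g == "up") +
      rnorm(n, 0, 0.5)
    data.frame(rna_log2fc = y, atac_status = a, g4_status = g)
  }
  # null: interaction p approximately uniform over 200 runs
  p_null <- replicate(200, {
    res <- anova_interaction(sim_tri(800))
    res$p[res$term == "atac:g4"]
  })
  expect_gt(ks.test(p_null, "punif")$p.value, 0.01)
  # power: +0.5 only in the up/up cell detected at p < 0.01 in >= 90%
  p_alt <- replicate(100, {
    res <- anova_interaction(sim_tri(3000, interaction = 0.5))
    res$p[res$term == "atac:g4"]
  })
  expect_gte(mean(p_alt < 0.01), 0.9)
  # empty cells: interaction flagged, mains still reported
  d <- sim_tri(200)
  d <- d[!(d$atac_status == "down" & d$g4_status == "down"), ]
  expect_warning(res <- anova_interaction(d), "flagged")
  expect_true(res$flagged[res$term == "atac:g4"])
  expect_true(all(is.finite(res$F[1:2])))
})

test_that("promoter-linked trimodal records recover planted concordance", {
  cfg <- fast_config(seed = 81, concordance_rho = 0.6, n_g4_peaks = 300,
                     frac_differential = c(atac = 0.3, g4 = 0.5, rna = 0.3))
  b <- generate_study(cfg)
  links <- link_peaks_to_genes(b$g4_peaks, b$genes)
  tg <- b$truth$g4
  rna <- b$truth$rna
  g4_lfc <- tg$true_log2fc[links$peak_index]
  rna_lfc <- rna$true_log2fc[match(links$gene_id, rna$feature_id)]
  r <- correlate_differentials(g4_lfc, rna_lfc)
  # planted pairwise correlation: rho among linked differential trios;
  # tolerance covers link mismatches at promoter boundaries
  expect_gt(r$r, 0.45)
  expect_lt(r$p, 1e-6)
})
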