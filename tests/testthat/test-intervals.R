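test_that("overlap_join computes intersection lengths and the >150bp rule", {
  a <- gr("chrA", 1, 200)     # [0,200) in BED terms
  b <- gr("chrA", 101, 400)   # [100,400)
  res <- overlap_join(a, b)
  expect_equal(res, data.frame(a_index = 1L, b_index = 1L, overlap_bp = 100L))
  # "overlap larger than 150 bp" = min_overlap 151
  expect_equal(nrow(overlap_join(a, b, min_overlap = 151)), 0L)
  expect_equal(nrow(overlap_join(a, b, min_overlap = 100)), 1L)
  expect_error(overlap_join(a, b, min_overlap = 0), "min_overlap")
})

test_that("overlap_join matches the all-pairs oracle and is symmetric", {
  withr::local_seed(101)
  for (rep in 1:4) {
    a <- random_intervals(200)
    b <- random_intervals(200)
    mo <- sample(c(1, 50, 151), 1)
    got <- overlap_join(a, b, min_overlap = mo)
    want <- naive_overlap_join(a, b, min_overlap = mo)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
    swapped <- overlap_join(b, a, min_overlap = mo)
    expect_equal(
      sort(paste(got$a_index, got$b_index)),
      sort(paste(swapped$b_index, swapped$a_index)))
  }
})

test_that("closest_intervals picks nearest edge, breaking ties low", {
  q <- gr("chrA", 501, 600)                    # [500,600)
  s <- gr("chrA", c(1, 701), c(100, 800))      # [0,100), [700,800)
  res <- closest_intervals(q, s)
  expect_equal(res$subject_index, 2L)
  expect_equal(res$distance_bp, 100)
  # overlap -> distance 0
  expect_equal(closest_intervals(q, gr("chrA", 550, 560))$distance_bp, 0)
  # tie: equidistant -> lower start wins
  tie <- closest_intervals(gr("chrA", 501, 600),
                           gr("chrA", c(701, 301), c(800, 400)))
  expect_equal(tie$subject_index, 2L)
  # chromosome absent from subject -> Inf sentinel
  miss <- closest_intervals(gr("chrZ", 1, 10), s)
  expect_true(is.na(miss$subject_index) && is.infinite(miss$distance_bp))
})

test_that("closest_intervals and peak_density match brute force", {
  withr::local_seed(202)
  for (rep in 1:3) {
    q <- random_intervals(100)
    s <- random_intervals(100)
    expect_equal(closest_intervals(q, s), naive_closest(q, s))
    x <- random_intervals(200, max_pos = 5e4, max_width = 2000)
    expect_equal(peak_density(x, flank = 5000),
                 naive_peak_density(x, flank = 5000))
  }
})

test_that("peak_density counts neighbours, excluding self", {
  expect_equal(peak_density(gr("chrA", 50001, 50100)), 0L)
  two <- gr("chrA", c(10001, 15001), c(10100, 15100))  # 5 kb apart
  expect_equal(peak_density(two, flank = 10000), c(1L, 1L))
  expect_equal(peak_density(two, flank = 1000), c(0L, 0L))
})

test_that("shuffle preserves lengths, avoids exclusions, is seeded", {
  genome <- tiny_genome(excluded = gr("chrA", 200001, 300000))
  x <- gr(rep(c("chrA", "chrB"), each = 25),
          seq(1, by = 1500, length.out = 50),
          seq(1, by = 1500, length.out = 50) + rep(99:148, length.out = 50))
  s1 <- shuffle_intervals(x, genome, seed = 5)
  s2 <- shuffle_intervals(x, genome, seed = 5)
  expect_identical(GenomicRanges::start(s1), GenomicRanges::start(s2))
  expect_equal(sort(GenomicRanges::width(s1)),
               sort(GenomicRanges::width(x)))
  expect_equal(as.character(GenomicRanges::seqnames(s1)),
               as.character(GenomicRanges::seqnames(x)))
  expect_false(any(IRanges::overlapsAny(s1, genome$excluded)))
  expect_error(
    shuffle_intervals(gr("chrB", 1, 6e5), genome),
    "longer")
})

test_that("shuffled starts are uniform over legal positions", {
  genome <- genome_spec(c(chr1 = 1e6))
  x <- gr("chr1", rep(1, 2000), rep(100, 2000))
  s <- shuffle_intervals(x, genome, seed = 11)
  ks <- suppressWarnings(
    ks.test(GenomicRanges::start(s), "punif", 1, 1e6 - 100 + 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("resample_within_universe draws uniformly without replacement", {
  u <- gr("chrA", seq(1, by = 1000, length.out = 10),
          seq(100, by = 1000, length.out = 10))
  full <- resample_within_universe(u, u, seed = 3)
  expect_equal(sort(GenomicRanges::start(full)),
               sort(GenomicRanges::start(u)))
  expect_error(resample_within_universe(c(u, u), u), "larger")
  withr::local_seed(42)
  freq <- integer(10)
  for (i in 1:4000) {
    smp <- resample_within_universe(u[1:3], u)
    idx <- match(GenomicRanges::start(smp), GenomicRanges::start(u))
    freq[idx] <- freq[idx] + 1L
  }
  expect_true(all(abs(freq / 4000 - 0.3) < 0.025))
})

test_that("promoter windows are TSS +/- flank, clipped and stranded", {
  gm <- gene_models(c("p1", "m1"), c("chrA", "chrA"), c("+", "-"),
                    exon_starts = list(c(5001, 7001), c(5001, 7001)),
                    exon_ends = list(c(6000, 9000), c(6000, 9000)))
  # "+" gene, TSS (0-based) 5000 -> window [2000, 8000)
  pw <- promoter_windows(gm, flank = 3000)
  expect_equal(GenomicRanges::start(pw)[1], 2001)
  expect_equal(GenomicRanges::end(pw)[1], 8000)
  # "-" gene: TSS = last covered base (0-based 8999)
  expect_equal(GenomicRanges::start(pw)[2], 6000)
  expect_equal(GenomicRanges::end(pw)[2], 11999)
  # clipping at chromosome start
  gm2 <- gene_models("e1", "chrA", "+",
                     exon_starts = list(c(1001, 3001)),
                     exon_ends = list(c(2000, 5000)))
  pw2 <- promoter_windows(gm2, flank = 3000)
  expect_equal(GenomicRanges::start(pw2), 1)
  expect_equal(GenomicRanges::end(pw2), 4000)
})

test_that("annotate_features applies the documented precedence", {
  gm <- two_gene_models()
  # gA ("+"): exons [10000,12000), [14000,15000), [18000,20000) 0-based;
  # promoter = TSS(10000) +/- 3kb = [7000,13000)
  x <- gr("chrA",
          c(10501,  # within the first exon, and within the promoter window
            13500,  # first intron, past the promoter window
            11950,  # covers the Ex1-Int1 junction, but inside the promoter
            13050,  # strictly inside the first intron, outside promoter
            14201,  # inside second (other) exon, outside promoter
            30001), # intergenic
          c(10600, 13600, 12050, 13080, 14300, 30100))
  res <- annotate_features(x, gm)
  expect_equal(as.character(res$category[1]), "promoter/TSS")
  expect_equal(as.character(res$category[2]), "first intron")
  # junction coverage is trumped by the promoter window
  expect_equal(as.character(res$category[3]), "promoter/TSS")
  expect_equal(as.character(res$category[4]), "first intron")
  expect_equal(as.character(res$category[5]), "other exon")
  expect_equal(as.character(res$category[6]), "intergenic")
  expect_true(all(!is.na(res$category)))
})

test_that("junction and UTR categories resolve outside promoter windows", {
  # long gene so features sit > 3 kb from the TSS
  gm <- gene_models("gL", "chrA", "+",
                    exon_starts = list(c(1001, 20001, 40001)),
                    exon_ends = list(c(15000, 25000, 45000)),
                    cds_start = 5001, cds_end = 42000)
  # junction between first exon end (0-based boundary 15000) and intron
  j <- annotate_features(gr("chrA", 14950, 15050), gm)
  expect_equal(as.character(j$category), "1st-Ex-Int junction")
  # one bp short of covering both junction bases -> first exon
  e <- annotate_features(gr("chrA", 14950, 15000), gm)
  expect_equal(as.character(e$category), "first exon")
  u3 <- annotate_features(gr("chrA", 43001, 43100), gm)
  expect_equal(as.character(u3$category), "3'UTR")
  fi <- annotate_features(gr("chrA", 16001, 16100), gm)
  expect_equal(as.character(fi$category), "first intron")
  # minus-strand gene: first exon is the 3'-most genomic exon
  gmr <- gene_models("gR", "chrB", "-",
                     exon_starts = list(c(1001, 20001, 40001)),
                     exon_ends = list(c(5000, 25000, 45000)),
                     cds_start = 3000, cds_end = 42000)
  jr <- annotate_features(gr("chrB", 39950, 40050), gmr)
  expect_equal(as.character(jr$category), "1st-Ex-Int junction")
  fe <- annotate_features(gr("chrB", 40500, 40600), gmr)
  expect_equal(as.character(fe$category), "first exon")
})

test_that("BED and chrom.sizes round-trip through the readers", {
  tmp <- withr::local_tempdir()
  genome <- tiny_genome()
  x <- gr("chrA", c(101, 501), c(200, 700), strand = c("+", "-"),
          name = c("a", "b"), score = c(1L, 2L))
  write_bed(x, file.path(tmp, "x.bed"))
  y <- read_bed(file.path(tmp, "x.bed"), genome = genome)
  expect_equal(GenomicRanges::start(y), GenomicRanges::start(x))
  expect_equal(GenomicRanges::end(y), GenomicRanges::end(x))
  expect_equal(as.character(GenomicRanges::strand(y)),
               as.character(GenomicRanges::strand(x)))
  expect_equal(y$name, x$name)
  write_chrom_sizes(genome$chrom_sizes, file.path(tmp, "g.sizes"))
  expect_equal(read_chrom_sizes(file.path(tmp, "g.sizes")),
               genome$chrom_sizes)
  # interval outside the genome bounds is rejected
  write_bed(gr("chrA", 999901, 1000200), file.path(tmp, "bad.bed"))
  expect_error(read_bed(file.path(tmp, "bad.bed"), genome = genome),
               "bounds")
})

test_that("gene models round-trip through BED12", {
  tmp <- withr::local_tempdir()
  gm <- two_gene_models()
  write_genes_bed12(gm, file.path(tmp, "genes.bed"))
  back <- read_genes_bed12(file.path(tmp, "genes.bed"))
  expect_equal(back$gene_id, gm$gene_id)
  expect_equal(back$tss, gm$tss)
  expect_equal(back$exon_starts, gm$exon_starts)
  expect_equal(back$exon_ends, gm$exon_ends)
  expect_equal(back$cds_start, gm$cds_start)
  expect_equal(back$cds_end, gm$cds_end)
})
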