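# Naive quadratic oracles and fixture builders, independent of the package
# implementations they check. Coordinates are pulled into plain vectors up
# front; the pair logic itself stays brute force.

gr <- function(chrom, start, end, strand = NULL, ...) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (!is.null(strand)) GenomicRanges::strand(g) <- strand
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(g)[[nm]] <- extra[[nm]]
  g
}

plain <- function(g) list(chrom = as.character(GenomicRanges::seqnames(g)),
                          start = GenomicRanges::start(g),
                          end = GenomicRanges::end(g))

random_intervals <- function(n, chroms = c("chrA", "chrB"), max_pos = 1e5,
                             max_width = 500) {
  ch <- sample(chroms, n, replace = TRUE)
  st <- sample.int(max_pos, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  gr(ch, st, st + w - 1)
}

# all-pairs overlap join
naive_overlap_join <- function(a, b, min_overlap = 1) {
  A <- plain(a); B <- plain(b)
  out <- list()
  for (i in seq_along(A$start)) for (j in seq_along(B$start)) {
    if (A$chrom[i] != B$chrom[j]) next
    ov <- min(A$end[i], B$end[j]) - max(A$start[i], B$start[j]) + 1
    if (ov >= min_overlap)
      out[[length(out) + 1]] <- c(i, j, ov)
  }
  if (!length(out))
    return(data.frame(a_index = integer(0), b_index = integer(0),
                      overlap_bp = integer(0)))
  m <- do.call(rbind, out)
  df <- data.frame(a_index = m[, 1], b_index = m[, 2], overlap_bp = m[, 3])
  df[order(df$a_index, df$b_index), , drop = FALSE]
}

# brute-force nearest subject by edge distance; ties -> lower start
naive_closest <- function(query, subject) {
  Q <- plain(query); S <- plain(subject)
  n <- length(Q$start)
  out <- data.frame(query_index = seq_len(n),
                    subject_index = rep(NA_integer_, n),
                    distance_bp = rep(Inf, n))
  for (i in seq_len(n)) {
    best_d <- Inf; best_j <- NA_integer_; best_start <- Inf
    for (j in seq_along(S$start)) {
      if (Q$chrom[i] != S$chrom[j]) next
      d <- max(S$start[j] - Q$end[i] - 1, Q$start[i] - S$end[j] - 1, 0)
      if (d < best_d || (d == best_d && S$start[j] < best_start)) {
        best_d <- d; best_j <- j; best_start <- S$start[j]
      }
    }
    out$subject_index[i] <- best_j
    out$distance_bp[i] <- best_d
  }
  out
}

naive_peak_density <- function(x, flank = 10000) {
  X <- plain(x)
  n <- length(X$start)
  cnt <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j == i || X$chrom[i] != X$chrom[j]) next
    if (X$start[j] <= X$end[i] + flank && X$end[j] >= X$start[i] - flank)
      cnt[i] <- cnt[i] + 1L
  }
  cnt
}

naive_count_overlaps <- function(query, subject, mode = "subject") {
  Q <- plain(query); S <- plain(subject)
  hit <- matrix(FALSE, length(Q$start), length(S$start))
  for (i in seq_along(Q$start)) for (j in seq_along(S$start)) {
    if (Q$chrom[i] != S$chrom[j]) next
    hit[i, j] <- min(Q$end[i], S$end[j]) - max(Q$start[i], S$start[j]) >= 0
  }
  if (mode == "subject") sum(colSums(hit) > 0) else sum(hit)
}

# exhaustive hypergeometric tails via choose(), independent of phyper
enum_hyper_upper <- function(k, K, N, n) {
  lo <- max(0, k); hi <- min(K, n)
  if (lo > hi) return(0)
  js <- lo:hi
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
enum_hyper_lower <- function(k, K, N, n) {
  lo <- max(0, n - (N - K)); hi <- min(k, K, n)
  if (lo > hi) return(0)
  js <- lo:hi
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# closed-form Pearson r
naive_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# direct median-of-ratios
naive_size_factors <- function(counts) {
  geo <- apply(counts, 1, function(r) exp(mean(log(r))))
  ok <- apply(counts, 1, function(r) all(r > 0))
  apply(counts, 2, function(col) median((col / geo)[ok]))
}

# small differential-result frames for concordance tests
mk_results <- function(ids, status, p = NULL, lfc = NULL) {
  if (is.null(p)) p <- ifelse(status == "nd", 0.5, 0.001)
  if (is.null(lfc)) lfc <- ifelse(status == "up", 1,
                           ifelse(status == "down", -1, 0))
  data.frame(feature_id = ids, p = p, p_adj = p, log2fc = lfc,
             status = factor(status, levels = c("up", "down", "nd")),
             stringsAsFactors = FALSE)
}

tiny_genome <- function(sizes = c(chrA = 1e6, chrB = 5e5), excluded = NULL) {
  genome_spec(sizes, excluded = excluded)
}

# two-gene fixture with known exon/UTR layout, one gene per strand
two_gene_models <- function() {
  gene_models(
    gene_id = c("gA", "gB"),
    chrom = c("chrA", "chrA"),
    strand = c("+", "-"),
    exon_starts = list(c(10001, 14001, 18001), c(50001, 56001)),
    exon_ends = list(c(12000, 15000, 20000), c(53000, 60000)),
    cds_start = c(11001, 52001),
    cds_end = c(19000, 58000))
}

# small study config used by several test files; sizes chosen so the whole
# suite stays fast while leaving every planted signal recoverable
fast_config <- function(seed = 1, ...) {
  args <- modifyList(
    list(seed = seed, n_chrom = 2, chrom_size = 2e6, n_genes = 80,
         n_atac_peaks = 500, n_g4_peaks = 200, g4seq_background = 100),
    list(...))
  do.call(sim_config, args)
}
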