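# On-disk form of a study bundle: plain-text standard formats only
# (chrom.sizes, BED6, BED12, TSV, YAML), so a bundle can be regenerated,
# archived and reloaded byte-comparably.

#' Write a study bundle to a directory of plain-text files
#'
#' Layout: `chrom.sizes`, `excluded.bed`, `genes.bed` (BED12),
#' `atac_peaks.bed`, `g4_peaks.bed`, `g4seq_hits.bed` (BED6),
#' `cnv_segments.tsv`, `counts_<modality>.tsv` (feature_id + one column
#' per sample), `design_<modality>.tsv` (sample, condition, size_factor),
#' `truth_<modality>.tsv`, `truth_scalars.yaml`, `config.yaml`.
#'
#' @param bundle a [generate_study()] result.
#' @param dir output directory (created if missing).
#' @return `dir` invisibly.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_chrom_sizes(bundle$genome$chrom_sizes, fp("chrom.sizes"))
  exc <- bundle$genome$excluded
  if (length(exc)) write_bed(exc, fp("excluded.bed"))
  else writeLines(character(0), fp("excluded.bed"))
  write_genes_bed12(bundle$genes, fp("genes.bed"))
  write_bed(bundle$atac_peaks, fp("atac_peaks.bed"))
  write_bed(bundle$g4_peaks, fp("g4_peaks.bed"))
  if (length(bundle$g4seq_hits)) write_bed(bundle$g4seq_hits,
                                           fp("g4seq_hits.bed"))
  else writeLines(character(0), fp("g4seq_hits.bed"))
  write_cnv_segments(bundle$cnv_segments, fp("cnv_segments.tsv"))
  for (mod in names(bundle$counts)) {
    cm <- bundle$counts[[mod]]
    tab <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, fp(sprintf("counts_%s.tsv", mod)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    des <- data.frame(sample = colnames(cm$counts),
                      condition = as.character(cm$condition),
                      size_factor = cm$size_factors)
    utils::write.table(des, fp(sprintf("design_%s.tsv", mod)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tt <- bundle$truth[[mod]]
    utils::write.table(tt, fp(sprintf("truth_%s.tsv", mod)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  scalars <- bundle$truth[!vapply(bundle$truth, is.data.frame, logical(1))]
  yaml::write_yaml(scalars, fp("truth_scalars.yaml"))
  cfg <- unclass(bundle$config)
  cfg$cnv <- as.list(cfg$cnv)
  cfg$frac_differential <- as.list(cfg$frac_differential)
  yaml::write_yaml(cfg, fp("config.yaml"))
  invisible(dir)
}

#' Read a study bundle written by [write_study()]
#'
#' @param dir directory written by [write_study()].
#' @return a `study_bundle`, structurally equal to the one written (count
#'   baselines, which are internal simulation state, are not serialized).
#' @export
read_study <- function(dir) {
  fp <- function(f) file.path(dir, f)
  sizes <- read_chrom_sizes(fp("chrom.sizes"))
  exc <- if (file.size(fp("excluded.bed")) > 0)
    read_bed(fp("excluded.bed")) else NULL
  genome <- genome_spec(sizes, excluded = exc)
  genes <- read_genes_bed12(fp("genes.bed"))
  atac <- read_bed(fp("atac_peaks.bed"), genome = genome)
  g4 <- read_bed(fp("g4_peaks.bed"), genome = genome)
  hits <- if (file.size(fp("g4seq_hits.bed")) > 0)
    read_bed(fp("g4seq_hits.bed"), genome = genome)
  else GenomicRanges::GRanges(seqinfo = genome_seqinfo(sizes))
  segments <- read_cnv_segments(fp("cnv_segments.tsv"), genome = genome)
  counts <- list(); truth <- list()
  for (mod in c("atac", "g4", "rna")) {
    tab <- utils::read.table(fp(sprintf("counts_%s.tsv", mod)), sep = "\t",
                             header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$feature_id
    storage.mode(m) <- "integer"
    des <- utils::read.table(fp(sprintf("design_%s.tsv", mod)), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
    counts[[mod]] <- list(
      counts = m,
      condition = factor(des$condition, levels = c("control", "case")),
      size_factors = des$size_factor)
    tt <- utils::read.table(fp(sprintf("truth_%s.tsv", mod)), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
    tt$true_status <- factor(tt$true_status, levels = c("up", "down", "nd"))
    truth[[mod]] <- tt
  }
  truth <- c(truth, yaml::read_yaml(fp("truth_scalars.yaml")))
  cfg <- yaml::read_yaml(fp("config.yaml"))
  cfg$cnv <- as.data.frame(cfg$cnv)
  cfg$frac_differential <- unlist(cfg$frac_differential)
  cfg$seed <- as.numeric(cfg$seed)
  config <- do.call(sim_config, cfg)
  # truth tables carry metadata that lives on the peak GRanges in memory
  g4$true_strand <- truth$g4$true_strand[match(g4$name,
                                               truth$g4$feature_id)]
  g4$planted_promoter <- truth$g4$planted_promoter[match(
    g4$name, truth$g4$feature_id)]
  g4$gene_id <- truth$g4$gene_id[match(g4$name, truth$g4$feature_id)]
  g4$atac_id <- truth$g4$atac_id[match(g4$name, truth$g4$feature_id)]
  structure(list(genome = genome, genes = genes, atac_peaks = atac,
                 g4_peaks = g4, g4seq_hits = hits,
                 cnv_segments = segments, counts = counts, truth = truth,
                 config = config),
            class = "study_bundle")
}
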