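# Permutation / resampling enrichment of one interval set within another:
# observed overlap vs a randomized null, summarized as z, empirical p and
# fold enrichment (observed / expected).

#' Count overlaps between two interval sets
#'
#' Two counting modes: `"subject"` (default) counts the number of subject
#' elements overlapped by at least one query element -- the natural reading
#' of "number of overlaps with TSSs" -- while `"pair"` counts overlapping
#' (query, subject) pairs. Strand is ignored.
#'
#' @param query,subject `GRanges`.
#' @param mode `"subject"` or `"pair"`.
#' @param min_overlap minimum intersection length in bp.
#' @return integer count.
#' @export
count_set_overlaps <- function(query, subject, mode = c("subject", "pair"),
                               min_overlap = 1) {
  mode <- match.arg(mode)
  if (mode == "subject") {
    sum(GenomicRanges::countOverlaps(subject, query, ignore.strand = TRUE,
                                     minoverlap = as.integer(min_overlap)) > 0)
  } else {
    length(GenomicRanges::findOverlaps(query, subject, ignore.strand = TRUE,
                                       minoverlap = as.integer(min_overlap)))
  }
}

#' Enrichment statistics from an observed overlap and a null
#'
#' Pure statistic computation: `z = (observed - null_mean)/null_sd`,
#' `fold = observed / null_mean`, a one-sided normal p, and -- when raw
#' null draws are supplied -- the add-one empirical p
#' `(1 + #(null >= observed)) / (1 + n_perm)` (mirrored for depletion),
#' which can never be exactly zero. Fold is reported unrounded; round only
#' at presentation.
#'
#' @param observed observed overlap count.
#' @param null_mean,null_sd,n_perm null summary (used when `null_draws` is
#'   `NULL`).
#' @param null_draws optional numeric vector of null overlap counts.
#' @param alternative `"enrichment"` (default) or `"depletion"`.
#' @return object of class `enrichment_result`: a list with `observed`,
#'   `null_mean`, `null_sd`, `n_perm`, `z`, `p_norm`, `p_empirical`,
#'   `fold`, `alternative`.
#' @examples
#' # from a published permutation summary:
#' r <- enrichment_stats(38514, null_mean = 8290, null_sd = 108.8)
#' round(r$fold, 2)  # 4.65
#' round(r$z, 2)     # 277.79
#' @export
enrichment_stats <- function(observed, null_mean = NULL, null_sd = NULL,
                             n_perm = NULL, null_draws = NULL,
                             alternative = c("enrichment", "depletion")) {
  alternative <- match.arg(alternative)
  p_emp <- NA_real_
  if (!is.null(null_draws)) {
    if (length(null_draws) < 2)
      stopf("need >= 2 null draws to estimate a null sd")
    n_perm <- length(null_draws)
    null_mean <- mean(null_draws)
    null_sd <- sd(null_draws)
    p_emp <- if (alternative == "enrichment")
      (1 + sum(null_draws >= observed)) / (1 + n_perm)
    else
      (1 + sum(null_draws <= observed)) / (1 + n_perm)
  }
  if (is.null(null_mean) || is.null(null_sd))
    stopf("supply either null_draws or (null_mean, null_sd)")
  if (null_sd > 0) {
    z <- (observed - null_mean) / null_sd
  } else {
    warnf("null sd is 0; z reported as +/-Inf")
    z <- sign(observed - null_mean) * Inf
  }
  fold <- if (null_mean > 0) observed / null_mean else NaN
  p_norm <- if (alternative == "enrichment") pnorm(z, lower.tail = FALSE)
            else pnorm(z, lower.tail = TRUE)
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = null_sd, n_perm = n_perm, z = z,
                 p_norm = p_norm, p_empirical = p_emp, fold = fold,
                 alternative = alternative),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result (%s): observed %s; expected %.4g +/- %.4g (n = %s)\n",
    x$alternative, format(x$observed), x$null_mean, x$null_sd,
    format(x$n_perm)))
  cat(sprintf("  fold = %.4g, z = %.4g, p_norm = %.3g, p_empirical = %s\n",
              x$fold, x$z, x$p_norm, format.pval(x$p_empirical)))
  invisible(x)
}

#' Permutation or resampling enrichment test
#'
#' Compares the observed overlap of `query` with `subject` against a null
#' built by randomizing `query` `n_perm` times: either relocating it across
#' the genome ([shuffle_intervals()]; the classic shuffle null) or drawing
#' same-size subsets of a `universe` ([resample_within_universe()]; for
#' constrained feature spaces such as "TSSs of differential genes within
#' TSSs of expressed genes").
#'
#' @param query,subject `GRanges`.
#' @param genome [genome_spec()], required for the shuffle null.
#' @param excluded optional `GRanges` overriding `genome$excluded`.
#' @param n_perm number of permutations (default 1000).
#' @param null `"shuffle"` or `"resample"`.
#' @param universe `GRanges`, required for the resample null; must contain
#'   at least `length(query)` elements.
#' @param mode overlap counting mode, see [count_set_overlaps()].
#' @param min_overlap minimum intersection length in bp.
#' @param same_chrom for the shuffle null, keep intervals on their own
#'   chromosome (default `TRUE`).
#' @param alternative `"enrichment"` (default) or `"depletion"`.
#' @param seed optional integer for reproducibility.
#' @return an `enrichment_result`, see [enrichment_stats()].
#' @export
permutation_enrichment <- function(query, subject, genome = NULL,
                                   excluded = NULL, n_perm = 1000,
                                   null = c("shuffle", "resample"),
                                   universe = NULL,
                                   mode = c("subject", "pair"),
                                   min_overlap = 1, same_chrom = TRUE,
                                   alternative = c("enrichment", "depletion"),
                                   seed = NULL) {
  null <- match.arg(null)
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (n_perm < 1) stopf("n_perm must be >= 1")
  if (null == "shuffle" && is.null(genome))
    stopf("the shuffle null requires a genome")
  if (null == "resample") {
    if (is.null(universe)) stopf("the resample null requires a universe")
    if (length(query) > length(universe))
      stopf("query larger than universe")
  }
  observed <- count_set_overlaps(query, subject, mode = mode,
                                 min_overlap = min_overlap)
  if (null == "shuffle" && is.null(excluded)) excluded <- genome$excluded
  state <- fast_null_state(query, subject, genome, excluded, mode,
                           min_overlap, null, universe, same_chrom)
  draws <- with_seed_maybe(seed, {
    if (!is.null(state)) {
      vapply(seq_len(n_perm), function(i) state$draw(), numeric(1))
    } else {
      vapply(seq_len(n_perm), function(i) {
        rand <- if (null == "shuffle")
          shuffle_intervals(query, genome, excluded = excluded,
                            same_chrom = same_chrom)
        else
          resample_within_universe(query, universe)
        count_set_overlaps(rand, subject, mode = mode,
                           min_overlap = min_overlap)
      }, numeric(1))
    }
  })
  enrichment_stats(observed, null_draws = draws, alternative = alternative)
}
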