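# Cross-contrast concordance of differential calls: signed quadrant tables
# (e.g. disease contrast vs drug-treatment contrast), hypergeometric
# enrichment/depletion of each quadrant, and direction-stratified fractions.

#' Signed quadrant table for two differential contrasts
#'
#' Features are matched by id; the universe N is the set of features tested
#' (non-`NA` p) in both contrasts. Every feature differential in both is
#' placed in exactly one signed quadrant (`++`, `--`, `+-`, `-+`, where the
#' first sign is contrast A), and quadrant fractions are reported over that
#' doubly-differential set.
#'
#' @param results_a,results_b data frames from [classify_differential()]
#'   (need `feature_id`, `p`, `status`).
#' @return object of class `quadrant_table`: list with `N`, `K_up`,
#'   `K_down` (contrast A margins), `n_up`, `n_down` (contrast B margins),
#'   `counts` (named vector `++`, `--`, `+-`, `-+`), `fractions`,
#'   `n_both_diff`.
#' @export
quadrant_counts <- function(results_a, results_b) {
  ta <- results_a[!is.na(results_a$p), ]
  tb <- results_b[!is.na(results_b$p), ]
  shared <- intersect(ta$feature_id, tb$feature_id)
  orphans <- c(setdiff(ta$feature_id, tb$feature_id),
               setdiff(tb$feature_id, ta$feature_id))
  if (!length(shared))
    stopf("no shared tested features between contrasts (e.g. %s)",
          paste(utils::head(orphans, 5), collapse = ", "))
  if (length(orphans))
    warnf("%d feature(s) tested in only one contrast dropped (e.g. %s)",
          length(orphans), paste(utils::head(orphans, 3), collapse = ", "))
  sa <- ta$status[match(shared, ta$feature_id)]
  sb <- tb$status[match(shared, tb$feature_id)]
  counts <- c(`++` = sum(sa == "up" & sb == "up"),
              `--` = sum(sa == "down" & sb == "down"),
              `+-` = sum(sa == "up" & sb == "down"),
              `-+` = sum(sa == "down" & sb == "up"))
  n_both <- sum(counts)
  structure(list(N = length(shared),
                 K_up = sum(sa == "up"), K_down = sum(sa == "down"),
                 n_up = sum(sb == "up"), n_down = sum(sb == "down"),
                 counts = counts,
                 fractions = if (n_both > 0) counts / n_both else counts * NA,
                 n_both_diff = n_both),
            class = "quadrant_table")
}

#' @export
print.quadrant_table <- function(x, ...) {
  cat(sprintf("quadrant_table: N = %d shared tested features; %d differential in both\n",
              x$N, x$n_both_diff))
  tab <- data.frame(quadrant = names(x$counts), count = as.integer(x$counts),
                    fraction = round(x$fractions, 4))
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Hypergeometric tests on a signed quadrant table
#'
#' For each quadrant, the observed count k is compared with drawing n
#' (the matching contrast-B margin) features from a population of N with K
#' successes (the matching contrast-A margin): expected `n*K/N`, fold
#' `k/expected`, and both tail probabilities (`p_upper` for enrichment,
#' `p_lower` for depletion, computed with the hypergeometric distribution
#' as `phyper` does). Same-sign quadrants are typically tested for
#' enrichment and opposite-sign quadrants for depletion.
#'
#' @param table a [quadrant_counts()] result.
#' @param population `"tested"` (default; N = shared tested features) or
#'   `"both_diff"` (N = features differential in both contrasts).
#' @return data frame with one row per quadrant: `quadrant`, `k`, `K`, `n`,
#'   `N`, `expected`, `fold`, `p_upper`, `p_lower`.
#' @export
hypergeom_tests <- function(table, population = c("tested", "both_diff")) {
  population <- match.arg(population)
  N <- if (population == "tested") table$N else table$n_both_diff
  quadrants <- names(table$counts)
  K <- c(`++` = table$K_up, `--` = table$K_down,
         `+-` = table$K_up, `-+` = table$K_down)
  n <- c(`++` = table$n_up, `--` = table$n_down,
         `+-` = table$n_down, `-+` = table$n_up)
  out <- lapply(quadrants, function(q) {
    k <- table$counts[[q]]
    expected <- n[[q]] * K[[q]] / N
    fold <- if (expected > 0) k / expected else NaN
    data.frame(quadrant = q, k = k, K = K[[q]], n = n[[q]], N = N,
               expected = expected, fold = fold,
               p_upper = phyper(k - 1, K[[q]], N - K[[q]], n[[q]],
                                lower.tail = FALSE),
               p_lower = phyper(k, K[[q]], N - K[[q]], n[[q]],
                                lower.tail = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Direction-stratified fractions of one contrast within another
#'
#' For features differential in the stratifying contrast (by sign), the
#' distribution of the other contrast's statuses. Answers questions like
#' "what fraction of regions losing G4 signal also lose accessibility?".
#'
#' @param results_a,results_b data frames from [classify_differential()].
#' @param stratify_by `"a"` (default) or `"b"`: which contrast defines the
#'   strata.
#' @return data frame with rows `up` and `down` (strata) and columns `up`,
#'   `down`, `nd` (fractions of the other contrast; rows sum to 1), plus
#'   `n` per stratum.
#' @export
direction_fractions <- function(results_a, results_b,
                                stratify_by = c("a", "b")) {
  stratify_by <- match.arg(stratify_by)
  if (stratify_by == "b") { tmp <- results_a; results_a <- results_b
                            results_b <- tmp }
  ta <- results_a[!is.na(results_a$p), ]
  tb <- results_b[!is.na(results_b$p), ]
  shared <- intersect(ta$feature_id, tb$feature_id)
  sa <- ta$status[match(shared, ta$feature_id)]
  sb <- tb$status[match(shared, tb$feature_id)]
  out <- do.call(rbind, lapply(c("up", "down"), function(dir) {
    sel <- sa == dir
    n <- sum(sel)
    fr <- if (n > 0) c(mean(sb[sel] == "up"), mean(sb[sel] == "down"),
                       mean(sb[sel] == "nd")) else rep(NA_real_, 3)
    data.frame(stratum = dir, up = fr[1], down = fr[2], nd = fr[3], n = n,
               stringsAsFactors = FALSE)
  }))
  out
}
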