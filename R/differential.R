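# Simplified count-based differential stage. This is a deliberately small
# stand-in for DESeq2/edgeR-style testing: median-of-ratios (or loess
# trended) normalization, method-of-moments dispersion, a per-feature
# negative-binomial Wald test with a normal reference, BH adjustment and
# up/down/nd status calls. It makes no claim of numeric parity with those
# packages; its contract is recovery of planted truth in simulation.

#' Median-of-ratios size factors
#'
#' `factor_j = median_i(count_ij / geometric_mean_i)` over features with
#' all-positive counts, the classical count-normalization scheme for
#' sequencing depth.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @return numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  ok <- is.finite(loggeo)
  if (!any(ok)) stopf("no feature has all-positive counts")
  geo <- exp(loggeo[ok])
  sf <- apply(counts[ok, , drop = FALSE], 2, function(col)
    median(col / geo))
  if (any(!is.finite(sf) | sf <= 0)) stopf("degenerate size factors")
  sf
}

#' Loess-trended normalization offsets
#'
#' Fits, per sample, a loess trend of M (log2 sample/reference ratio)
#' against A (mean log2 abundance) and returns the fitted trend as a
#' natural-log offset matrix for the NB model. With no M-A trend the
#' offsets reduce (up to a constant) to log size factors; with a trend they
#' remove it, the remedy for contrasts whose MA plot is skewed.
#'
#' @param counts non-negative integer matrix with >= 100 features.
#' @param span loess span (default 0.5).
#' @return numeric matrix of natural-log offsets, same shape as `counts`.
#' @export
loess_offset_normalize <- function(counts, span = 0.5) {
  if (nrow(counts) < 100)
    stopf("need >= 100 features for a stable loess trend")
  l2 <- log2(counts + 0.5)
  a <- rowMeans(l2)
  if (diff(range(a)) < 1e-8) {
    warnf("degenerate A range; falling back to size factors")
    sf <- size_factors(counts)
    return(matrix(log(sf), nrow(counts), ncol(counts), byrow = TRUE,
                  dimnames = dimnames(counts)))
  }
  off <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (j in seq_len(ncol(counts))) {
    m <- l2[, j] - a
    fit <- limma::loessFit(m, a, span = span)
    off[, j] <- fit$fitted * log(2)
  }
  off
}

#' Method-of-moments dispersion estimates
#'
#' Per feature, within each condition, `alpha_k = (var_k - mean_k) /
#' mean_k^2` on size-factor-normalized counts; estimates are pooled across
#' conditions by degrees of freedom, truncated at zero and floored at
#' `floor`. With `shrink = TRUE` (the default) the per-feature estimate is
#' moderated toward a mean-dispersion trend with weight
#' `df / (df + shrink_strength)` on the per-feature value. The trend is a
#' ratio-of-sums over mean-ordered feature bins
#' (`sum(s^2 - m) / sum(m^2)` per bin, interpolated on log mean): unlike
#' an average of per-feature ratios it is nearly unbiased at small
#' replicate numbers, which keeps the downstream Wald test close to its
#' nominal size.
#'
#' @param counts non-negative integer matrix.
#' @param sf per-sample size factors.
#' @param condition two-level factor per sample.
#' @param floor lower bound for the returned dispersions.
#' @param shrink moderate per-feature estimates toward the mean-dispersion
#'   trend.
#' @param shrink_strength prior degrees of freedom for the trend
#'   (default 20).
#' @return numeric vector of per-feature dispersions.
#' @export
estimate_dispersion <- function(counts, sf, condition, floor = 1e-8,
                                shrink = TRUE, shrink_strength = 20) {
  condition <- check_condition(condition, ncol(counts))
  y <- sweep(counts, 2, sf, "/")
  num <- den <- 0
  for (lev in levels(condition)) {
    yk <- y[, condition == lev, drop = FALSE]
    nk <- ncol(yk)
    mk <- rowMeans(yk)
    vk <- apply(yk, 1, var)
    num <- num + (nk - 1) * (vk - mk)
    den <- den + (nk - 1) * mk^2
  }
  alpha <- ifelse(den > 0, num / den, 0)
  if (shrink) {
    mu <- rowMeans(y)
    ok <- mu > 0 & is.finite(alpha) & den > 0
    if (sum(ok) >= 50) {
      oki <- which(ok)
      ord <- oki[order(mu[oki])]
      n_bins <- max(1L, min(20L, floor(length(ord) / 50)))
      bin <- if (n_bins == 1) rep(1L, length(ord))
             else cut(seq_along(ord), n_bins, labels = FALSE)
      bin_alpha <- vapply(seq_len(n_bins), function(b) {
        i <- ord[bin == b]
        max(sum(num[i]) / sum(den[i]), 0)
      }, numeric(1))
      bin_logmu <- vapply(seq_len(n_bins), function(b)
        mean(log(mu[ord[bin == b]])), numeric(1))
      trend <- if (n_bins == 1) rep(bin_alpha, length(oki)) else
        stats::approx(bin_logmu, bin_alpha, xout = log(mu[oki]),
                      rule = 2)$y
      df <- ncol(counts) - 2L
      w <- df / (df + shrink_strength)
      alpha[oki] <- w * pmax(alpha[oki], 0) +
        (1 - w) * pmax(trend, floor)
    }
  }
  pmax(alpha, floor)
}

#' Per-feature negative-binomial Wald test
#'
#' Fits, per feature, the NB log-link model
#' `mu_ij = exp(offset_ij + b0 + b1 * case_j)` with fixed dispersion
#' (variance `mu + alpha mu^2`) by iteratively reweighted least squares,
#' and tests `b1 = 0` with the Wald statistic against a standard normal.
#' `log2fc = b1 / ln 2`. Features with all-zero counts, or whose fit does
#' not converge, are returned with `p = NA` and excluded from downstream
#' BH adjustment.
#'
#' @param counts non-negative integer matrix with row names (feature ids).
#' @param condition two-level factor per sample; the second level is the
#'   case condition.
#' @param sf per-sample size factors (used when `offsets` is `NULL`).
#' @param offsets optional natural-log offset matrix (e.g. from
#'   [loess_offset_normalize()]), overriding `sf`.
#' @param dispersions per-feature dispersions; default estimated with
#'   [estimate_dispersion()].
#' @param max_iter,tol IRLS controls.
#' @return data frame with columns `feature_id`, `baseMean`, `log2fc`,
#'   `se`, `p`, `converged`.
#' @export
nb_wald_test <- function(counts, condition, sf = NULL, offsets = NULL,
                         dispersions = NULL, max_iter = 50, tol = 1e-8) {
  condition <- check_condition(condition, ncol(counts))
  n <- nrow(counts)
  if (is.null(offsets)) {
    if (is.null(sf)) sf <- size_factors(counts)
    offsets <- matrix(log(sf), n, ncol(counts), byrow = TRUE)
  }
  if (is.null(dispersions)) {
    if (is.null(sf)) sf <- exp(colMeans(offsets))
    dispersions <- estimate_dispersion(counts, sf, condition)
  }
  if (any(dispersions < 0)) stopf("dispersions must be >= 0")
  is_case <- condition == levels(condition)[2]
  y <- as.matrix(counts)
  o <- offsets
  alpha <- dispersions
  base_mean <- rowMeans(sweep(y, 2, exp(colMeans(o)), "/"))

  testable <- rowSums(y) > 0
  b0 <- b1 <- rep(NA_real_, n)
  conv <- rep(FALSE, n)
  idx <- which(testable)
  if (length(idx)) {
    # initialize from group means of offset-corrected counts
    yn <- y[idx, , drop = FALSE] / exp(o[idx, , drop = FALSE])
    m_ctrl <- rowMeans(yn[, !is_case, drop = FALSE])
    m_case <- rowMeans(yn[, is_case, drop = FALSE])
    b0c <- log(pmax(m_ctrl, 1e-8))
    b1c <- log(pmax(m_case, 1e-8)) - b0c
    active <- rep(TRUE, length(idx))
    for (it in seq_len(max_iter)) {
      if (!any(active)) break
      eta <- o[idx, , drop = FALSE] + b0c +
        outer(b1c, as.numeric(is_case))
      mu <- exp(eta)
      w <- mu / (1 + alpha[idx] * mu)
      z <- (eta - o[idx, , drop = FALSE]) +
        (y[idx, , drop = FALSE] - mu) / mu
      sw_ctrl <- rowSums(w[, !is_case, drop = FALSE])
      sw_case <- rowSums(w[, is_case, drop = FALSE])
      swz_ctrl <- rowSums((w * z)[, !is_case, drop = FALSE])
      swz_case <- rowSums((w * z)[, is_case, drop = FALSE])
      nb0 <- swz_ctrl / sw_ctrl
      nb1 <- swz_case / sw_case - nb0
      nb1 <- pmin(pmax(nb1, -30), 30)
      step <- pmax(abs(nb0 - b0c), abs(nb1 - b1c))
      done <- active & is.finite(step) & step < tol
      conv[idx[done]] <- TRUE
      active <- active & !done & is.finite(step)
      b0c <- ifelse(is.finite(nb0), nb0, b0c)
      b1c <- ifelse(is.finite(nb1), nb1, b1c)
    }
    b0[idx] <- b0c; b1[idx] <- b1c
  }
  # Wald se from expected information at the fit
  se <- rep(NA_real_, n)
  ok <- which(conv)
  if (length(ok)) {
    eta <- o[ok, , drop = FALSE] + b0[ok] + outer(b1[ok], as.numeric(is_case))
    mu <- exp(eta)
    w <- mu / (1 + alpha[ok] * mu)
    se[ok] <- sqrt(1 / rowSums(w[, is_case, drop = FALSE]) +
                     1 / rowSums(w[, !is_case, drop = FALSE]))
  }
  p <- ifelse(conv & is.finite(se) & se > 0,
              2 * pnorm(abs(b1 / se), lower.tail = FALSE), NA_real_)
  ids <- rownames(counts)
  if (is.null(ids)) ids <- paste0("f", seq_len(n))
  data.frame(feature_id = ids, baseMean = base_mean,
             log2fc = b1 / log(2), se = se / log(2), p = p,
             converged = conv, stringsAsFactors = FALSE)
}

#' BH adjustment and differential status calls
#'
#' Benjamini-Hochberg adjustment over the tested features (those with a
#' non-`NA` p-value), then status classification: `up` if `p_adj < alpha`
#' and `log2fc > 0`, `down` if `p_adj < alpha` and `log2fc < 0`, otherwise
#' `nd`.
#'
#' @param results data frame from [nb_wald_test()] (needs `p`, `log2fc`).
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return the input with added `p_adj` and `status` columns; `status` is a
#'   factor with levels `up`, `down`, `nd`.
#' @export
classify_differential <- function(results, alpha = 0.05) {
  if (!nrow(results)) {
    results$p_adj <- numeric(0)
    results$status <- factor(character(0), levels = c("up", "down", "nd"))
    return(results)
  }
  p_adj <- rep(NA_real_, nrow(results))
  tested <- !is.na(results$p)
  p_adj[tested] <- p.adjust(results$p[tested], method = "BH")
  status <- rep("nd", nrow(results))
  status[tested & p_adj < alpha & results$log2fc > 0] <- "up"
  status[tested & p_adj < alpha & results$log2fc < 0] <- "down"
  results$p_adj <- p_adj
  results$status <- factor(status, levels = c("up", "down", "nd"))
  results
}

#' One-call differential analysis of a count matrix
#'
#' Convenience wrapper chaining normalization ([size_factors()] or
#' [loess_offset_normalize()]), dispersion estimation, the NB Wald test and
#' [classify_differential()].
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param condition two-level factor per sample (second level = case).
#' @param normalization `"mor"` (median-of-ratios, default) or `"loess"`.
#' @param alpha significance threshold (default 0.05).
#' @param dispersions optional per-feature dispersions.
#' @return data frame with columns `feature_id`, `baseMean`, `log2fc`,
#'   `se`, `p`, `p_adj`, `status`.
#' @export
diff_test <- function(counts, condition, normalization = c("mor", "loess"),
                      alpha = 0.05, dispersions = NULL) {
  normalization <- match.arg(normalization)
  if (normalization == "mor") {
    res <- nb_wald_test(counts, condition, sf = size_factors(counts),
                        dispersions = dispersions)
  } else {
    off <- loess_offset_normalize(counts)
    res <- nb_wald_test(counts, condition, offsets = off,
                        dispersions = dispersions)
  }
  classify_differential(res, alpha = alpha)
}
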