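## Screen-level count statistics: low-count filtering, median-of-ratios
## normalization with a per-sgRNA geometric-mean reference, and the
## sgRNA-level negative-binomial differential-abundance test whose
## mean-variance trend is fitted on the non-targeting (NT) controls.

#' Remove sgRNAs undercovered in any tissue
#'
#' An sgRNA is discarded from all samples when, in at least one tissue,
#' more than `max_low_replicates` replicates have fewer than `threshold`
#' raw counts. Both inequalities are strict, so e.g. counts of
#' (50, 0, 0) across three replicates survive the default rule (two lows,
#' and 50 is not below 50) while (49, 49, 49) does not.
#'
#' @param counts Integer matrix (sgRNA x sample).
#' @param meta Sample metadata (`sample_id`, `tissue`, `replicate`).
#' @param threshold Counts below this are "low" (default 50).
#' @param max_low_replicates Tolerated low replicates per tissue (default 2).
#' @return List with `counts` (filtered matrix) and `dropped` (sgrna ids).
#' @export
filter_low_counts <- function(counts, meta, threshold = 50L, max_low_replicates = 2L) {
  if (is.null(meta)) stop_config("filter_low_counts requires sample metadata")
  if (!all(colnames(counts) %in% meta$sample_id)) {
    stop_config("every count column must appear in the sample metadata")
  }
  tissue_of <- setNames(meta$tissue, meta$sample_id)[colnames(counts)]
  low <- counts < threshold
  drop <- rep(FALSE, nrow(counts))
  for (tis in unique(tissue_of)) {
    n_low <- rowSums(low[, tissue_of == tis, drop = FALSE])
    drop <- drop | (n_low > max_low_replicates)
  }
  list(counts = counts[!drop, , drop = FALSE], dropped = rownames(counts)[drop])
}

#' Median-of-ratios size factors with a geometric-mean reference
#'
#' For each reference sgRNA i the pseudo-reference is the geometric mean of
#' its counts across samples, `g_i`; the size factor of sample j is the
#' median over reference sgRNAs of `c_ij / g_i`. The reference set is
#' restricted to sgRNAs whose counts are at least `min_count` in every
#' sample (and, with `reference = "nt"`, to NT guides), so normalization is
#' driven by well-measured guides.
#'
#' @param counts Integer matrix (sgRNA x sample).
#' @param reference `"all"` or `"nt"`.
#' @param nt_ids NT sgRNA ids (required for `reference = "nt"`).
#' @param min_count Minimum count in every sample for a reference sgRNA.
#' @return Named positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts, reference = c("all", "nt"), nt_ids = NULL,
                         min_count = 50L) {
  reference <- match.arg(reference)
  keep <- rowSums(counts >= min_count) == ncol(counts)
  if (reference == "nt") {
    if (is.null(nt_ids)) stop_config("reference = 'nt' requires nt_ids")
    keep <- keep & rownames(counts) %in% nt_ids
  }
  if (!any(keep)) {
    stop_normalization(
      "no reference sgRNA has all counts >= min_count; lower min_count")
  }
  ref <- counts[keep, , drop = FALSE]
  g <- exp(rowMeans(log(ref)))
  sf <- apply(ref / g, 2L, stats::median)
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop_normalization("non-positive size factor; reference set degenerate")
  }
  # anchor the factors at median 1 so rescaling one sample by lambda scales
  # its factor by lambda and leaves every normalized count unchanged
  sf / stats::median(sf)
}

#' Normalize counts by size factors
#' @param counts Count matrix.
#' @param sf Size factors from [size_factors()].
#' @return Matrix of normalized counts (`c_ij / s_j`).
#' @export
normalize_counts <- function(counts, sf) {
  sweep(counts, 2L, sf, "/")
}

## Mean-variance trend on log-log scale from per-guide replicate means and
## variances, with the chi-square bias of log(sample variance) removed so
## the fitted curve targets log of the true variance.
fit_var_trend <- function(means, vars, n_rep) {
  ok <- is.finite(means) & is.finite(vars) & means > 0 & vars > 0
  if (sum(ok) < 10L) return(NULL)
  bias <- if (n_rep >= 2L) digamma((n_rep - 1) / 2) + log(2 / (n_rep - 1)) else 0
  fit <- stats::lm.fit(cbind(1, log(means[ok])), log(vars[ok]) - bias)
  coefs <- fit$coefficients
  function(mu) exp(coefs[1L] + coefs[2L] * log(pmax(mu, 1e-8)))
}

#' sgRNA-level differential abundance between two tissue groups
#'
#' For the comparison "B versus A" (e.g. meninges versus blood) each
#' sgRNA's fold change is `lfc = log2((meanB + pc) / (meanA + pc))` on
#' normalized counts. The null distribution of the group-B mean is modeled
#' as negative binomial with mean `meanA` and variance
#' `v_A(meanA)/n_A + v_B(meanA)/n_B`, where each group's variance function
#' is a log-log least-squares trend fitted on the NT control guides
#' (falling back to all guides when fewer than 30 NT guides are scored).
#' One-sided tail probabilities give `p_low` (depletion in B) and `p_high`
#' (enrichment); rank percentiles are mid-ranks of the one-sided p-values
#' divided by the number of scored sgRNAs.
#'
#' @param norm_counts Normalized count matrix.
#' @param group_a,group_b Sample ids of the reference and test groups.
#' @param nt_ids NT sgRNA ids used for the variance trend.
#' @param pseudocount Added to means before the log-ratio (default 1).
#' @return `data.frame` of class `sgrna_stats`: `sgrna_id`, `mean_a`,
#'   `mean_b`, `lfc`, `p_low`, `p_high`, `rank_low`, `rank_high`,
#'   `flagged` (all-zero group).
#' @export
sgrna_test <- function(norm_counts, group_a, group_b, nt_ids = character(0),
                       pseudocount = 1) {
  if (length(group_a) < 1L || length(group_b) < 1L) {
    stop_config("each group needs at least one sample")
  }
  missing <- setdiff(c(group_a, group_b), colnames(norm_counts))
  if (length(missing)) stop_config(paste("unknown sample id:", missing[1L]))

  A <- norm_counts[, group_a, drop = FALSE]
  B <- norm_counts[, group_b, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  lfc <- log2((mB + pseudocount) / (mA + pseudocount))

  is_nt <- rownames(norm_counts) %in% nt_ids
  trend_rows <- if (sum(is_nt) >= 30L) is_nt else rep(TRUE, nrow(norm_counts))
  vA_fun <- if (nA >= 2L)
    fit_var_trend(mA[trend_rows], apply(A[trend_rows, , drop = FALSE], 1L, stats::var), nA)
  else NULL
  vB_fun <- if (nB >= 2L)
    fit_var_trend(mB[trend_rows], apply(B[trend_rows, , drop = FALSE], 1L, stats::var), nB)
  else NULL
  # single-replicate groups (or degenerate fits) fall back to Poisson-like
  # variance at the reference mean
  var_at <- function(fun, mu) if (is.null(fun)) mu else pmax(fun(mu), mu)

  # an all-zero group carries no usable information for this test
  flagged <- rowSums(A) == 0 | rowSums(B) == 0
  mu0 <- pmax(mA, 1e-8)
  v_tot <- var_at(vA_fun, mu0) / nA + var_at(vB_fun, mu0) / nB

  size <- ifelse(v_tot > mu0 * (1 + 1e-8), mu0^2 / (v_tot - mu0), 1e9)
  p_low <- stats::pnbinom(floor(mB), size = size, mu = mu0)
  p_high <- stats::pnbinom(ceiling(mB) - 1, size = size, mu = mu0,
                           lower.tail = FALSE)
  p_low[flagged] <- 1; p_high[flagged] <- 1
  p_low <- pmin(pmax(p_low, .Machine$double.xmin), 1)
  p_high <- pmin(pmax(p_high, .Machine$double.xmin), 1)

  n <- length(p_low)
  out <- data.frame(
    sgrna_id = rownames(norm_counts),
    mean_a = mA, mean_b = mB, lfc = lfc,
    p_low = p_low, p_high = p_high,
    rank_low = rank(p_low, ties.method = "average") / n,
    rank_high = rank(p_high, ties.method = "average") / n,
    flagged = flagged,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("sgrna_stats", "data.frame")
  out
}
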