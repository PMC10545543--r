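## Gene-level aggregation by alpha-robust rank aggregation (alpha-RRA) with
## a permutation null, and the non-targeting pseudo-gene resampling null
## used by the essentiality threshold.

## Core alpha-RRA score for one set of member rank percentiles.
## With sorted percentiles r_(1) <= ... <= r_(n), beta_k = Pr[Binomial(n,
## r_(k)) >= k]; the score is the minimum beta_k over the informative
## positions (members whose directional p-value passes alpha); 1 if none.
rra_rho <- function(percentiles, informative) {
  n <- length(percentiles)
  m <- sum(informative)
  if (m == 0L) return(1)
  r <- sort(percentiles)
  k <- seq_len(m)
  beta <- stats::pbinom(k - 1L, n, r[k], lower.tail = FALSE)
  min(beta)
}

## Vectorized null-rho draws: `n_draws` random same-size member sets drawn
## without replacement from the scored sgRNA pool. Returns a numeric vector.
rra_null_rho <- function(perc_pool, inform_pool, n, n_draws) {
  total <- n * n_draws
  idx <- matrix(sample.int(length(perc_pool), total, replace = TRUE), nrow = n)
  r <- matrix(perc_pool[idx], nrow = n)
  inf <- matrix(inform_pool[idx], nrow = n)
  m <- colSums(inf)
  # column-wise ascending sort of an n x C matrix
  o <- order(col(r), r)
  rs <- matrix(r[o], nrow = n)
  rho <- rep(Inf, n_draws)
  for (k in seq_len(n)) {
    beta_k <- stats::pbinom(k - 1L, n, rs[k, ], lower.tail = FALSE)
    beta_k[m < k] <- Inf  # position k beyond the informative prefix
    rho <- pmin(rho, beta_k)
  }
  rho[!is.finite(rho)] <- 1
  rho
}

#' Aggregate sgRNA statistics to gene level by alpha-RRA
#'
#' For each target, member sgRNAs with directional p-value at most `alpha`
#' are "informative" (`goodsgrna` counts them); the gene score rho is the
#' minimum binomial-tail probability over the informative prefix of the
#' sorted member rank percentiles. The gene p-value compares rho against
#' `n_perm` random same-size sgRNA sets drawn from the scored pool
#' (independently per gene): `p = (1 + #{rho' <= rho}) / (n_perm + 1)`.
#' The gene log2 fold change is the median (or mean) of member sgRNA lfcs.
#'
#' @param stats An `sgrna_stats` table from [sgrna_test()].
#' @param manifest `library_manifest` mapping sgRNAs to targets; NT guides
#'   contribute to the ranking pool but are not scored as genes.
#' @param direction `"neg"` (depletion, uses `p_low`/`rank_low`) or
#'   `"pos"` (enrichment).
#' @param alpha Significance cutoff defining informative sgRNAs
#'   (default 0.25).
#' @param n_perm Random sets per gene (default 1000); the p-value floor is
#'   `1/(n_perm+1)`.
#' @param seed Integer seed for the permutation draws.
#' @param gene_lfc `"median"` (default) or `"mean"` member-lfc summary.
#' @return Data frame: `target_id`, `n_sgrna`, `score`, `p`, `lfc`,
#'   `goodsgrna` for the requested direction.
#' @export
rra_aggregate <- function(stats, manifest, direction = c("neg", "pos"),
                          alpha = 0.25, n_perm = 1000L, seed = 1L,
                          gene_lfc = c("median", "mean")) {
  direction <- match.arg(direction)
  gene_lfc <- match.arg(gene_lfc)
  p_dir <- if (direction == "neg") stats$p_low else stats$p_high
  perc <- if (direction == "neg") stats$rank_low else stats$rank_high

  map <- manifest[match(stats$sgrna_id, manifest$sgrna_id), ]
  if (anyNA(map$target_id)) {
    stop_config("every scored sgRNA must map to one manifest target")
  }
  scoreable <- map$target_type != "nt"
  targets <- unique(map$target_id[scoreable])
  informative <- p_dir <= alpha

  lfc_fun <- if (gene_lfc == "median") stats::median else mean
  idx_by_target <- split(which(scoreable), map$target_id[scoreable])
  idx_by_target <- idx_by_target[targets]

  n_sgrna <- lengths(idx_by_target)
  rho <- vapply(idx_by_target, function(ii) rra_rho(perc[ii], informative[ii]),
                numeric(1))
  good <- vapply(idx_by_target, function(ii) sum(informative[ii]), integer(1))
  glfc <- vapply(idx_by_target, function(ii) lfc_fun(stats$lfc[ii]), numeric(1))

  set.seed(derive_seed(seed, paste0("rra_", direction)))
  p_gene <- numeric(length(targets))
  for (n in sort(unique(n_sgrna))) {
    sel <- which(n_sgrna == n)
    # independent null draws per gene, generated in one block per size
    null_rho <- rra_null_rho(perc, informative, n, n_perm * length(sel))
    null_mat <- matrix(null_rho, nrow = n_perm)
    rho_rep <- rep(rho[sel], each = n_perm)
    lt <- colSums(null_mat < rho_rep)
    eq <- colSums(null_mat == rho_rep)
    # Tie-randomized Monte Carlo p-value: rho has an atom at 1 (genes with
    # no informative member), so ties with the null draws are broken
    # uniformly to keep the null p-value distribution uniform. The floor
    # 1/(n_perm+1) is preserved; continuous-scored genes are unaffected.
    k <- as.integer(floor(stats::runif(length(sel)) * (eq + 1)))
    k <- pmin(k, eq)
    p_gene[sel] <- (1 + lt + k) / (n_perm + 1)
  }

  data.frame(target_id = targets, n_sgrna = as.integer(n_sgrna),
             score = rho, p = p_gene, lfc = glfc,
             goodsgrna = as.integer(good),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-directional gene summary
#'
#' Runs [rra_aggregate()] in both directions and merges the results into a
#' screen-style gene summary with `neg_*` and `pos_*` columns.
#'
#' @inheritParams rra_aggregate
#' @return Data frame of class `gene_summary`: `target_id`, `n_sgrna`,
#'   `neg_score`, `neg_p`, `neg_lfc`, `neg_goodsgrna`, `pos_score`,
#'   `pos_p`, `pos_lfc`, `pos_goodsgrna`.
#' @export
gene_summary <- function(stats, manifest, alpha = 0.25, n_perm = 1000L,
                         seed = 1L, gene_lfc = c("median", "mean")) {
  gene_lfc <- match.arg(gene_lfc)
  neg <- rra_aggregate(stats, manifest, "neg", alpha, n_perm, seed, gene_lfc)
  pos <- rra_aggregate(stats, manifest, "pos", alpha, n_perm, seed, gene_lfc)
  stopifnot(identical(neg$target_id, pos$target_id))
  out <- data.frame(
    target_id = neg$target_id, n_sgrna = neg$n_sgrna,
    neg_score = neg$score, neg_p = neg$p, neg_lfc = neg$lfc,
    neg_goodsgrna = neg$goodsgrna,
    pos_score = pos$score, pos_p = pos$p, pos_lfc = pos$lfc,
    pos_goodsgrna = pos$goodsgrna,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_summary", "data.frame")
  out
}

#' Write / read a gene summary TSV with screen-conventional column names
#'
#' Columns: `id, num, neg|score, neg|p-value, neg|lfc, neg|goodsgrna,
#' pos|score, pos|p-value, pos|lfc, pos|goodsgrna`.
#' @param summary A `gene_summary`.
#' @param path File path.
#' @export
write_gene_summary <- function(summary, path) {
  out <- data.frame(
    id = summary$target_id, num = summary$n_sgrna,
    summary[c("neg_score", "neg_p", "neg_lfc", "neg_goodsgrna",
              "pos_score", "pos_p", "pos_lfc", "pos_goodsgrna")],
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(out) <- c("id", "num", "neg|score", "neg|p-value", "neg|lfc",
                  "neg|goodsgrna", "pos|score", "pos|p-value", "pos|lfc",
                  "pos|goodsgrna")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_summary
#' @export
read_gene_summary <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(
    target_id = raw$id, n_sgrna = raw$num,
    neg_score = raw[["neg|score"]], neg_p = raw[["neg|p-value"]],
    neg_lfc = raw[["neg|lfc"]], neg_goodsgrna = raw[["neg|goodsgrna"]],
    pos_score = raw[["pos|score"]], pos_p = raw[["pos|p-value"]],
    pos_lfc = raw[["pos|lfc"]], pos_goodsgrna = raw[["pos|goodsgrna"]],
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_summary", "data.frame")
  out
}

#' Non-targeting pseudo-gene resampling null
#'
#' Models the gene-level fold-change variability expected from a "gene"
#' made of control guides: each of `n_pseudo` pseudo-genes averages `k` NT
#' sgRNA log2 fold changes drawn with replacement from the NT pool. The
#' standard deviation of the pseudo-gene lfcs is the yardstick of the
#' essentiality threshold (gene |lfc| must exceed 3 of these SDs).
#'
#' @param nt_lfcs Numeric vector of NT sgRNA log2 fold changes.
#' @param k Guides per pseudo-gene (default 4).
#' @param n_pseudo Number of pseudo-genes (default 800).
#' @param seed Integer seed.
#' @return List of class `nt_null`: `pseudo_lfcs`, `k`, `n_pseudo`, `sd`,
#'   `seed`.
#' @export
build_nt_null <- function(nt_lfcs, k = 4L, n_pseudo = 800L, seed = 1L) {
  nt_lfcs <- nt_lfcs[is.finite(nt_lfcs)]
  if (length(nt_lfcs) < k) {
    stop_null_build(sprintf("need at least k = %d NT lfc values", k))
  }
  set.seed(derive_seed(seed, "nt_null"))
  draws <- matrix(sample(nt_lfcs, k * n_pseudo, replace = TRUE), nrow = k)
  pseudo <- colMeans(draws)
  structure(list(pseudo_lfcs = pseudo, k = as.integer(k),
                 n_pseudo = as.integer(n_pseudo),
                 sd = stats::sd(pseudo), seed = as.integer(seed)),
            class = "nt_null")
}
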