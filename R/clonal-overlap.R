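## TCR clonal overlap between blood and CSF, per-cluster migration
## propensity, and its correlation with regulator expression.
##
## A blood or CSF T cell is "overlapping" when its TCR clonotype (by
## default the beta-chain CDR3 amino-acid sequence, after restricting to
## single-beta cells) occurs in both compartments of the same participant;
## clones seen at least three times in total are additionally "expanded".
## The migration propensity of a cluster is the percentage of its blood
## cells that are overlapping.

#' Flag overlapping and expanded cells
#'
#' @param cells Data frame with `cell_id`, `participant_id`, `group`,
#'   `compartment` (`blood`/`csf`), `cluster`, `tcrb_cdr3aa`,
#'   `n_beta_chains`. Cells with more than one beta chain or an empty CDR3
#'   are excluded (count reported in the `n_excluded` attribute).
#' @param key `"cdr3"` (default) keys clones on the CDR3beta amino-acid
#'   sequence; `"cdr3_vj"` additionally uses `v_gene`/`j_gene` columns.
#' @return The retained cells with logical columns `is_overlapping` and
#'   `is_expanded`; attribute `n_excluded`.
#' @export
flag_overlap <- function(cells, key = c("cdr3", "cdr3_vj")) {
  key <- match.arg(key)
  need <- c("cell_id", "participant_id", "compartment", "tcrb_cdr3aa", "n_beta_chains")
  if (!all(need %in% names(cells))) {
    stop_format(paste("cell table needs columns:", paste(need, collapse = ", ")))
  }
  if (!all(cells$compartment %in% c("blood", "csf"))) {
    stop_format("compartment must be 'blood' or 'csf'")
  }
  ok <- cells$n_beta_chains == 1L & !is.na(cells$tcrb_cdr3aa) & nzchar(cells$tcrb_cdr3aa)
  n_excluded <- sum(!ok)
  cells <- cells[ok, , drop = FALSE]

  clone_key <- paste(cells$participant_id, cells$tcrb_cdr3aa, sep = "\r")
  if (key == "cdr3_vj") {
    if (!all(c("v_gene", "j_gene") %in% names(cells))) {
      stop_format("key = 'cdr3_vj' needs v_gene and j_gene columns")
    }
    clone_key <- paste(clone_key, cells$v_gene, cells$j_gene, sep = "\r")
  }
  in_blood <- unique(clone_key[cells$compartment == "blood"])
  in_csf <- unique(clone_key[cells$compartment == "csf"])
  shared <- intersect(in_blood, in_csf)
  cells$is_overlapping <- clone_key %in% shared
  total <- table(clone_key)
  cells$is_expanded <- cells$is_overlapping & total[clone_key] >= 3L
  rownames(cells) <- NULL
  attr(cells, "n_excluded") <- n_excluded
  cells
}

#' Per-cluster overlap fractions and mean regulator expression
#'
#' For each cluster and group, the migration propensity is
#' `100 * n_overlapping / n_cells_blood` over that group's blood cells.
#' Optionally the mean (log-normalized) expression of queried genes over
#' the same blood cells is attached as `mean_expr.<gene>` columns.
#'
#' @param cells Output of [flag_overlap()] with a `cluster` and `group`
#'   column.
#' @param expression Optional cells x genes matrix (rownames = cell ids).
#' @param genes Genes to summarize from `expression`.
#' @param expr_stat `"mean"` (default) or `"median"` per-cluster summary.
#' @return Data frame per cluster x group: `cluster`, `group`,
#'   `n_cells_blood`, `n_overlapping`, `pct_overlapping` (`NA` and
#'   `undefined = TRUE` when a cluster has no blood cells), plus
#'   expression columns.
#' @export
cluster_overlap <- function(cells, expression = NULL, genes = NULL,
                            expr_stat = c("mean", "median")) {
  expr_stat <- match.arg(expr_stat)
  if (!all(c("cluster", "group", "is_overlapping") %in% names(cells))) {
    stop_format("cells need cluster, group and is_overlapping (run flag_overlap)")
  }
  stat_fun <- if (expr_stat == "mean") base::mean else stats::median
  grid <- unique(cells[, c("cluster", "group")])
  grid <- grid[order(grid$cluster, grid$group), , drop = FALSE]
  out <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- cells$cluster == grid$cluster[i] & cells$group == grid$group[i] &
      cells$compartment == "blood"
    nb <- sum(sel); nov <- sum(cells$is_overlapping[sel])
    row <- data.frame(cluster = grid$cluster[i], group = grid$group[i],
                      n_cells_blood = nb, n_overlapping = nov,
                      pct_overlapping = if (nb > 0) 100 * nov / nb else NA_real_,
                      undefined = nb == 0, stringsAsFactors = FALSE)
    if (!is.null(expression) && !is.null(genes)) {
      ids <- intersect(cells$cell_id[sel], rownames(expression))
      for (g in genes) {
        row[[paste0("mean_expr.", g)]] <-
          if (length(ids)) stat_fun(expression[ids, g]) else NA_real_
      }
    }
    row
  })
  do.call(rbind, out)
}

#' Correlate cluster migration propensity with a per-cluster quantity
#'
#' Pearson correlation between `pct_overlapping` and either the mean
#' expression of `gene` (from [cluster_overlap()]) or an externally
#' supplied per-cluster vector `values` (e.g. an MS-versus-control
#' expression log2 fold change). The p-value uses the t transform with
#' `n - 2` degrees of freedom.
#'
#' @param overlap A [cluster_overlap()] table (rows with undefined
#'   propensity are dropped).
#' @param gene Gene whose `mean_expr.<gene>` column to use.
#' @param values Alternative per-row numeric vector (same order as
#'   `overlap`).
#' @return List: `r`, `p_two_sided`, `n_clusters`.
#' @export
correlate_propensity <- function(overlap, gene = NULL, values = NULL) {
  y <- overlap$pct_overlapping
  x <- if (!is.null(values)) values else {
    col <- paste0("mean_expr.", gene)
    if (is.null(gene) || !col %in% names(overlap)) {
      stop_config("supply 'values' or a 'gene' present in the overlap table")
    }
    overlap[[col]]
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_config("need >= 3 clusters with defined propensity")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_undefined_cor("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_two_sided = ct$p.value, n_clusters = length(x))
}

#' Flag differentially expressed genes by the adaptive lfc rule
#'
#' A gene is flagged when its adjusted p-value is below 0.05 and its
#' |log2 fold change| exceeds `sd_mult` times the standard deviation of
#' all fold changes in the table (strict inequalities).
#'
#' @param de Data frame `gene`, `lfc`, `p_adj`.
#' @param sd_mult SD multiplier (default 3).
#' @param p_cut Adjusted p cutoff (default 0.05).
#' @return The table with a logical `flagged` column.
#' @export
flag_significant_genes <- function(de, sd_mult = 3, p_cut = 0.05) {
  if (!all(c("gene", "lfc", "p_adj") %in% names(de))) {
    stop_format("de table needs gene, lfc, p_adj")
  }
  s <- stats::sd(de$lfc)
  de$flagged <- de$p_adj < p_cut & abs(de$lfc) > sd_mult * s
  de
}
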