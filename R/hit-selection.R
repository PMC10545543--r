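## Tiered candidate selection (genome-wide screen -> validation library)
## and facilitator/brake essentiality calling (validation screen).
##
## All inequalities are implemented exactly as stated in the selection
## rules (strict vs non-strict), table-driven so boundary behaviour is
## testable: CNS-versus-blood comparisons admit any gene with |lfc| > 0.5;
## other comparisons need (|lfc| > 1 and directional goodsgrna >= 2) or
## (|lfc| > 0.6 and directional goodsgrna > 2); non-expressed genes are
## dropped unless a CNS-versus-blood |lfc| > 0.85 rescues them; externally
## supplied gene lists (e.g. GO-derived) are unioned in verbatim.

#' Selection configuration
#'
#' @param expressed_genes Character vector of genes expressed in T cells
#'   (external list), or `NULL` to skip the expression filter.
#' @param extra_lists Named list of externally derived gene sets to union
#'   in verbatim (e.g. GO-term candidates).
#' @param cns_comparisons Comparison names treated as CNS-versus-blood
#'   (tier 1).
#' @param other_comparisons Recognized non-CNS comparison names (tier 2).
#' @param lfc_tier1,lfc_tier2a,lfc_tier2b,lfc_rescue The four |lfc|
#'   cutoffs (defaults 0.5, 1, 0.6, 0.85).
#' @param good_tier2a,good_tier2b goodsgrna cutoffs: tier 2a requires
#'   `>= good_tier2a` (default 2), tier 2b `> good_tier2b` (default 2).
#' @param strict_text If `TRUE`, the tier-2a goodsgrna clause consults
#'   `neg_goodsgrna` regardless of direction (a literal reading of the
#'   rule's wording); default `FALSE` uses the directional column.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(expressed_genes = NULL, extra_lists = list(),
                             cns_comparisons = c("meninges:blood", "parenchyma:blood"),
                             other_comparisons = c("meninges:spleen",
                                                   "parenchyma:spleen",
                                                   "spleen:blood"),
                             lfc_tier1 = 0.5, lfc_tier2a = 1, lfc_tier2b = 0.6,
                             lfc_rescue = 0.85, good_tier2a = 2L, good_tier2b = 2L,
                             strict_text = FALSE) {
  for (v in c(lfc_tier1, lfc_tier2a, lfc_tier2b, lfc_rescue)) {
    if (v <= 0) stop_config("lfc cutoffs must be > 0")
  }
  structure(list(expressed_genes = expressed_genes, extra_lists = extra_lists,
                 cns_comparisons = cns_comparisons,
                 other_comparisons = other_comparisons,
                 lfc_tier1 = lfc_tier1, lfc_tier2a = lfc_tier2a,
                 lfc_tier2b = lfc_tier2b, lfc_rescue = lfc_rescue,
                 good_tier2a = good_tier2a, good_tier2b = good_tier2b,
                 strict_text = strict_text),
            class = "selection_config")
}

## The directional lfc of a gene: the lfc column is shared between
## directions here (gene lfc is the member-lfc summary), so |lfc| uses
## whichever of neg_lfc/pos_lfc is larger in magnitude, and direction
## follows its sign.
gene_abs_lfc <- function(s) pmax(abs(s$neg_lfc), abs(s$pos_lfc))
gene_lfc_sign <- function(s) {
  ifelse(abs(s$pos_lfc) > abs(s$neg_lfc), sign(s$pos_lfc), sign(s$neg_lfc))
}

#' Select validation-screen candidates from genome-wide gene summaries
#'
#' @param summaries Named list of `gene_summary` tables, keyed by
#'   comparison name (e.g. `"meninges:blood"`).
#' @param config A [selection_config()].
#' @return List with `candidates` (sorted unique gene ids) and
#'   `provenance` (data frame gene, comparison, rule for every admission,
#'   including `extra:<list>` rows).
#' @export
select_candidates <- function(summaries, config) {
  if (!inherits(config, "selection_config")) stop_config("config must be a selection_config")
  unknown <- setdiff(names(summaries),
                     c(config$cns_comparisons, config$other_comparisons))
  if (length(unknown)) {
    stop_config(paste("unknown comparison name:", unknown[1L]))
  }
  prov <- list()
  for (cmp in names(summaries)) {
    s <- summaries[[cmp]]
    alfc <- gene_abs_lfc(s)
    sgn <- gene_lfc_sign(s)
    is_cns <- cmp %in% config$cns_comparisons
    if (is_cns) {
      hit <- alfc > config$lfc_tier1
      rule <- ifelse(alfc > config$lfc_rescue, "cns_lfc_gt_0.85", "cns_lfc_gt_0.5")
    } else {
      dir_good <- ifelse(sgn < 0, s$neg_goodsgrna, s$pos_goodsgrna)
      good_a <- if (config$strict_text) s$neg_goodsgrna else dir_good
      tier2a <- alfc > config$lfc_tier2a & good_a >= config$good_tier2a
      tier2b <- alfc > config$lfc_tier2b & dir_good > config$good_tier2b
      hit <- tier2a | tier2b
      rule <- ifelse(tier2a, "other_lfc_gt_1_good_ge_2", "other_lfc_gt_0.6_good_gt_2")
    }
    if (any(hit)) {
      prov[[cmp]] <- data.frame(gene = s$target_id[hit], comparison = cmp,
                                rule = rule[hit], abs_lfc = alfc[hit],
                                stringsAsFactors = FALSE)
    }
  }
  prov <- if (length(prov)) do.call(rbind, unname(prov)) else
    data.frame(gene = character(0), comparison = character(0),
               rule = character(0), abs_lfc = numeric(0))

  # expression filter: keep a gene only if expressed, or if some
  # CNS-versus-blood admission has |lfc| > lfc_rescue
  if (!is.null(config$expressed_genes) && nrow(prov) > 0) {
    rescued <- unique(prov$gene[prov$comparison %in% config$cns_comparisons &
                                  prov$abs_lfc > config$lfc_rescue])
    keep_gene <- prov$gene %in% config$expressed_genes | prov$gene %in% rescued
    prov <- prov[keep_gene, , drop = FALSE]
  }

  extra <- list()
  for (nm in names(config$extra_lists)) {
    g <- unique(config$extra_lists[[nm]])
    if (length(g)) {
      extra[[nm]] <- data.frame(gene = g, comparison = NA_character_,
                                rule = paste0("extra:", nm), abs_lfc = NA_real_,
                                stringsAsFactors = FALSE)
    }
  }
  prov <- rbind(prov, if (length(extra)) do.call(rbind, unname(extra)))
  list(candidates = sort(unique(prov$gene)), provenance = prov)
}

#' Call essential facilitators and brakes of CNS migration
#'
#' Per comparison, a gene is a *facilitator* (knockout impairs migration)
#' when `neg_lfc < -sd_mult * sd_NT`, `neg_goodsgrna >= min_goodsgrna` and
#' `neg_p < p_cut`; a *brake* by the mirrored positive rule. `sd_NT` is
#' the standard deviation of the NT pseudo-gene null for that comparison
#' ([build_nt_null()]). A gene is flagged `essential` when the same
#' direction is called in at least `min_support` comparisons.
#'
#' @param summaries Named list of `gene_summary` tables per comparison.
#' @param nt_nulls Named list of `nt_null` objects (or numeric SDs) keyed
#'   by the same comparison names.
#' @param min_goodsgrna Minimum directional goodsgrna (default 3).
#' @param p_cut Directional p-value cutoff (default 0.05, strict `<`).
#' @param sd_mult NT-SD multiplier (default 3, strict inequality).
#' @param min_support Comparisons required for the aggregate essential
#'   flag (default 3).
#' @return List with `per_comparison` (gene x comparison calls) and
#'   `aggregate` (gene, direction, n_support, essential).
#' @export
call_essential <- function(summaries, nt_nulls, min_goodsgrna = 3L,
                           p_cut = 0.05, sd_mult = 3, min_support = 3L) {
  missing_null <- setdiff(names(summaries), names(nt_nulls))
  if (length(missing_null)) {
    stop_calling(paste("missing NT null for comparison:", missing_null[1L]))
  }
  per <- list()
  for (cmp in names(summaries)) {
    s <- summaries[[cmp]]
    null <- nt_nulls[[cmp]]
    sd_nt <- if (inherits(null, "nt_null")) null$sd else as.numeric(null)
    fac <- s$neg_lfc < -sd_mult * sd_nt &
      s$neg_goodsgrna >= min_goodsgrna & s$neg_p < p_cut
    brk <- s$pos_lfc > sd_mult * sd_nt &
      s$pos_goodsgrna >= min_goodsgrna & s$pos_p < p_cut
    # a gene cannot be both directions in one comparison; the (defensive)
    # tie goes to the larger |lfc|
    both <- fac & brk
    if (any(both)) {
      fac[both] <- abs(s$neg_lfc[both]) >= abs(s$pos_lfc[both])
      brk[both] <- !fac[both]
    }
    per[[cmp]] <- data.frame(target_id = s$target_id, comparison = cmp,
                             facilitator = fac, brake = brk,
                             stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, unname(per))
  agg <- stats::aggregate(cbind(facilitator, brake) ~ target_id, per, sum)
  direction <- ifelse(agg$facilitator >= agg$brake & agg$facilitator > 0, "facilitator",
                      ifelse(agg$brake > 0, "brake", "none"))
  n_support <- pmax(agg$facilitator, agg$brake)
  aggregate <- data.frame(target_id = agg$target_id, direction = direction,
                          n_support = n_support,
                          essential = n_support >= min_support & direction != "none",
                          stringsAsFactors = FALSE)
  list(per_comparison = per, aggregate = aggregate)
}
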