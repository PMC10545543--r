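## End-to-end screen pipeline: counts -> filter -> normalize -> per-
## comparison sgRNA tests -> gene summaries -> NT null -> essential calls,
## with plain-file handoff so every stage is independently rerunnable.

#' Run configuration
#'
#' @param comparisons Character vector `"tissueB:tissueA"` (B tested
#'   against reference A), e.g. `"meninges:blood"`.
#' @param seed Master seed (mandatory).
#' @param filter_threshold,filter_max_low Low-count filter parameters.
#' @param norm_reference,norm_min_count Normalization parameters.
#' @param pseudocount,alpha,n_perm,gene_lfc Test/aggregation parameters.
#' @param nt_k,nt_n_pseudo NT pseudo-gene null parameters.
#' @param min_goodsgrna,p_cut,sd_mult,min_support Essentiality-call
#'   parameters.
#' @return List of class `run_config`.
#' @export
run_config <- function(comparisons = c("meninges:blood", "parenchyma:blood",
                                       "meninges:spleen", "parenchyma:spleen",
                                       "spleen:blood"),
                       seed = NULL,
                       filter_threshold = 50L, filter_max_low = 2L,
                       norm_reference = "all", norm_min_count = 50L,
                       pseudocount = 1, alpha = 0.25, n_perm = 1000L,
                       gene_lfc = "median",
                       nt_k = 4L, nt_n_pseudo = 800L,
                       min_goodsgrna = 3L, p_cut = 0.05, sd_mult = 3,
                       min_support = 3L) {
  if (is.null(seed)) stop_config("run_config requires an explicit integer seed")
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with any subset of [run_config()] fields.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

## Wrap a stage so failures carry the stage name.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_cnscreen("cnscreen_stage_error",
                  sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full screen analysis
#'
#' @param counts Raw integer count matrix (sgRNA x sample).
#' @param meta Sample metadata (`sample_id`, `tissue`, `replicate`).
#' @param manifest A `library_manifest`.
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, gene summaries, the NT
#'   nulls, essential calls and a provenance record are written there.
#' @return List: `summaries` (per comparison), `nt_nulls`, `calls`,
#'   `filter` (dropped guides), `size_factors`.
#' @export
run_pipeline <- function(counts, meta, manifest, config, out_dir = NULL) {
  if (!inherits(config, "run_config")) stop_config("config must be a run_config")
  tissues <- unique(meta$tissue)
  for (cmp in config$comparisons) {
    pair <- strsplit(cmp, ":", fixed = TRUE)[[1L]]
    if (length(pair) != 2L || !all(pair %in% tissues)) {
      stop_config(paste("comparison references unknown tissue:", cmp))
    }
  }
  validate_manifest(manifest)
  nt_ids <- nt_guides(manifest)

  run_stage("counts", {
    if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
      stop_format("counts must be non-negative integers without missing values")
    }
    if (!all(rownames(counts) %in% manifest$sgrna_id)) {
      stop_format("count rows must be manifest sgRNA ids")
    }
  })

  flt <- run_stage("filter", filter_low_counts(
    counts, meta, config$filter_threshold, config$filter_max_low))
  sf <- run_stage("normalize", size_factors(
    flt$counts, reference = config$norm_reference, nt_ids = nt_ids,
    min_count = config$norm_min_count))
  norm <- normalize_counts(flt$counts, sf)

  samples_of <- function(tis) meta$sample_id[meta$tissue == tis]
  summaries <- list(); nt_nulls <- list()
  for (cmp in config$comparisons) {
    pair <- strsplit(cmp, ":", fixed = TRUE)[[1L]]
    st <- run_stage(paste0("test:", cmp), sgrna_test(
      norm, group_a = samples_of(pair[2L]), group_b = samples_of(pair[1L]),
      nt_ids = nt_ids, pseudocount = config$pseudocount))
    summaries[[cmp]] <- run_stage(paste0("aggregate:", cmp), gene_summary(
      st, manifest, alpha = config$alpha, n_perm = config$n_perm,
      seed = derive_seed(config$seed, cmp), gene_lfc = config$gene_lfc))
    nt_lfcs <- st$lfc[st$sgrna_id %in% nt_ids]
    nt_nulls[[cmp]] <- run_stage(paste0("nt_null:", cmp), build_nt_null(
      nt_lfcs, k = config$nt_k, n_pseudo = config$nt_n_pseudo,
      seed = derive_seed(config$seed, paste0("null_", cmp))))
  }
  calls <- run_stage("call_essential", call_essential(
    summaries, nt_nulls, min_goodsgrna = config$min_goodsgrna,
    p_cut = config$p_cut, sd_mult = config$sd_mult,
    min_support = config$min_support))

  res <- list(summaries = summaries, nt_nulls = nt_nulls, calls = calls,
              filter = flt["dropped"], size_factors = sf)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cmp in names(summaries)) {
      write_gene_summary(summaries[[cmp]],
                         file.path(out_dir, paste0("gene_summary_", gsub(":", "_vs_", cmp), ".tsv")))
    }
    null_df <- data.frame(
      comparison = names(nt_nulls),
      sd = vapply(nt_nulls, function(x) x$sd, numeric(1)),
      n_pseudo = vapply(nt_nulls, function(x) x$n_pseudo, integer(1)),
      k = vapply(nt_nulls, function(x) x$k, integer(1))
    )
    utils::write.table(null_df, file.path(out_dir, "nt_null.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(calls$aggregate, file.path(out_dir, "essential_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    prov <- list(
      package = "cnscreen",
      version = as.character(utils::packageVersion("cnscreen")),
      seed = config$seed,
      config = unclass(config),
      n_sgrna_in = nrow(counts), n_sgrna_kept = nrow(flt$counts),
      n_dropped = length(flt$dropped),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}
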