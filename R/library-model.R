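## Library manifests and screen-design arithmetic.
##
## A pooled CRISPR migration screen is designed around three numbers: the
## library size (distinct sgRNAs), the multiplicity of infection (kept low so
## most transduced T cells carry a single guide), and the coverage (average
## cells carrying each guide). The functions here do that arithmetic and
## build the sgRNA manifest objects every other module consumes.

NT_TARGET_ID <- "non_targeting"

#' Build an sgRNA library manifest
#'
#' Constructs a manifest of gene-targeting, miRNA-targeting and
#' non-targeting (NT) control sgRNAs with unique random 20-nt guide
#' sequences. Genome-wide migration screens typically use 4 guides per gene
#' (6 in focused validation libraries) plus several hundred NT controls that
#' define the empirical null.
#'
#' @param n_genes Number of target genes.
#' @param sgrnas_per_gene Guides designed per gene (and per miRNA).
#' @param n_nt Number of non-targeting control guides; they share the
#'   reserved target id `"non_targeting"`.
#' @param n_mirna Number of miRNA targets.
#' @param seed Integer seed; manifests are reproducible.
#' @param total Optional exact total number of records. If smaller than the
#'   nominal `n_genes*sgrnas_per_gene + n_mirna*sgrnas_per_gene + n_nt`,
#'   miRNA-class guides are trimmed (the class for which fewer unique guides
#'   tend to be available) to reach the requested total.
#' @return A `data.frame` of class `library_manifest` with columns
#'   `sgrna_id`, `target_id`, `target_type` (`gene`/`mirna`/`nt`) and
#'   `guide_seq`.
#' @examples
#' m <- build_manifest(n_genes = 2, sgrnas_per_gene = 4, n_nt = 3, seed = 1)
#' nrow(m)  # 11
#' @export
build_manifest <- function(n_genes, sgrnas_per_gene = 4L, n_nt = 0L,
                           n_mirna = 0L, seed = 1L, total = NULL) {
  for (v in list(n_genes, sgrnas_per_gene, n_nt, n_mirna)) {
    if (!is_count(v)) stop_invalid_design("manifest counts must be non-negative integers")
  }
  n_records <- n_genes * sgrnas_per_gene + n_mirna * sgrnas_per_gene + n_nt
  if (n_records < 1) stop_invalid_design("manifest would contain zero sgRNA records")

  wd <- function(prefix, n) sprintf(paste0(prefix, "%0", max(4L, nchar(n)), "d"), seq_len(n))
  rows <- list()
  if (n_genes > 0 && sgrnas_per_gene > 0) {
    gid <- wd("gene_", n_genes)
    rows$gene <- data.frame(
      sgrna_id = paste0(rep(gid, each = sgrnas_per_gene), "_sg", seq_len(sgrnas_per_gene)),
      target_id = rep(gid, each = sgrnas_per_gene),
      target_type = "gene", stringsAsFactors = FALSE
    )
  }
  if (n_mirna > 0 && sgrnas_per_gene > 0) {
    mid <- wd("mir_", n_mirna)
    rows$mirna <- data.frame(
      sgrna_id = paste0(rep(mid, each = sgrnas_per_gene), "_sg", seq_len(sgrnas_per_gene)),
      target_id = rep(mid, each = sgrnas_per_gene),
      target_type = "mirna", stringsAsFactors = FALSE
    )
  }
  if (n_nt > 0) {
    rows$nt <- data.frame(
      sgrna_id = wd("nt_sg_", n_nt),
      target_id = NT_TARGET_ID,
      target_type = "nt", stringsAsFactors = FALSE
    )
  }
  man <- do.call(rbind, unname(rows))

  if (!is.null(total)) {
    if (!is_count(total) || total < 1) stop_invalid_design("'total' must be a positive count")
    excess <- nrow(man) - total
    if (excess > 0) {
      idx_mirna <- which(man$target_type == "mirna")
      if (length(idx_mirna) < excess) {
        stop_invalid_design("cannot trim manifest to 'total': not enough miRNA-class guides")
      }
      man <- man[-utils::tail(idx_mirna, excess), , drop = FALSE]
    } else if (excess < 0) {
      stop_invalid_design("'total' exceeds the nominal record count")
    }
  }

  man$guide_seq <- random_guides(nrow(man), seed = derive_seed(seed, "guides"))
  rownames(man) <- NULL
  class(man) <- c("library_manifest", "data.frame")
  validate_manifest(man)
  man
}

## Unique random 20-mers; duplicate draws are rejected and redrawn.
random_guides <- function(n, width = 20L, seed = 1L) {
  set.seed(seed)
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * width, replace = TRUE), nrow = k)
    apply(m, 1L, paste0, collapse = "")
  }
  g <- draw(n)
  while (anyDuplicated(g)) {
    dup <- which(duplicated(g))
    g[dup] <- draw(length(dup))
  }
  g
}

#' Validate a library manifest
#'
#' Checks the manifest invariants: unique sgRNA ids, 20-nt ACGT guide
#' sequences, NT records carrying the shared reserved target id, and at
#' least one guide per target.
#' @param manifest A `library_manifest`.
#' @return The manifest, invisibly; errors on violation.
#' @export
validate_manifest <- function(manifest) {
  need <- c("sgrna_id", "target_id", "target_type", "guide_seq")
  if (!all(need %in% names(manifest))) {
    stop_format(paste("manifest must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(manifest$sgrna_id)) stop_format("duplicated sgrna_id in manifest")
  if (any(nchar(manifest$guide_seq) != 20L) ||
      any(grepl("[^ACGT]", manifest$guide_seq))) {
    stop_format("guide_seq must be 20-nt uppercase DNA (A/C/G/T)")
  }
  if (!all(manifest$target_type %in% c("gene", "mirna", "nt"))) {
    stop_format("target_type must be gene, mirna or nt")
  }
  nt <- manifest$target_type == "nt"
  if (any(nt) && !all(manifest$target_id[nt] == NT_TARGET_ID)) {
    stop_format(sprintf("all NT records must share target_id '%s'", NT_TARGET_ID))
  }
  if (any(manifest$target_id[!nt] == NT_TARGET_ID)) {
    stop_format(sprintf("target_id '%s' is reserved for NT guides", NT_TARGET_ID))
  }
  invisible(manifest)
}

#' Non-targeting guide ids of a manifest
#' @param manifest A `library_manifest`.
#' @return Character vector of NT sgRNA ids.
#' @export
nt_guides <- function(manifest) manifest$sgrna_id[manifest$target_type == "nt"]

#' Cells required to screen a library at a target coverage
#'
#' `required_cells = library_size * target_coverage`; e.g. a 12,000-guide
#' validation library at 1,000x coverage needs 12e6 transduced cells.
#'
#' @param library_size Number of distinct sgRNAs.
#' @param target_coverage Desired cells per sgRNA.
#' @return Required cell count (numeric, exact integer value).
#' @export
plan_coverage <- function(library_size, target_coverage) {
  if (!is_count(library_size) || library_size < 1 ||
      !is_count(target_coverage) || target_coverage < 1) {
    stop_invalid_design("library_size and target_coverage must be positive counts")
  }
  as.numeric(library_size) * as.numeric(target_coverage)
}

#' Expected coverage from cell number, MOI and library size
#'
#' Average number of transduced cells carrying each sgRNA:
#' `n_cells * moi / library_size`. With 300e6 T cells at MOI 0.3 and a
#' genome-wide library of ~88,000 guides this is about 1,000 cells/guide.
#'
#' @param n_cells Cells exposed to the library.
#' @param moi Multiplicity of infection, in (0, 1].
#' @param library_size Number of distinct sgRNAs.
#' @return Cells per sgRNA (real).
#' @export
expected_coverage <- function(n_cells, moi, library_size) {
  if (!is.numeric(moi) || length(moi) != 1L || moi <= 0 || moi > 1) {
    stop_invalid_design("moi must lie in (0, 1]")
  }
  if (!is.numeric(n_cells) || n_cells < 1 || !is.numeric(library_size) || library_size < 1) {
    stop_invalid_design("n_cells and library_size must be >= 1")
  }
  as.numeric(n_cells) * moi / as.numeric(library_size)
}

#' Fraction of transduced cells with more than one integration
#'
#' Under a Poisson model of viral integration at multiplicity `moi`, the
#' fraction of *transduced* cells (at least one integration) that carry more
#' than one guide is `(1 - exp(-moi) - moi exp(-moi)) / (1 - exp(-moi))`.
#' Screens keep MOI < 0.3 so this stays low and sgRNA effects remain
#' attributable to single perturbations.
#'
#' @param moi Multiplicity of infection (> 0).
#' @return Fraction in (0, 1), strictly increasing in `moi`.
#' @export
multi_integration_fraction <- function(moi) {
  if (!is.numeric(moi) || length(moi) != 1L || !is.finite(moi) || moi <= 0) {
    stop_invalid_design("moi must be a positive number")
  }
  (1 - exp(-moi) - moi * exp(-moi)) / (1 - exp(-moi))
}

#' Read / write a manifest TSV
#'
#' Tab-separated with header `sgrna_id, target_id, target_type, guide_seq`.
#' @param manifest A `library_manifest`.
#' @param path File path.
#' @return `read_manifest` returns a validated `library_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_io(paste("no such file:", path))
  man <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  class(man) <- c("library_manifest", "data.frame")
  validate_manifest(man)
  man
}
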