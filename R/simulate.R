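## Synthetic data with known ground truth.
##
## The screen generator mimics the in vivo design: a transduced T cell pool
## is injected per animal (replicate); blood and peripheral tissues sample
## that pool without selection, while CNS compartments (meninges,
## parenchyma) impose a migration bottleneck in which a cell carrying guide
## g against target t is drawn with relative weight 2^(effect_lfc(t) *
## efficacy(g)). Facilitator knockouts (negative effect_lfc) are depleted
## from the CNS; brake knockouts (positive) are enriched. Sequencing adds
## negative-binomial noise on top of the sampled cell counts.

#' Simulation configuration for a migration screen
#'
#' @param n_genes,sgrnas_per_gene,n_nt,n_mirna Library composition, as in
#'   [build_manifest()].
#' @param coverage Cells per sgRNA in the injected pool (the screen's
#'   nominal coverage; the paper-scale design is ~1,000x).
#' @param tissues Data frame with columns `tissue`, `bottleneck` (cells
#'   sampled from the pool) and `cns` (logical; migration selection
#'   applies). Defaults model blood, spleen and the two CNS compartments
#'   with progressively tighter bottlenecks.
#' @param replicates Animals per tissue; each replicate has its own
#'   injected pool shared by all of that replicate's tissues.
#' @param depth Expected total reads per sample.
#' @param dispersion Negative-binomial dispersion of sequencing counts
#'   (variance = mu + dispersion * mu^2).
#' @param n_facilitators,n_brakes Number of planted effect genes.
#' @param facilitator_lfc,brake_lfc Planted log2 change of CNS migration
#'   probability for knockouts of each class (facilitator knockouts migrate
#'   less, so their `effect_lfc` is negative).
#' @param efficacy_mean,efficacy_conc Per-guide knockout efficacy is drawn
#'   from a Beta distribution with this mean and concentration
#'   (`shape1 + shape2`); efficacies scale the planted effect per guide.
#' @param seed Master seed; mandatory. All stage seeds derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, sgrnas_per_gene = 4L, n_nt = 800L,
                       n_mirna = 0L,
                       coverage = 500,
                       tissues = default_tissues(),
                       replicates = 3L,
                       depth = NULL,
                       dispersion = 0.05,
                       n_facilitators = 0L, n_brakes = 0L,
                       facilitator_lfc = -2, brake_lfc = 2,
                       efficacy_mean = 0.8, efficacy_conc = 10,
                       seed = NULL) {
  if (is.null(seed)) stop_config("sim_config requires an explicit integer seed")
  if (!is.data.frame(tissues) ||
      !all(c("tissue", "bottleneck", "cns") %in% names(tissues))) {
    stop_config("tissues must be a data.frame with tissue, bottleneck, cns")
  }
  if (any(tissues$bottleneck < 1)) stop_config("bottleneck sizes must be >= 1")
  n_guides <- n_genes * sgrnas_per_gene + n_mirna * sgrnas_per_gene + n_nt
  pool <- coverage * n_guides
  if (any(tissues$bottleneck > pool)) {
    stop_config("bottleneck exceeds the injected pool size (coverage * library size)")
  }
  if (is.null(depth)) depth <- 300 * n_guides
  if (depth < 1) stop_config("depth must be >= 1")
  if (n_facilitators + n_brakes > n_genes) stop_config("more planted effects than genes")
  if (efficacy_mean <= 0 || efficacy_mean > 1) stop_config("efficacy_mean must be in (0, 1]")
  structure(list(
    n_genes = n_genes, sgrnas_per_gene = sgrnas_per_gene, n_nt = n_nt,
    n_mirna = n_mirna, coverage = coverage, tissues = tissues,
    replicates = as.integer(replicates), depth = depth, dispersion = dispersion,
    n_facilitators = n_facilitators, n_brakes = n_brakes,
    facilitator_lfc = facilitator_lfc, brake_lfc = brake_lfc,
    efficacy_mean = efficacy_mean, efficacy_conc = efficacy_conc,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_tissues <- function() {
  data.frame(
    tissue = c("blood", "spleen", "meninges", "parenchyma"),
    bottleneck = c(1e6, 2e6, 5e5, 2e5),
    cns = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

## Planted truth: which targets are facilitators/brakes and each guide's
## knockout efficacy. NT targets are always null with efficacy 0 relevance.
make_effect_truth <- function(manifest, config) {
  set.seed(derive_seed(config$seed, "effects"))
  targets <- unique(manifest$target_id[manifest$target_type != "nt"])
  gene_targets <- unique(manifest$target_id[manifest$target_type == "gene"])
  eff_class <- setNames(rep("null", length(targets)), targets)
  eff_lfc <- setNames(rep(0, length(targets)), targets)
  n_eff <- config$n_facilitators + config$n_brakes
  if (n_eff > 0) {
    chosen <- sample(gene_targets, n_eff)
    fac <- chosen[seq_len(config$n_facilitators)]
    brk <- setdiff(chosen, fac)
    eff_class[fac] <- "facilitator"; eff_lfc[fac] <- config$facilitator_lfc
    eff_class[brk] <- "brake";       eff_lfc[brk] <- config$brake_lfc
  }
  a <- config$efficacy_mean * config$efficacy_conc
  b <- (1 - config$efficacy_mean) * config$efficacy_conc
  efficacy <- if (b > 0) stats::rbeta(nrow(manifest), a, b) else rep(1, nrow(manifest))
  targets_df <- data.frame(
    target_id = c(targets, NT_TARGET_ID),
    effect_class = c(unname(eff_class), "null"),
    effect_lfc = c(unname(eff_lfc), 0),
    stringsAsFactors = FALSE
  )
  guides_df <- data.frame(
    sgrna_id = manifest$sgrna_id,
    efficacy = efficacy,
    stringsAsFactors = FALSE
  )
  list(targets = targets_df, guides = guides_df)
}

#' Simulate a pooled in vivo CRISPR migration screen
#'
#' Generates a manifest, a raw sgRNA x sample count matrix with sample
#' metadata, and the planted effect truth. Per replicate: (1) the injected
#' pool assigns `coverage * library_size` cells to guides multinomially;
#' (2) each tissue draws its bottleneck-many cells from that pool,
#' weighting CNS tissues by `2^(effect_lfc * efficacy)`; (3) sequencing
#' reads are negative-binomial around the cell counts scaled to `depth`.
#'
#' @param config A [sim_config()].
#' @return List with `manifest`, `counts` (integer matrix, sgRNA x sample),
#'   `meta` (sample_id, tissue, replicate) and `truth`
#'   (`$targets`, `$guides`).
#' @export
simulate_screen <- function(config) {
  if (!inherits(config, "sim_config")) stop_config("config must be a sim_config")
  manifest <- build_manifest(config$n_genes, config$sgrnas_per_gene,
                             config$n_nt, config$n_mirna,
                             seed = derive_seed(config$seed, "manifest"))
  truth <- make_effect_truth(manifest, config)

  lfc_by_target <- setNames(truth$targets$effect_lfc, truth$targets$target_id)
  guide_weight <- 2^(lfc_by_target[manifest$target_id] * truth$guides$efficacy)
  n_guides <- nrow(manifest)
  pool_cells <- round(config$coverage * n_guides)

  tissues <- config$tissues
  samples <- expand.grid(replicate = seq_len(config$replicates),
                         tissue = tissues$tissue,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample_id <- paste0(samples$tissue, "_r", samples$replicate)
  counts <- matrix(0L, n_guides, nrow(samples),
                   dimnames = list(manifest$sgrna_id, samples$sample_id))

  set.seed(derive_seed(config$seed, "screen"))
  for (r in seq_len(config$replicates)) {
    pool <- as.numeric(stats::rmultinom(1L, pool_cells, rep(1, n_guides)))
    for (ti in seq_len(nrow(tissues))) {
      w <- if (tissues$cns[ti]) pool * guide_weight else pool
      cells <- as.numeric(stats::rmultinom(1L, tissues$bottleneck[ti], w))
      mu <- config$depth * cells / sum(cells)
      reads <- if (config$dispersion > 0) {
        stats::rnbinom(n_guides, mu = mu, size = 1 / config$dispersion)
      } else {
        stats::rpois(n_guides, mu)
      }
      sid <- paste0(tissues$tissue[ti], "_r", r)
      counts[, sid] <- as.integer(reads)
    }
  }
  meta <- data.frame(sample_id = samples$sample_id, tissue = samples$tissue,
                     replicate = samples$replicate, stringsAsFactors = FALSE)
  list(manifest = manifest, counts = counts, meta = meta, truth = truth)
}

#' Simulate flow-cytometry co-transfer counts
#'
#' Each animal's tissue gate contains `cells_per_gate` cells split between
#' knockout (KO) and control populations: `ko ~ Binomial(cells_per_gate,
#' r/(1+r))` where `r` is the tissue's true KO/control ratio. Blood is
#' always included with ratio `blood_ratio` so downstream blood
#' normalization is defined.
#'
#' @param n_animals Number of animals.
#' @param tissues Character vector of non-blood tissues.
#' @param true_ratio Named per-tissue true KO/control ratio (> 0); a scalar
#'   is recycled.
#' @param cells_per_gate Cells in the lymphocyte gate; scalar or named per
#'   tissue (including `"blood"`).
#' @param blood_ratio True KO/control ratio in blood (default 1).
#' @param seed Integer seed.
#' @return Data frame: `animal_id`, `tissue`, `ko_count`, `control_count`.
#' @export
simulate_flow <- function(n_animals, tissues, true_ratio, cells_per_gate = 1000L,
                          blood_ratio = 1, seed = 1L) {
  if (any(true_ratio <= 0) || blood_ratio <= 0) stop_config("true ratios must be > 0")
  if (length(true_ratio) == 1L) true_ratio <- setNames(rep(true_ratio, length(tissues)), tissues)
  if (!all(tissues %in% names(true_ratio))) stop_config("true_ratio must name every tissue")
  all_tissues <- c("blood", setdiff(tissues, "blood"))
  ratio <- c(blood = blood_ratio, true_ratio[setdiff(tissues, "blood")])
  gate <- if (length(cells_per_gate) == 1L) {
    setNames(rep(cells_per_gate, length(all_tissues)), all_tissues)
  } else cells_per_gate
  if (!all(all_tissues %in% names(gate))) stop_config("cells_per_gate must name every tissue")

  set.seed(derive_seed(seed, "flow"))
  grid <- expand.grid(animal_id = paste0("animal_", seq_len(n_animals)),
                      tissue = all_tissues,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r <- ratio[grid$tissue]
  n <- gate[grid$tissue]
  ko <- stats::rbinom(nrow(grid), size = n, prob = r / (1 + r))
  data.frame(animal_id = grid$animal_id, tissue = grid$tissue,
             ko_count = ko, control_count = as.integer(n - ko),
             stringsAsFactors = FALSE)
}

#' Simulate paired blood/CSF clonotype and expression tables
#'
#' Emulates paired single-cell TCR data from blood and cerebrospinal fluid
#' (CSF): blood cells are organised into clones with unique CDR3beta amino
#' acid sequences per participant; each blood clone seeds the CSF with
#' probability equal to its cluster's migration propensity `pi_c`, making
#' its cells "overlapping". CSF-only filler clones populate the rest of the
#' CSF compartment. Per-cluster mean expression of each configured gene is
#' `intercept + slope * pi_c` plus noise, so expression-propensity
#' correlations have a known generating slope.
#'
#' @param n_participants Number of participants (alternately assigned to
#'   `ms` and `control` groups).
#' @param clusters Data frame with columns `cluster` and `propensity`
#'   (`pi_c` in `[0, 1]`).
#' @param cells_per_cluster Blood cells per participant per cluster.
#' @param csf_cells_per_cluster CSF filler cells per participant per cluster.
#' @param mean_clone_size Mean blood clone size (geometric, >= 1).
#' @param genes Data frame `gene`, `intercept`, `slope`, `noise_sd`
#'   (cluster-level noise) describing simulated regulator genes; `NULL` for
#'   no expression matrix.
#' @param cell_noise_sd Within-cluster per-cell expression noise.
#' @param seed Integer seed.
#' @return List with `cells` (CellRecord table), `expression` (cells x
#'   genes matrix or `NULL`) and `truth` (`clusters`, `genes`,
#'   `cluster_expr`).
#' @export
simulate_clones <- function(n_participants, clusters, cells_per_cluster = 100L,
                            csf_cells_per_cluster = 30L, mean_clone_size = 2,
                            genes = NULL, cell_noise_sd = 0.25, seed = 1L) {
  if (!is.data.frame(clusters) || nrow(clusters) == 0 ||
      !all(c("cluster", "propensity") %in% names(clusters))) {
    stop_config("clusters must be a non-empty data.frame with cluster, propensity")
  }
  if (any(clusters$propensity < 0 | clusters$propensity > 1)) {
    stop_config("propensity must lie in [0, 1]")
  }
  set.seed(derive_seed(seed, "clones"))
  group_of <- function(i) if (i %% 2L == 1L) "ms" else "control"

  random_cdr3 <- function(n) {
    mid <- vapply(seq_len(n), function(i) {
      paste0(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                    sample(6:10, 1L), replace = TRUE), collapse = "")
    }, character(1))
    paste0("CASS", mid, "F")
  }

  cells <- list(); expr_means <- list()
  # cluster-level expression means, shared across participants
  if (!is.null(genes)) {
    em <- sapply(seq_len(nrow(genes)), function(g) {
      genes$intercept[g] + genes$slope[g] * clusters$propensity +
        stats::rnorm(nrow(clusters), 0, genes$noise_sd[g])
    })
    em <- matrix(em, nrow = nrow(clusters),
                 dimnames = list(clusters$cluster, genes$gene))
  } else em <- NULL

  cid <- 0L
  for (p in seq_len(n_participants)) {
    pid <- paste0("P", p)
    grp <- group_of(p)
    for (ci in seq_len(nrow(clusters))) {
      cl <- clusters$cluster[ci]; pi_c <- clusters$propensity[ci]
      # blood clones until the cluster's blood cell budget is filled
      n_left <- cells_per_cluster; sizes <- integer(0)
      while (n_left > 0) {
        s <- min(1L + stats::rgeom(1L, 1 / mean_clone_size), n_left)
        sizes <- c(sizes, s); n_left <- n_left - s
      }
      cdr3 <- random_cdr3(length(sizes))
      seeds_csf <- stats::runif(length(sizes)) < pi_c
      n_csf_over <- ifelse(seeds_csf, 1L + stats::rpois(length(sizes), 0.5), 0L)
      blood <- data.frame(
        participant_id = pid, group = grp, compartment = "blood", cluster = cl,
        tcrb_cdr3aa = rep(cdr3, sizes), stringsAsFactors = FALSE
      )
      csf_over <- if (any(seeds_csf)) data.frame(
        participant_id = pid, group = grp, compartment = "csf", cluster = cl,
        tcrb_cdr3aa = rep(cdr3, n_csf_over), stringsAsFactors = FALSE
      ) else NULL
      n_filler <- csf_cells_per_cluster
      csf_only <- if (n_filler > 0) data.frame(
        participant_id = pid, group = grp, compartment = "csf", cluster = cl,
        tcrb_cdr3aa = rep(random_cdr3(max(1L, n_filler %/% 2L)),
                          length.out = n_filler),
        stringsAsFactors = FALSE
      ) else NULL
      cid <- cid + 1L
      cells[[cid]] <- rbind(blood, csf_over, csf_only)
    }
  }
  cells <- do.call(rbind, cells)
  cells$cell_id <- sprintf("cell_%06d", seq_len(nrow(cells)))
  cells$n_beta_chains <- 1L
  cells <- cells[, c("cell_id", "participant_id", "group", "compartment",
                     "cluster", "tcrb_cdr3aa", "n_beta_chains")]

  expression <- NULL
  if (!is.null(em)) {
    mu <- em[cells$cluster, , drop = FALSE]
    expression <- mu + matrix(stats::rnorm(length(mu), 0, cell_noise_sd),
                              nrow = nrow(mu))
    rownames(expression) <- cells$cell_id
  }
  list(cells = cells, expression = expression,
       truth = list(clusters = clusters, genes = genes, cluster_expr = em))
}
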