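cell <- function(id, part, comp, cdr3, cluster = "T1", group = "ms", nb = 1L) {
  data.frame(cell_id = id, participant_id = part, group = group,
             compartment = comp, cluster = cluster, tcrb_cdr3aa = cdr3,
             n_beta_chains = nb, stringsAsFactors = FALSE)
}

test_that("clones shared across compartments of one participant overlap", {
  cells <- rbind(
    cell("c1", "P1", "blood", "CASSLGQF"),
    cell("c2", "P1", "csf", "CASSLGQF"),
    cell("c3", "P1", "blood", "CASSXYZF"),
    # identical sequence in different participants does not overlap
    cell("c4", "P2", "csf", "CASSXYZF")
  )
  fl <- flag_overlap(cells)
  expect_equal(fl$is_overlapping, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("expansion requires three total occurrences of an overlapping clone", {
  cells <- rbind(
    cell("c1", "P1", "blood", "CASSAF"), cell("c2", "P1", "blood", "CASSAF"),
    cell("c3", "P1", "csf", "CASSAF"),          # 3 total -> expanded
    cell("c4", "P1", "blood", "CASSBF"), cell("c5", "P1", "csf", "CASSBF")  # 2 total
  )
  fl <- flag_overlap(cells)
  expect_true(all(fl$is_expanded[fl$tcrb_cdr3aa == "CASSAF"]))
  expect_false(any(fl$is_expanded[fl$tcrb_cdr3aa == "CASSBF"]))
})

test_that("cells failing the single-beta or CDR3 invariants are excluded with a count", {
  cells <- rbind(cell("c1", "P1", "blood", "CASSAF"),
                 cell("c2", "P1", "csf", "CASSAF", nb = 2L),
                 cell("c3", "P1", "csf", ""))
  fl <- flag_overlap(cells)
  expect_equal(nrow(fl), 1)
  expect_equal(attr(fl, "n_excluded"), 2)
  expect_false(fl$is_overlapping)  # its CSF partner was excluded
})

test_that("overlap flags are invariant to row permutation", {
  set.seed(41)
  cl <- data.frame(cluster = paste0("T", 1:3), propensity = c(0.1, 0.5, 0.8))
  sim <- simulate_clones(2, cl, cells_per_cluster = 40, seed = 6)
  fl1 <- flag_overlap(sim$cells)
  perm <- sample(nrow(sim$cells))
  fl2 <- flag_overlap(sim$cells[perm, ])
  fl2 <- fl2[order(fl2$cell_id), ]
  fl1 <- fl1[order(fl1$cell_id), ]
  expect_equal(fl1$is_overlapping, fl2$is_overlapping)
  expect_equal(fl1$is_expanded, fl2$is_expanded)
})

test_that("per-cluster overlap percentages match a brute-force tally", {
  cl <- data.frame(cluster = paste0("T", 1:4), propensity = c(0, 0.3, 0.6, 1))
  sim <- simulate_clones(4, cl, cells_per_cluster = 50, seed = 7)
  fl <- flag_overlap(sim$cells)
  ov <- cluster_overlap(fl)
  for (i in seq_len(nrow(ov))) {
    sel <- fl$cluster == ov$cluster[i] & fl$group == ov$group[i] &
      fl$compartment == "blood"
    expect_equal(ov$n_cells_blood[i], sum(sel))
    expect_equal(ov$n_overlapping[i], sum(fl$is_overlapping[sel]))
    expect_equal(ov$pct_overlapping[i],
                 100 * sum(fl$is_overlapping[sel]) / sum(sel))
  }
  # propensity 0 cluster has zero overlap
  expect_true(all(ov$pct_overlapping[ov$cluster == "T1"] == 0))
})

test_that("a fully overlapping cluster reaches 100 percent", {
  cells <- rbind(cell("c1", "P1", "blood", "CASSAF"),
                 cell("c2", "P1", "csf", "CASSAF"))
  ov <- cluster_overlap(flag_overlap(cells))
  expect_equal(ov$pct_overlapping[1], 100)
})

test_that("propensity correlation equals the closed-form Pearson formula", {
  ov <- data.frame(cluster = paste0("T", 1:6), group = "ms",
                   n_cells_blood = 50, n_overlapping = 1:6,
                   pct_overlapping = c(2, 7, 13, 21, 33, 40),
                   undefined = FALSE)
  ov$mean_expr.g <- c(0.3, 0.5, 0.8, 0.9, 1.4, 1.6)
  res <- correlate_propensity(ov, gene = "g")
  x <- ov$mean_expr.g; y <- ov$pct_overlapping
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    (sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2)))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$n_clusters, 6)

  # perfectly linear relation gives r = 1
  ov$mean_expr.g <- 2 * ov$pct_overlapping + 1
  expect_equal(correlate_propensity(ov, gene = "g")$r, 1, tolerance = 1e-12)

  # zero variance is an undefined correlation
  ov$mean_expr.g <- 1
  expect_error(correlate_propensity(ov, gene = "g"),
               class = "cnscreen_undefined_correlation")
})

test_that("recovered propensities track the generating values", {
  cl <- data.frame(cluster = sprintf("T%02d", 1:12),
                   propensity = seq(0.02, 0.85, length.out = 12))
  sim <- simulate_clones(4, cl, cells_per_cluster = 110,
                         csf_cells_per_cluster = 30, seed = 10)
  fl <- flag_overlap(sim$cells)
  ov <- cluster_overlap(fl)
  ov_ms <- ov[ov$group == "ms", ]
  res <- correlate_propensity(ov_ms, values = cl$propensity[match(ov_ms$cluster, cl$cluster)])
  expect_gte(res$r, 0.9)
})

test_that("adaptive lfc significance flags follow the 3-SD rule exactly", {
  de <- data.frame(gene = paste0("g", 1:5),
                   lfc = c(0.1, -0.2, 2.5, 0.05, -2.8),
                   p_adj = c(0.2, 0.01, 0.001, 0.001, 0.04))
  res <- flag_significant_genes(de)
  s <- sd(de$lfc)
  expect_equal(res$flagged, de$p_adj < 0.05 & abs(de$lfc) > 3 * s)

  # random tables: flags equal a direct evaluation of the rule, including
  # the strict inequalities
  set.seed(91)
  for (i in 1:20) {
    de2 <- data.frame(gene = paste0("g", 1:30), lfc = rnorm(30, 0, 0.4),
                      p_adj = runif(30))
    got <- flag_significant_genes(de2)$flagged
    want <- de2$p_adj < 0.05 & abs(de2$lfc) > 3 * sd(de2$lfc)
    expect_identical(got, want)
  }

  # degenerate table: all lfcs identical -> sd 0, any nonzero significant lfc flags
  de5 <- data.frame(gene = c("a", "b"), lfc = c(0.5, 0.5), p_adj = c(0.01, 0.5))
  res5 <- flag_significant_genes(de5)
  expect_equal(res5$flagged, c(TRUE, FALSE))
})
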