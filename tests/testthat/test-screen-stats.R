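make_meta <- function(tissues, reps) {
  data.frame(sample_id = paste0(rep(tissues, each = reps), "_r", seq_len(reps)),
             tissue = rep(tissues, each = reps),
             replicate = rep(seq_len(reps), length(tissues)),
             stringsAsFactors = FALSE)
}

test_that("low-count filter applies the strict more-than-two-replicates rule", {
  meta <- make_meta("blood", 3)
  counts <- rbind(
    dropped   = c(49, 49, 49),  # 3 replicates below 50 -> out
    kept_two  = c(49, 49, 60),  # only 2 low -> kept
    kept_edge = c(50, 0, 0)     # 50 is not < 50; 2 low -> kept
  )
  colnames(counts) <- meta$sample_id
  res <- filter_low_counts(counts, meta)
  expect_equal(res$dropped, "dropped")
  expect_equal(rownames(res$counts), c("kept_two", "kept_edge"))
})

test_that("removal is global across samples when one tissue fails", {
  meta <- make_meta(c("blood", "meninges"), 3)
  counts <- matrix(500, 2, 6, dimnames = list(c("a", "b"), meta$sample_id))
  counts["a", meta$tissue == "meninges"] <- c(10, 10, 10)
  res <- filter_low_counts(counts, meta)
  expect_equal(res$dropped, "a")
  expect_equal(ncol(res$counts), 6)
})

test_that("size factors solve the trivial cases exactly", {
  counts <- matrix(rep(c(100, 200, 400), 3), 3, 3, byrow = FALSE,
                   dimnames = list(letters[1:3], paste0("s", 1:3)))
  expect_equal(unname(size_factors(counts)), rep(1, 3))
  counts2 <- counts
  counts2[, 2] <- counts2[, 2] * 2
  sf <- size_factors(counts2)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
})

test_that("size factors equal the brute-force median-of-ratios oracle", {
  set.seed(12)
  counts <- matrix(rpois(200 * 6, 300), 200, 6,
                   dimnames = list(paste0("sg", 1:200), paste0("s", 1:6)))
  expect_equal(size_factors(counts), oracle_size_factors(counts), tolerance = 1e-12)
})

test_that("normalization is scale-equivariant", {
  # scaling up the sample with the largest factor keeps the median anchor
  # stable, so equivariance is exact (see the methods vignette for why the
  # anchor matters)
  set.seed(13)
  counts <- matrix(rpois(100 * 4, 400), 100, 4,
                   dimnames = list(paste0("sg", 1:100), paste0("s", 1:4)))
  sf <- size_factors(counts)
  k <- which.max(sf)
  scaled <- counts
  scaled[, k] <- scaled[, k] * 5
  sf2 <- size_factors(scaled)
  expect_equal(unname(sf2[k] / sf[k]), 5, tolerance = 1e-10)
  expect_equal(normalize_counts(scaled, sf2), normalize_counts(counts, sf),
               tolerance = 1e-10)
})

test_that("size factors agree with an established median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(14)
  counts <- matrix(rpois(300 * 5, 500) + 50L, 300, 5,
                   dimnames = list(paste0("sg", 1:300), paste0("s", 1:5)))
  ours <- size_factors(counts, min_count = 0)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(counts)
  # same estimator up to the overall geometric-mean scale convention
  expect_equal(unname(ours / exp(mean(log(ours)))),
               unname(theirs / exp(mean(log(theirs)))), tolerance = 1e-6)
})

test_that("empty reference sets raise a normalization error", {
  counts <- matrix(5L, 3, 2, dimnames = list(letters[1:3], c("s1", "s2")))
  expect_error(size_factors(counts, min_count = 50),
               class = "cnscreen_normalization_error")
})

test_that("self-comparison gives zero lfc and mid-range p-values", {
  set.seed(15)
  counts <- matrix(rnbinom(600 * 6, mu = 400, size = 20), 600, 6,
                   dimnames = list(paste0("sg", 1:600), paste0("s", 1:6)))
  norm <- normalize_counts(counts, size_factors(counts, min_count = 1))
  st <- sgrna_test(norm, group_a = paste0("s", 1:3), group_b = paste0("s", 1:3))
  expect_true(all(st$lfc == 0))
  expect_true(all(st$p_low >= 0.45))
  expect_true(all(st$p_high >= 0.45))
})

test_that("strong planted depletion is detected at high counts", {
  set.seed(16)
  n_null <- 800; n_dep <- 100
  mk <- function(mu, n) matrix(rnbinom(n * 6, mu = rep(mu, 6), size = 25), n, 6)
  counts <- rbind(mk(1000, n_null), cbind(mk(1000, n_dep)[, 1:3], mk(125, n_dep)[, 4:6]))
  dimnames(counts) <- list(paste0("sg", 1:(n_null + n_dep)), paste0("s", 1:6))
  nt <- paste0("sg", 1:n_null)
  st <- sgrna_test(counts, group_a = paste0("s", 1:3), group_b = paste0("s", 4:6),
                   nt_ids = nt)
  dep <- st[!(st$sgrna_id %in% nt), ]
  expect_gte(mean(dep$p_low < 0.01), 0.95)
})

test_that("NT p-values are calibrated under the null simulation", {
  cfg <- sim_config(n_genes = 300, n_nt = 800, seed = 19,
                    tissues = data.frame(tissue = c("blood", "meninges"),
                                         bottleneck = c(4e5, 2e5),
                                         cns = c(FALSE, TRUE)))
  sim <- simulate_screen(cfg)
  flt <- filter_low_counts(sim$counts, sim$meta)
  norm <- normalize_counts(flt$counts, size_factors(flt$counts))
  nt <- nt_guides(sim$manifest)
  st <- sgrna_test(norm, paste0("blood_r", 1:3), paste0("meninges_r", 1:3),
                   nt_ids = nt)
  pnt <- st$p_low[st$sgrna_id %in% nt]
  ks <- suppressWarnings(ks.test(pnt, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
  # all-zero groups are flagged with p = 1
  norm2 <- norm
  norm2[1, paste0("meninges_r", 1:3)] <- 0
  st2 <- sgrna_test(norm2, paste0("blood_r", 1:3), paste0("meninges_r", 1:3),
                    nt_ids = nt)
  expect_true(st2$flagged[1])
  expect_equal(st2$p_low[1], 1)
})
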