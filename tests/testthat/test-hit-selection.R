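mk_summary <- function(ids, lfc, good = 0L) {
  data.frame(target_id = ids, n_sgrna = 4L,
             neg_score = 1, neg_p = 1, neg_lfc = lfc,
             neg_goodsgrna = as.integer(good),
             pos_score = 1, pos_p = 1, pos_lfc = lfc,
             pos_goodsgrna = as.integer(good),
             stringsAsFactors = FALSE)
}

test_that("CNS-versus-blood tier and the expression rescue behave at 0.85", {
  s <- list("meninges:blood" = mk_summary("geneA", -0.6))
  # not expressed: |lfc| 0.6 passes the 0.5 tier but fails the 0.85 rescue
  cfg <- selection_config(expressed_genes = "other_gene")
  expect_false("geneA" %in% select_candidates(s, cfg)$candidates)
  # expressed: included through the 0.5 tier
  cfg2 <- selection_config(expressed_genes = "geneA")
  expect_true("geneA" %in% select_candidates(s, cfg2)$candidates)
  # not expressed but |lfc| > 0.85 in a CNS-versus-blood comparison: rescued
  s2 <- list("meninges:blood" = mk_summary("geneA", -0.9))
  expect_true("geneA" %in% select_candidates(s2, cfg)$candidates)
})

test_that("other-comparison tiers use the printed strict/non-strict cutoffs", {
  cfg <- selection_config(expressed_genes = NULL)
  # |lfc| > 1 and goodsgrna >= 2
  s <- list("spleen:blood" = mk_summary("geneB", 1.1, good = 2))
  expect_true("geneB" %in% select_candidates(s, cfg)$candidates)
  # boundary: |lfc| exactly 1 fails the strict > 1 (and goodsgrna 2 is not
  # enough for the 0.6 tier, which needs strictly more than 2)
  s2 <- list("spleen:blood" = mk_summary("geneB", 1.0, good = 2))
  expect_false("geneB" %in% select_candidates(s2, cfg)$candidates)
  # |lfc| > 0.6 needs goodsgrna strictly > 2
  s3 <- list("spleen:blood" = mk_summary("geneB", 0.7, good = 2))
  expect_false("geneB" %in% select_candidates(s3, cfg)$candidates)
  s4 <- list("spleen:blood" = mk_summary("geneB", 0.7, good = 3))
  expect_true("geneB" %in% select_candidates(s4, cfg)$candidates)
  # CNS tier does not apply goodsgrna conditions
  s5 <- list("meninges:blood" = mk_summary("geneB", 0.51, good = 0))
  expect_true("geneB" %in% select_candidates(s5, cfg)$candidates)
})

test_that("threshold-selected and GO-derived lists union to the full candidate set", {
  sel_ids <- sprintf("sel_%04d", 1:1374)
  go_ids <- sprintf("go_%04d", 1:587)
  s <- list("meninges:blood" = mk_summary(sel_ids, -0.9))
  cfg <- selection_config(expressed_genes = sel_ids,
                          extra_lists = list(go_terms = go_ids))
  res <- select_candidates(s, cfg)
  expect_length(res$candidates, 1961)
  expect_equal(sum(grepl("^extra:", res$provenance$rule)), 587)
})

test_that("candidate selection is monotone in |lfc|", {
  cfg <- selection_config()
  set.seed(55)
  for (i in 1:50) {
    lfc <- runif(1, -2, 2)
    good <- sample(0:4, 1)
    cmp <- sample(c("meninges:blood", "spleen:blood"), 1)
    s <- list(mk_summary("g", lfc, good)); names(s) <- cmp
    in1 <- "g" %in% select_candidates(s, cfg)$candidates
    s2 <- list(mk_summary("g", lfc * 1.5, good)); names(s2) <- cmp
    in2 <- "g" %in% select_candidates(s2, cfg)$candidates
    expect_true(!in1 || in2)
  }
})

test_that("unknown comparison names are rejected", {
  s <- list("liver:blood" = mk_summary("g", -1))
  cfg <- selection_config(cns_comparisons = "cortex:blood")
  expect_error(select_candidates(s, cfg), class = "cnscreen_config_error")
})

test_that("essentiality calls apply all three criteria with strict inequalities", {
  nulls <- list("meninges:blood" = structure(list(sd = 0.2), class = "nt_null"))
  mk <- function(neg_lfc, good, p) {
    data.frame(target_id = "g", n_sgrna = 4L, neg_score = 0.001, neg_p = p,
               neg_lfc = neg_lfc, neg_goodsgrna = good,
               pos_score = 1, pos_p = 1, pos_lfc = neg_lfc, pos_goodsgrna = 0L,
               stringsAsFactors = FALSE)
  }
  call1 <- call_essential(list("meninges:blood" = mk(-1.2, 4L, 0.001)), nulls)
  expect_true(call1$per_comparison$facilitator)
  # boundary: lfc exactly at -3 * sd fails the strict <
  call2 <- call_essential(list("meninges:blood" = mk(-0.6, 4L, 0.001)), nulls)
  expect_false(call2$per_comparison$facilitator)
  # insufficient goodsgrna
  call3 <- call_essential(list("meninges:blood" = mk(-1.2, 2L, 0.001)), nulls)
  expect_false(call3$per_comparison$facilitator)
  # p-value boundary is strict
  call4 <- call_essential(list("meninges:blood" = mk(-1.2, 4L, 0.05)), nulls)
  expect_false(call4$per_comparison$facilitator)
  # missing null errors
  expect_error(call_essential(list("meninges:blood" = mk(-1.2, 4L, 0.001)),
                              list()), class = "cnscreen_calling_error")
})

test_that("facilitator and brake sets are disjoint per comparison", {
  set.seed(66)
  ids <- paste0("g", 1:200)
  s <- data.frame(target_id = ids, n_sgrna = 4L,
                  neg_score = runif(200), neg_p = runif(200),
                  neg_lfc = rnorm(200, 0, 1),
                  neg_goodsgrna = sample(0:4, 200, TRUE),
                  pos_score = runif(200), pos_p = runif(200),
                  pos_lfc = rnorm(200, 0, 1),
                  pos_goodsgrna = sample(0:4, 200, TRUE),
                  stringsAsFactors = FALSE)
  nulls <- list(cmp = structure(list(sd = 0.1), class = "nt_null"))
  cc <- call_essential(list(cmp = s), nulls)
  expect_false(any(cc$per_comparison$facilitator & cc$per_comparison$brake))
})

test_that("the aggregate essential flag needs support in >= 3 comparisons", {
  mk <- function(lfc) data.frame(target_id = "g", n_sgrna = 4L,
                                 neg_score = 0.001, neg_p = 0.001, neg_lfc = lfc,
                                 neg_goodsgrna = 4L, pos_score = 1, pos_p = 1,
                                 pos_lfc = lfc, pos_goodsgrna = 0L,
                                 stringsAsFactors = FALSE)
  nulls <- lapply(1:3, function(i) structure(list(sd = 0.1), class = "nt_null"))
  names(nulls) <- paste0("c", 1:3)
  two <- call_essential(list(c1 = mk(-1), c2 = mk(-1), c3 = mk(-0.1)), nulls)
  expect_false(two$aggregate$essential)
  three <- call_essential(list(c1 = mk(-1), c2 = mk(-1), c3 = mk(-1)), nulls)
  expect_true(three$aggregate$essential)
})
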