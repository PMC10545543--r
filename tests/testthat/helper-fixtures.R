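# Shared fixtures built in code: tiny manifests, count matrices and
# independent brute-force oracles used across test files.

tiny_manifest <- function(n_genes = 3, sgrnas_per_gene = 2, n_nt = 2, seed = 42) {
  build_manifest(n_genes, sgrnas_per_gene, n_nt, seed = seed)
}

# meta for a counts matrix whose columns are named <tissue>_r<rep>
meta_from_colnames <- function(counts) {
  parts <- strsplit(colnames(counts), "_r", fixed = TRUE)
  data.frame(
    sample_id = colnames(counts),
    tissue = vapply(parts, `[`, character(1), 1L),
    replicate = as.integer(vapply(parts, `[`, character(1), 2L)),
    stringsAsFactors = FALSE
  )
}

# brute-force median-of-ratios, written as direct loops over the formula
oracle_size_factors <- function(counts, min_count = 50) {
  keep <- apply(counts, 1, function(r) all(r >= min_count))
  ref <- counts[keep, , drop = FALSE]
  g <- numeric(nrow(ref))
  for (i in seq_len(nrow(ref))) g[i] <- prod(ref[i, ])^(1 / ncol(ref))
  sf <- numeric(ncol(ref))
  for (j in seq_len(ncol(ref))) sf[j] <- median(ref[, j] / g)
  setNames(sf / median(sf), colnames(counts))
}

# exhaustive binomial-tail alpha-RRA score for one gene
oracle_rra_rho <- function(percentiles, informative) {
  n <- length(percentiles)
  if (!any(informative)) return(1)
  r <- sort(percentiles)
  m <- sum(informative)
  tail_prob <- function(n, k, p) {
    s <- 0
    for (j in k:n) s <- s + choose(n, j) * p^j * (1 - p)^(n - j)
    s
  }
  best <- Inf
  for (k in seq_len(m)) best <- min(best, tail_prob(n, k, r[k]))
  best
}

# independently coded two-stage linear step-up FDR reference
oracle_bky_reject <- function(p, q = 0.05) {
  m <- length(p)
  qp <- q / (1 + q)
  step_up <- function(p, level) {
    o <- order(p)
    ps <- p[o]
    below <- which(ps <= seq_len(m) * level / m)
    r <- if (length(below)) max(below) else 0L
    rej <- logical(m)
    if (r > 0) rej[o[seq_len(r)]] <- TRUE
    rej
  }
  r1 <- sum(step_up(p, qp))
  m0 <- m - r1
  if (m0 == 0) return(rep(TRUE, m))
  step_up(p, qp * m / m0)
}
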