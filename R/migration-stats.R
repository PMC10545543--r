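## Flow-cytometry co-transfer statistics: per-animal blood-normalized
## KO/control migration ratios, the one-sample location test against the
## no-effect value 1 (t or Wilcoxon signed-rank, gated by Shapiro-Wilk
## normality), and two-stage Benjamini-Krieger-Yekutieli FDR control.

#' Blood-normalized migration ratios
#'
#' For each animal and non-blood tissue, the migration ratio is
#' `(ko/control in tissue) / (ko/control in blood of the same animal)`; 1
#' means the knockout migrates like the control. Animals are excluded from
#' a tissue's ratio when any of the four referenced populations (KO and
#' control, tissue and blood) has fewer than `min_cells` cells, or when the
#' blood row is missing.
#'
#' @param flow Data frame `animal_id`, `tissue`, `ko_count`,
#'   `control_count` containing a `blood` row per animal.
#' @param min_cells Exclusion threshold (default 100; strict `<`).
#' @return Data frame: `animal_id`, `tissue`, `ko_count`, `control_count`,
#'   `normalized_ratio`, `excluded`, `reason`.
#' @export
migration_ratio <- function(flow, min_cells = 100L) {
  need <- c("animal_id", "tissue", "ko_count", "control_count")
  if (!all(need %in% names(flow))) {
    stop_format(paste("flow table needs columns:", paste(need, collapse = ", ")))
  }
  blood <- flow[flow$tissue == "blood", , drop = FALSE]
  rows <- flow[flow$tissue != "blood", , drop = FALSE]
  bi <- match(rows$animal_id, blood$animal_id)

  ratio <- rep(NA_real_, nrow(rows))
  excluded <- rep(FALSE, nrow(rows))
  reason <- rep(NA_character_, nrow(rows))

  no_blood <- is.na(bi)
  excluded[no_blood] <- TRUE
  reason[no_blood] <- "missing blood row"

  ok <- !no_blood
  b_ko <- blood$ko_count[bi]; b_ctrl <- blood$control_count[bi]
  low <- ok & (rows$ko_count < min_cells | rows$control_count < min_cells |
                 b_ko < min_cells | b_ctrl < min_cells)
  excluded[low] <- TRUE
  reason[low] <- sprintf("<%d cells in a referenced population", min_cells)

  keep <- ok & !low
  ratio[keep] <- (rows$ko_count[keep] / rows$control_count[keep]) /
    (b_ko[keep] / b_ctrl[keep])

  data.frame(animal_id = rows$animal_id, tissue = rows$tissue,
             ko_count = rows$ko_count, control_count = rows$control_count,
             normalized_ratio = ratio, excluded = excluded, reason = reason,
             stringsAsFactors = FALSE)
}

#' One-sample location test against a hypothetical mean
#'
#' Raw values are first screened with the Shapiro-Wilk normality test at
#' `gate_alpha`: normal-looking samples get a one-sample t-test, others a
#' Wilcoxon signed-rank test (exact null for n <= 25, normal approximation
#' with continuity correction above). Summary statistics (`mean`, `sd`,
#' `n`) force the t-test: `t = (mean - mu) / (sd / sqrt(n))` with `n - 1`
#' degrees of freedom, two-sided.
#'
#' @param values Numeric vector of ratios, or `NULL` when using summaries.
#' @param mean,sd,n Summary statistics (used when `values` is `NULL`).
#' @param mu Hypothesized location (default 1 = no migration effect).
#' @param gate_alpha Normality-gate level (default 0.05).
#' @return List of class `location_test`: `method` (`"t"`/`"wilcoxon"`),
#'   `statistic`, `p_two_sided`, `n`, `mean`, `sd`.
#' @export
one_sample_location_test <- function(values = NULL, mean = NULL, sd = NULL,
                                     n = NULL, mu = 1, gate_alpha = 0.05) {
  if (is.null(values)) {
    if (is.null(mean) || is.null(sd) || is.null(n)) {
      stop_config("supply either values or all of mean, sd, n")
    }
    if (n < 2) stop_degenerate("summary t-test needs n >= 2")
    tstat <- (mean - mu) / (sd / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    return(structure(list(method = "t", statistic = tstat, p_two_sided = p,
                          n = n, mean = mean, sd = sd),
                     class = "location_test"))
  }
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop_degenerate("need at least 2 finite values")
  m <- base::mean(values); s <- stats::sd(values)
  if (s == 0) {
    if (m == mu) {
      return(structure(list(method = "t", statistic = 0, p_two_sided = 1,
                            n = n, mean = m, sd = s), class = "location_test"))
    }
    stop_degenerate("zero variance with mean != mu: test undefined")
  }
  normal <- if (n >= 3) stats::shapiro.test(values)$p.value >= gate_alpha else TRUE
  if (normal) {
    tt <- stats::t.test(values, mu = mu)
    structure(list(method = "t", statistic = unname(tt$statistic),
                   p_two_sided = tt$p.value, n = n, mean = m, sd = s),
              class = "location_test")
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(values, mu = mu, exact = n <= 25, correct = TRUE))
    structure(list(method = "wilcoxon", statistic = unname(wt$statistic),
                   p_two_sided = wt$p.value, n = n, mean = m, sd = s),
              class = "location_test")
  }
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR control
#'
#' The two-stage linear step-up procedure: stage 1 runs Benjamini-Hochberg
#' at level `q' = q/(1+q)` and estimates the number of true nulls as
#' `m0 = m - r1`; stage 2 rejects `p_(i) <= i * q' / m0`. Adjusted values
#' are the stage-2 step-up quantities (monotonized `p_(i) * m0 / i`),
#' so a hypothesis is rejected iff its adjusted value is `<= q/(1+q)`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q Target FDR level (default 0.05).
#' @return List: `rejected` (logical), `adjusted` (numeric), `m0`
#'   (estimated true nulls). Empty input gives empty output.
#' @export
adjust_bky <- function(p, q = 0.05) {
  m <- length(p)
  if (m == 0L) return(list(rejected = logical(0), adjusted = numeric(0), m0 = 0L))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_config("p-values must lie in [0, 1]")
  qp <- q / (1 + q)
  r1 <- sum(stats::p.adjust(p, "BH") <= qp)
  m0 <- m - r1
  if (m0 == 0L) {
    return(list(rejected = rep(TRUE, m), adjusted = rep(0, m), m0 = 0L))
  }
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m0 / seq_len(m))))
  adjusted <- numeric(m)
  adjusted[o] <- pmin(adj_sorted, 1)
  list(rejected = adjusted <= qp, adjusted = adjusted, m0 = m0)
}

#' Test migration ratios per tissue with FDR control
#'
#' Convenience wrapper: computes [migration_ratio()], runs
#' [one_sample_location_test()] per tissue on non-excluded ratios, and
#' applies [adjust_bky()] across tissues.
#'
#' @param flow Flow table as in [migration_ratio()].
#' @param mu Hypothesized ratio (default 1).
#' @param q FDR level (default 0.05).
#' @param min_cells Exclusion threshold passed to [migration_ratio()].
#' @return List with `ratios` (per-animal table) and `tests` (per-tissue
#'   data frame with method, statistic, p, adjusted p, rejected).
#' @export
flow_stats <- function(flow, mu = 1, q = 0.05, min_cells = 100L) {
  ratios <- migration_ratio(flow, min_cells = min_cells)
  used <- ratios[!ratios$excluded, , drop = FALSE]
  tissues <- unique(used$tissue)
  tests <- lapply(tissues, function(tis) {
    lt <- one_sample_location_test(used$normalized_ratio[used$tissue == tis], mu = mu)
    data.frame(tissue = tis, method = lt$method, statistic = lt$statistic,
               p = lt$p_two_sided, n = lt$n, mean = lt$mean, sd = lt$sd,
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  bky <- adjust_bky(tests$p, q = q)
  tests$p_adj <- bky$adjusted
  tests$rejected <- bky$rejected
  list(ratios = ratios, tests = tests)
}
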