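---
title: "Statistical methods for in vivo CRISPR migration screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for in vivo CRISPR migration screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnscreen)
```

# The experimental design this package models

In a pooled in vivo CRISPR migration screen, autoreactive CD4+ T cells are
transduced with Cas9 and a genome-wide sgRNA library (on the order of
88,000 guides: ~21,400 genes and ~400 miRNAs at 4 guides each, plus 800
non-targeting controls), kept at a multiplicity of infection below 0.3 so
that most transduced cells carry a single guide, and injected into
animals. Days later the cells are recovered from blood, spleen, spinal
cord meninges and spinal cord parenchyma, and the sgRNA composition of
each compartment is read out by sequencing. A gene whose knockout impairs
entry into the CNS (a migration *facilitator*) shows guide depletion in
meninges/parenchyma relative to blood; a *brake* shows enrichment.

Design arithmetic is deliberately simple and exposed as functions:
`plan_coverage()` (cells needed for a target per-guide coverage),
`expected_coverage()` (cells per guide actually delivered by a
transduction), and `multi_integration_fraction()`, the Poisson fraction of
transduced cells carrying more than one integration,
$(1 - e^{-m} - m e^{-m})/(1 - e^{-m})$ at MOI $m$ — about 14% at
$m = 0.3$, which is why screens cap the MOI there.

# Count processing

**Guide counting.** `count_guides()` locates the first occurrence of the
constant vector anchor (`CACCG`, the end of the U6 scaffold) in each read
and matches the following 20 nt against the library. Anchor search (rather
than fixed trimming) absorbs the staggered primer offsets used to
de-phase amplicon sequencing. Matching is exact by default: the library's
guides are unique 20-mers, and Hamming-tolerant matching (`max_mismatch`)
is opt-in and assigns a read only when a unique best guide exists.

**Filtering.** An sgRNA is dropped from all samples when more than
`max_low_replicates` (default 2) replicates of any one tissue have fewer
than 50 raw counts. Both inequalities are strict: counts of (50, 0, 0)
survive, (49, 49, 49) do not. Dropping globally (not per tissue) keeps the
same guide universe in every comparison.

**Normalization.** `size_factors()` implements median-of-ratios with a
per-sgRNA geometric-mean pseudo-reference: for reference guides $i$,
$g_i = (\prod_j c_{ij})^{1/m}$ and $s_j = \mathrm{median}_i\, c_{ij}/g_i$.
The reference set is restricted to guides with at least 50 counts in every
sample, so poorly measured guides do not steer the factors; set
`min_count = 0` to reproduce the unrestricted estimator (which then agrees
with DESeq2's `estimateSizeFactorsForMatrix` up to scale, a cross-check in
the test suite).

A note on the anchoring convention: raw median-of-ratios factors are only
defined up to the reference scale — multiplying one sample's counts by
$\lambda$ rescales every $g_i$ by $\lambda^{1/m}$ and therefore perturbs
*all* raw factors. We anchor the factors at median 1. With that convention
the intuitive behaviours hold exactly: identical samples get factors of 1,
a sample whose counts are doubled gets factor 2, and rescaling a sample
that does not straddle the median anchor scales its factor by $\lambda$
while leaving every normalized count unchanged. No symmetric
median-of-ratios definition can make that last property hold for
arbitrary samples; the anchor makes it hold whenever the rescaled
sample's rank among the factors is preserved, which is the practically
relevant case (library-size differences between sequencing runs).

# The sgRNA-level test

For a comparison "B versus A" (say meninges versus blood),
`sgrna_test()` computes per-guide fold changes
$\mathrm{lfc} = \log_2\frac{\bar c_B + 1}{\bar c_A + 1}$ on normalized
counts (pseudocount 1 keeps zeros finite; zeros are never removed) and
one-sided p-values from a negative-binomial tail. The null distribution
of the group-B mean is parameterized by the reference mean $\bar c_A$ and
the variance
$v_A(\bar c_A)/n_A + v_B(\bar c_A)/n_B$, where each group's
mean–variance function is a log–log least-squares trend fitted on the
**non-targeting guides** (the screen's own empirical null; all guides are
used as a fallback when fewer than 30 NT guides are scored). Two details
matter for calibration:

* the trend is fitted per group, because bottleneck sizes differ between
  tissues and so does the count variance at a given mean;
* the log of a sample variance on $n$ replicates is biased by
  $\psi\!\left(\tfrac{n-1}{2}\right) + \log\tfrac{2}{n-1}$ (about −0.58
  at $n = 3$); the fit removes this bias, otherwise variances would be
  underestimated by ~40% and p-values would be anticonservative.

Groups whose counts are all zero carry no information and are flagged
with $p = 1$. Rank percentiles (mid-rank of the one-sided p-values over
all scored guides) feed the gene-level aggregation.

# Gene-level aggregation: alpha-RRA with a permutation null

For a gene with member percentiles $r_{(1)} \le \dots \le r_{(n)}$,
members whose directional p-value exceeds `alpha` (default 0.25) are
non-informative; `goodsgrna` counts the informative ones. The score is

$$\rho = \min_{k \le m} \Pr[\mathrm{Binomial}(n, r_{(k)}) \ge k],$$

the best binomial-tail probability over the informative prefix
($\rho = 1$ when no member is informative). The gene p-value compares
$\rho$ with `n_perm` (default 1,000) random same-size guide sets drawn
from the scored pool, independently per gene:
$p = (1 + \#\{\rho' \le \rho\})/(n_\mathrm{perm} + 1)$, floored at
$1/(n_\mathrm{perm}+1)$.

Because $\rho$ has an atom at 1 (a fraction $(1-\alpha)^n$ of null genes
have no informative member), a plain permutation p-value would put ~32%
of null genes exactly at $p = 1$ and the null p-value distribution would
be far from uniform. We therefore break ties against the null draws
uniformly at random (the standard Monte-Carlo device for discrete
statistics): $p = (1 + \#\{\rho' < \rho\} + K)/(n_\mathrm{perm}+1)$ with
$K$ uniform on $0..\#\{\rho' = \rho\}$. The resulting null p-values are
uniform (Kolmogorov–Smirnov statistic ≈ 0.01 at 2,000 genes in the test
suite), the floor is preserved, genes with informative signal are
essentially unaffected, and the draw is reproducible from the seed.

The gene-level `lfc` is the **median** of member guide lfcs (`mean` is
available; screen-analysis tools differ between versions on this point
and the choice is deliberately exposed).

# The non-targeting pseudo-gene null and essentiality calls

`build_nt_null()` models what a "gene" made of controls looks like: 800
pseudo-genes, each averaging 4 NT guide lfcs drawn with replacement. By
the CLT the pseudo-gene SD is about half the NT guide SD; the 3-SD band
of this null is the effect-size yardstick.

`call_essential()` declares a gene a facilitator in a comparison when all
three hold (strict inequalities as printed):
`neg_lfc < -3 * sd_NT`, `neg_goodsgrna >= 3`, `neg_p < 0.05`; a brake by
the mirrored positive rule. An aggregate `essential` flag requires the
same direction in at least 3 pairwise tissue comparisons (configurable;
the multi-comparison support rule is stated in figure legends rather than
as a single formula, so it is a parameter here).

`select_candidates()` implements the tiered genome-wide-to-validation
funnel with the printed cutoffs: CNS-versus-blood comparisons admit
|lfc| > 0.5; the other comparisons admit (|lfc| > 1 and directional
goodsgrna ≥ 2) or (|lfc| > 0.6 and goodsgrna > 2); non-expressed genes
(an external list) are dropped unless a CNS-versus-blood |lfc| > 0.85
rescues them; externally derived (e.g. GO-based) lists are unioned in
verbatim. Every admission records which rule fired.

# Flow-cytometry migration ratios

`migration_ratio()` computes, per animal and tissue, the KO/control cell
ratio normalized to the same animal's blood ratio — 1 means the knockout
migrates like the control. Any referenced population (KO or control,
tissue or blood) under 100 cells excludes the animal from that tissue;
the rule is applied to all four populations since a noisy denominator
corrupts the ratio wherever it appears. `one_sample_location_test()`
gates on Shapiro–Wilk at 0.05 (the gate level is not part of the original
analysis description; 0.05 is the conventional choice and is exposed):
normal-looking samples get the one-sample t-test against 1, others the
Wilcoxon signed-rank (exact null for n ≤ 25, normal approximation with
continuity correction above). With published summary statistics the
t-test is forced; the two printed validation p-values (0.0291 and 0.0336
at n = 5) are reproduced within rounding of the printed mean/SD.
`adjust_bky()` is the two-stage Benjamini–Krieger–Yekutieli step-up:
stage 1 runs BH at $q' = q/(1+q)$ to estimate $m_0$, stage 2 rejects
$p_{(i)} \le i\,q'/m_0$; when stage 1 rejects everything ($m_0 = 0$) all
hypotheses are rejected by convention.

# TCR clonal overlap and migration propensity

After restricting to cells with exactly one detected beta chain and a
non-empty CDR3, a clone is keyed by participant and CDR3beta amino-acid
sequence (V/J gene calls can be added to the key). A cell is
*overlapping* when its clone occurs in both blood and CSF of the same
participant, and *expanded* when the clone is seen at least 3 times in
total. A cluster's *migration propensity* is the percentage of its blood
cells that are overlapping, computed within participant group (MS or
control); the denominator — blood cells of that cluster and group — is a
package choice, as the source analyses do not state it explicitly.
`correlate_propensity()` is a plain Pearson correlation (t transform,
n − 2 df) between propensity and a per-cluster quantity: mean
log-normalized expression over the cluster's MS blood cells by default,
or an externally supplied per-cluster fold change.

# What the synthetic data emulate — and what they do not

`simulate_screen()` mirrors the screen's causal structure: per replicate
(animal pool), guide cell counts are multinomial at the configured
coverage; each tissue draws its bottleneck-many cells from the shared
pool, with CNS tissues weighting a cell carrying guide $g$ against target
$t$ by $2^{\mathrm{lfc}(t)\,\cdot\,\mathrm{efficacy}(g)}$; sequencing
reads are negative-binomial around the sampled cell counts
(variance $\mu + \phi\mu^2$, default $\phi = 0.05$). Per-guide knockout
efficacy is Beta-distributed (default mean 0.8, concentration 10), so
planted genes have imperfect guides, as real libraries do. Bottlenecks
are multinomial draws conditioned on pool composition — an approximation
to without-replacement sampling that is slightly noisier, hence
conservative for recovery claims. Defaults (2,000 genes × 4 guides, 800
NT, 500× coverage, 3 replicates, bottlenecks 10⁶/2·10⁶/5·10⁵/2·10⁵ cells
for blood/spleen/meninges/parenchyma, planted |lfc| 2) are a scaled-down
version of the genome-wide design that keeps its per-guide coverage and
bottleneck ratios; the test suite and the analysis scripts state the
sizes they run.

The generator does **not** emulate: guide-sequence biology (GC content,
off-target), PCR jackpotting beyond NB dispersion, animal-to-animal
biological heterogeneity beyond independent bottleneck draws, real V(D)J
recombination statistics (CDR3 strings are arbitrary unique tags), or
transcriptome-wide expression (only configured regulator genes plus
noise). Passing recovery tests therefore demonstrate that the
*statistics* behave as designed under the modeled noise sources, not that
the pipeline is robust to every artefact of real screens.

Randomness is controlled by one integer seed per generator or pipeline
run; stage seeds are derived by hashing a stage label into an offset
(`derive_seed`), so outputs are byte-reproducible and stages are
decoupled from call order.

# Numerical choices and degenerate inputs

* NB tail evaluation at the (non-integer) group-B mean uses
  `floor` for the depletion tail and `ceiling − 1` for the enrichment
  tail, keeping both in (0, 1].
* When the modeled variance does not exceed the mean, the test falls back
  to an effectively Poisson tail (size 10⁹).
* Rank ties use mid-ranks; residual determinism comes from the fixed
  guide order.
* Zero-variance ratio samples: mean equal to the hypothesized value gives
  p = 1; otherwise the test is refused as degenerate rather than
  reporting p = 0.
* `flag_significant_genes()` with an all-identical lfc table has SD 0, so
  any nonzero significant lfc is flagged — the boundary the adaptive rule
  implies.
* Percentile ranks are divided by the number of *scored* guides, so the
  RRA null draws come from exactly the pool that generated the gene
  scores.

# Known limitations

* The sgRNA test is a moment-matched NB tail, not a full GLM; with one
  replicate per group it degrades to a Poisson-like test with no
  empirical variance.
* The permutation null draws guides with replacement from the scored
  pool; for genes whose guides dominate the pool (tiny libraries) the
  null is slightly contaminated.
* `rra_aggregate` p-values are Monte-Carlo; at `n_perm = 1000` the floor
  of ~0.001 limits how far multiple-testing correction can push gene
  significance. Raise `n_perm` for large candidate sets.
* The clonal model seeds CSF clones independently per clone; it does not
  model CSF clone sizes matching blood expansion, so expansion-dependent
  analyses beyond the ≥3 rule should not lean on the generator.
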