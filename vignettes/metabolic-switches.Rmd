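---
title: "Detecting age-related metabolic switches by pathway pairwise comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting age-related metabolic switches by pathway pairwise comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboswitch)
library(dplyr)
```

## The problem

Metabolic reprogramming is a hallmark of both aging and cancer. A
recurring observation in aged tumors is a Warburg-like shift — glycolysis
gains at the expense of oxidative phosphorylation — but single-pathway
contrasts between age groups are fragile: absolute pathway activity rides
on library size, platform, and per-sample batch effects, and a pathway's
activity is only meaningful relative to the metabolic alternatives the
cell could have used. `metaboswitch` therefore works on *pathway pairs*:
within each sample it records only which pathway of a pair is more active,
and asks whether that within-sample preference is redistributed between
age groups. We call a pair whose dominance flips with age a *metabolic
switch*.

## Model and assumptions

### Activity scores

For a pathway $P$ with member genes $g$ and nonnegative weights $w_g$, the
activity in sample $s$ is

$$A(P, s) = \frac{\sum_{g \in E(P)} w_g\, x_{g,s}}{\sum_{g \in E(P)} w_g},$$

where $E(P)$ is the set of member genes *expressed* in the cohort (nonzero
in at least one sample; the count is configurable) and $x_{g,s} =
\log_2(v_{g,s} + 1)$ for linear-scale input (TPM/FPKM), or the raw value
for input already on log scale. The log transform matters: without it the
mean is dominated by a few high-abundance genes, and the downstream
dominance calls are sensitive to monotone transforms *across* pathways
even though they are invariant to per-sample ones.

A pathway is scored only if at least 30% of its genes are expressed
(inclusive boundary: 3 of 10 genes is enough). The gate protects the score
from being an average over one or two stray genes. "Expressed" is defined
at the cohort level — detectability, not per-sample abundance — because
the score already handles per-sample zeros.

### PPI weights

Weights default to 1. When a within-pathway protein–protein interaction
edge list is supplied, `attach_ppi_weights()` sets

$$w_g = \mathrm{floor} + \frac{\deg_P(g)}{\max_{h \in P} \deg_P(h)},$$

with $\deg_P$ the weighted degree in the subgraph induced by $P$'s genes,
and uniform weight 1 for pathways whose induced subgraph has no edges.
With the default floor of 1, a hub gene counts at most twice a peripheral
gene: the weighting is bounded, robust to scale-free degree tails, and
degenerates gracefully to the unweighted mean. Published PPI-weighted
scoring schemes differ in detail and the exact upstream formula is not
recoverable; this choice is deliberately isolated in one function so an
alternative scheme can be swapped in without touching the rest of the
pipeline.

### Dominance and its batch-effect contract

For a pair $(A, B)$ and sample $s$, the call is
$+1$ if $A(A,s) - A(B,s) > \tau$, $-1$ if $< -\tau$, else $0$, with
absolute tie tolerance $\tau = 10^{-9}$ (exact float equality is fragile;
ties carry no information and are excluded downstream, not split). Because
the comparison is entirely within one sample, any per-sample strictly
monotone transformation of all pathway scores — an affine rescaling, a
library-size effect, a monotone normalization — leaves every call
unchanged. This is the property that substitutes for explicit batch
correction, and it is asserted directly in the test suite with random
per-sample affine maps.

### Group contrast and test choice

Samples are grouped by age either by cohort-specific quartiles (young:
age ≤ Q1, old: age ≥ Q3, interpolated type-7 quantiles, boundary samples
in the extreme group) or by fixed thresholds with half-open intervals
([0, 50) young, [50, 65) middle, [65, ∞) old — so age 50 is middle and 65
is old). The default contrast is young vs old; middle samples are retained
in the metadata but excluded from the two-group test, with r×2 tables
supported for three-group designs.

Non-tie calls form a group × {first, second} table. The test is:

* chi-square test of independence, no continuity correction, when every
  expected count is ≥ 5 (Fisher covers small tables, so Yates' correction
  would only double-penalise);
* Fisher's exact test for 2×2 tables below that;
* a seeded Monte-Carlo permutation p (default 10,000 draws) for r×2
  small-count tables — reproducible and tractable where the exact
  Freeman–Halton test is not.

Degenerate tables (an empty group or an empty dominance column) return
p = 1, direction `none`, and a flag. p-values are Benjamini–Hochberg
adjusted across all pairs of one cohort; significance is strict
(`adjusted_p < alpha`, so 0.05 exactly is dropped).

### Odds ratio and direction

With rows young→old and columns first/second-dominant, the cross-product
odds ratio $(a d)/(b c)$ equals
$\mathrm{odds}(\text{first} \mid \text{young}) /
\mathrm{odds}(\text{first} \mid \text{old})$. The Haldane–Anscombe +0.5
correction is applied to all four cells when any cell is zero, keeping the
ratio finite and the row-swap identity exact (swapping group rows inverts
the OR and flips the direction). We report direction as the pathway
*gaining* dominance in the older group: OR > 1 means first-dominance is
depleted with age (`toward_second`), OR < 1 the reverse. For r×2 tables
the OR and direction come from the youngest/oldest margin, matching the
pairwise-group usage of odds ratios.

### Network and hubs

Each cohort contributes its top `k = 200` significant events (ascending
adjusted p, ties broken by pair id) as edges. Cohorts are *not* collapsed:
the same pair recurring in several cohorts yields parallel edges, so node
degree measures recurrence. Weighted degree sums $-\log_{10}(\text{adjusted } p)$
clipped at 50 (an adjusted p of exactly 0 would otherwise be infinite).
Hub ranking is by degree, then weighted degree, then pathway id —
a deterministic surrogate for the visual hub criterion of force-directed
layouts. Betweenness (exact Brandes, unnormalized pair counts) is computed
on the collapsed simple graph and reported as an auxiliary attribute, not
a ranking key.

### ssGSEA and R~o/e~

The immune-infiltration view uses the classic rank-weighted single-sample
enrichment statistic: genes ranked by expression descending (ties by gene
id), members increment a running sum by their rank weight $r^{\alpha}$
normalized within the signature ($\alpha = 0.25$, the conventional
exponent, exposed as an argument), non-members decrement by
$1/(N - |S|)$, and the score is the sum of running-sum deviations; scores
are min–max rescaled to [0, 1] across the run. A Gaussian-kernel variant
of the rank CDF exists in some implementations; we implement the plain
rank statistic because only ordering and group contrasts are consumed
downstream, and the rank statistic is exactly invariant to monotone
per-sample transforms. Signatures with no gene in the matrix are flagged
`NA`, never silently scored.

Cell-type enrichment by group is the ratio of observed to expected counts
under independence, $R_{o/e} = O_{tg} / (R_t C_g / N)$; values above 1
mark enrichment. The expected-count-weighted mean of each cell type's
$R_{o/e}$ across groups is identically 1 (mass conservation), which the
tests assert to $10^{-12}$ on random tables.

### Single-cell QC

The five-rule filter drops a cell iff UMIs < 200 or > 20,000, detected
genes > 4500, mitochondrial percentage > 10, or gene-to-UMI ratio < 0.8 —
all comparisons strict, so boundary cells are kept. The gene-to-UMI ratio
is interpreted as the standard per-cell complexity score
$\log_{10}(\text{genes})/\log_{10}(\text{UMIs})$: a *raw* genes/UMI ratio
of 0.8 would reject essentially every genuine cell (a 5000-UMI cell would
need 4000 distinct genes), whereas the log-ratio threshold of 0.8 is the
conventional novelty cutoff. The raw mode is available via
`ratio_mode = "raw"` for datasets that define it differently. An optional
per-cell doublet flag column (from an external caller) drops flagged cells
after the five rules.

## What the generators emulate — and what they do not

`simulate_bulk_cohort()` produces log-scale expression
$x_{g,s} = \text{baseline}_g + \text{effect}_{g,s} + \mathcal N(0, \sigma)$
with per-gene baselines uniform on [2, 8] (a realistic log2 abundance
spread), noise $\sigma = 0.5$, and cohorts of 30 young + 30 old samples —
the default study conditions used throughout the tests. A planted switch
$(A, B, \delta)$ adds $\delta$ to all of $A$'s genes in young samples and
to all of $B$'s genes in old samples, reversing the pair's dominance.
Effects are planted at the gene level so the coverage gate, weighting and
scoring path are all exercised, with one structural consequence: a
gene-level effect on pathway $A$ genuinely perturbs *every* pair
containing $A$, not just the designated partner. The truth table therefore
records both the planted pairs (the sensitivity denominator) and the full
set of affected pathways; `score_switch_recovery()` counts as false
positives only discoveries among pairs of two *unaffected* pathways.
Ages are drawn in disjoint bands (35–49 and 66–80) so quartile grouping
never contradicts the generating labels.

At the default conditions ($\delta = 1$, $\sigma = 0.5$, 20 genes per
pathway) the pair signal shift is $\pm 1$ log2 unit against a score noise
of $\sigma/\sqrt{20} \approx 0.11$, so planted pairs are recovered with
sensitivity above 0.9 unless the two pathways' random baselines happen to
differ by more than the shift — a few percent of plants — while BH keeps
the truly-null false discovery fraction well under 0.1.

The **null-calibration experiment** deserves its own note. With random
baselines, a null pair's two pathways almost always differ by a fixed
offset larger than the noise, every sample gives the same call, and the
table is degenerate — the test (correctly) reports p = 1 and nothing is
learned about calibration. The calibration cohort therefore fixes a
common baseline (`baseline_mean_range = c(5, 5)`), making the designated
pair's dominance a fair per-sample coin flip; with 50 + 50 samples every
replicate then takes the chi-square path, and the rejection rate at
nominal 0.05 over 1000 seeded replicates falls inside the exact binomial
99% interval.

`simulate_sc_cohort()` draws each cell's UMI total from a negative
binomial per cell type (mean 2000, size 10), clamped to a QC-safe band
[500, 9000], and spreads it over a concentrated per-type gene-frequency
profile (log-normal, sd 2.5, 10,000 genes, a fixed 2% mitochondrial
share). The concentration is a contract, not a tuning: under it the
expected distinct-gene count stays below ~1900 even at the largest totals
(threshold 4500) and the complexity ratio above ~0.82 (threshold 0.8), so
*every* baseline cell passes the filter and the planted-violator exactness
check is meaningful. Violators are deterministic count vectors breaking
exactly one named rule each with a wide margin (e.g. UMI total 80 against
the 200 floor; 9000 detected genes against the 4500 cap; 30% mitochondrial
reads against the 10% cap). Cell-type composition per group follows the
requested frequencies exactly by largest-remainder rounding.

Neither generator attempts realistic transcriptomes: there is no gene–gene
correlation, no batch structure, no doublets, no zero-inflation beyond the
multinomial. Passing tests demonstrate that the statistical machinery does
what it claims under its own model — they do not certify performance on
real data, where pathway co-regulation will correlate pair signals and
make the effective number of independent tests smaller than the pair
count.

## Numerical choices

* Tie tolerance $10^{-9}$ absolute; ties excluded from tables.
* Quartiles are interpolated (type 7); boundary samples join the extreme
  group so the young/old sets are never silently empty.
* Haldane–Anscombe +0.5 on all cells only when some cell is zero.
* `min_expected = 5` routes tables between chi-square and exact/permutation
  paths; the permutation path requires an explicit seed and refuses to run
  without one.
* $-\log_{10}(p)$ clipped at 50 in weighted degree.
* BH is applied over all tested pairs of one cohort (or one cell type),
  never pooled across cohorts.
* The two-group scan is vectorised (closed-form 2×2 chi-square); the test
  suite asserts it is exactly equal, p-value for p-value, to the per-pair
  route through `chisq.test()`/`fisher.test()`.

## Problem sizes used in the checks

The test suite and the acceptance script run: planted-switch recovery on
50 pathways × 20 genes (1225 pairs), 30 + 30 samples, 10 planted pairs,
averaged over 20 seeds; null calibration on 1000 replicates of a
2-pathway, 50 + 50-sample cohort; QC exactness on 5000 cells with 1%
violators per rule; and oracle cross-checks on 100–250 random instances
per statistic. These sizes give stable estimates (binomial standard error
≈ 0.007 at 1000 replicates) while keeping a full run around a minute.

## Known limitations

* Dominance discards effect magnitude; a switch says which pathway wins,
  not by how much. Pair activity differences are available via
  `pair_covariate_association()` when magnitude matters.
* Covariate-adjusted (stratified) switch tests are out of scope; the
  grouping is the only design variable.
* The PPI weighting is one defensible choice among several; it is
  intentionally swappable.
* The r×2 permutation p is Monte-Carlo, so its resolution is 1/B; raise
  `n_perm` for small target levels.
* Gene identifiers are opaque case-sensitive symbols; no alias mapping is
  performed.
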