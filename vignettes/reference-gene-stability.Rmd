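---
title: "Evaluating RT-qPCR reference genes: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating RT-qPCR reference genes: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

RT-qPCR quantifies a target gene *relative* to reference genes assumed to
be uniformly expressed. That assumption fails often enough — across
tissues, sexes, treatments — that candidate references must be screened
per experiment. `refstab` implements the four screening methods in common
use plus a consensus, and the downstream quantification they feed. This
vignette records the models, the tunable constants, and the design
decisions taken where conventions diverge.

## Data model and conventions

A `ct_matrix` is genes × samples of quantification-cycle values with a
group label per sample. Ct is log2-linear in template amount under perfect
doubling, which is why most of the machinery below works directly on the
Ct scale. Three conventions apply everywhere:

* **Canonical order.** Gene and sample order is first occurrence in the
  input. Every tie — equal stability values, equal M at a GeNorm
  exclusion step — is broken by this order, making all rankings
  deterministic.
* **Technical replicates** (when a `replicate` column is present) are
  collapsed to their arithmetic mean Ct per (gene, sample) at load time.
  Stability methods then see biological samples only. This mirrors common
  practice; nothing in the methods themselves wants technical replicates
  as separate columns.
* **Missing cells are an error**, not silently imputed: the stability
  estimators assume a complete matrix, and a cell imputed from the very
  statistics being estimated biases them invisibly. An opt-in `impute`
  flag fills a missing cell with the gene's same-group mean and logs
  every imputation.
* **Sample SDs use the n − 1 denominator** throughout, matching the
  source methods. The one deliberate exception is BestKeeper (below).

## The four stability methods

**Comparative ΔCt.** Stability of gene *i* = mean over partners *j* of
the sample SD of (Ct_i − Ct_j). No normalization is required because
differencing removes per-sample loading effects.

**GeNorm.** Relative quantities `q = E^−ΔCt` with ΔCt taken to the
per-gene minimum over the analyzed samples (so subsetting samples changes
q but not any log-ratio statistic). Internally the package computes
`log2 q = −ΔCt·log2(E)` directly, which avoids an exp/log round trip; at
E = 2 the initial M value is then *algebraically* identical to the
comparative ΔCt stability, a cross-method identity the test suite asserts
to 1e−12. Exclusion iterates on the highest M (ties: the later gene in
canonical order is removed) until the final, inseparable pair; the
reported per-gene M is the value at the gene's exclusion step, so the top
pair shares one M, reproducing the pattern of published stability tables.
An option reports full-set M instead. The unsuitability flag (default
M > 1.5) applies to the reported per-gene M, not the full-set M: one
wildly unstable candidate inflates the full-set M of every sound gene,
which would flag the entire panel.

Normalization factors NF_n use the top n genes by exclusion order;
V_n/n+1 = SD(log2(NF_n/NF_n+1)). The optimal reference count is the
smallest n with V *strictly* below the cutoff (default 0.15); when no n
qualifies, the count falls back to k with an explicit `cutoff_met = FALSE`
flag rather than a silent answer.

**NormFinder.** Operates on Ct directly (already log-scale). Ungrouped:
two-way centered residuals give per-gene variances u_i; the estimator
`σ̂²_i = (k/(k−2))·(u_i − Σu/(k(k−1)))`, clipped at zero, corrects for the
fact that every gene's residuals absorb a share of the other genes'
variation; SV_i = √σ̂²_i. Grouped: the same estimator within each group,
plus per-(gene, group) deviations d̂ shrunk toward zero by the estimated
between-gene variance of group differences; SV averages |d̃| with the
corresponding standard-error term. Numeric identity with the original
Excel implementation is not claimed; the contract is the formulas above,
verified against an independent brute-force implementation (explicit
loops, no shared code) to 1e−12, plus rank agreement on simulated data.
Grouped mode requires ≥ 2 groups of ≥ 2 samples; k ≥ 3 always (the
estimator divides by k − 2).

**BestKeeper.** Descriptive dispersion of raw Ct. Following the original
tool's documented convention, "SD" is the **mean absolute deviation** from
the arithmetic mean and CV = 100·SD/mean; a flag switches to the n − 1
standard deviation. Only CV and SD are computed — the original tool's
crossing-point index and pairwise correlations are out of scope. Note
BestKeeper is the one method sensitive to additive shifts: it measures raw
Ct spread, so per-sample loading offsets count against every gene equally,
and CV depends on the gene's mean Ct.

## Consensus

Each method's stability values become ordinal ranks 1..k (ties by
canonical order — the tie convention under which published comprehensive
values are exactly reproducible, whereas the per-method columns of such
tables typically print dense ranks; the package outputs both, labelled).
The comprehensive value is the geometric mean of the four ranks, final
ranking ascending, and the recommendation is the top GeNorm-optimal-n
genes (overridable). Geometric-mean aggregation is monotone: improving
any single method rank strictly improves the comprehensive value.

## Quantification

Efficiency: OLS of Ct on log10(amount), replicates as individual points,
`E = (10^(−1/slope) − 1)·100%`, R² computed directly from residuals. E
outside 90–110% or R² < 0.90 warn but never error (practitioners accept
wider bands; both bounds are arguments). A 3-point collinear series with
fivefold dilution every 2 cycles has the closed form E = (√5 − 1)·100 ≈
123.61%, which the tests pin down.

2^−ΔΔCt: the reference signal per sample is the arithmetic mean Ct of the
reference genes — exactly the log of the geometric mean of their relative
quantities, i.e. the GeNorm NF convention (the combination rule for
multiple references is rarely stated in papers; this is the defensible
one). Group summaries are mean and SD of per-sample fold changes by
default, with a flag to summarize ΔΔCt on the log scale instead.

## Motif classification

Patterns are ordered windows on the residues *strictly between*
consecutive conserved cysteines (a literal reading of the Cys-X_n-Cys
notation: X_30 means positions differ by 31). The matcher does
depth-first search over cysteine positions and returns every satisfying
subsequence; an independent exhaustive-enumeration oracle checks it in the
tests. Two deliberate defaults:

* Published spacings that are single observations (classic, plus-C, two
  of the CSP gaps) are widened by ±2 residues when the gap exceeds 10
  (long loops vary between species; short spacings are structurally
  rigid). Both the tolerance and the 10-residue boundary are arguments.
* Non-matched cysteines inside a gap are permitted by default — the
  patterns describe *conserved* cysteines and family members may carry
  extras; `strict = TRUE` enforces the no-Cys reading of X.

When several patterns of equal cysteine count match, all labels are
returned rather than picking silently; more-cysteine patterns win over
fewer (plus-C > classic > minus-C/CSP). Signal peptides are not
predicted; a `mature_start` argument lets callers strip them.

## The simulator and what it does (not) show

`simulate_ct()` draws `Ct = B_i + s_j + δ_ig + ε_ij`: per-gene baselines
(Uniform 18–30 cycles), a shared per-sample loading offset (SD 0.5
cycles — the nuisance reference genes exist to absorb), group shifts for
regulated genes, and per-gene noise. The true instability score is
`sqrt(Var_g(δ) + σ²)`, the cycles² scale all the methods operate on. The
benchmark preset uses ten genes over 2 groups × 9 samples: two stable
genes (σ = 0.1), four noisy (σ = 0.5–2.0) and four shifted (±0.5–2.0
cycles, σ = 0.3). The shifts alternate in sign deliberately: relative
quantification cannot distinguish a shift common to the whole panel from
a loading offset, so a panel whose regulated genes all move the same way
would make the truth score unidentifiable *in principle* — and real
condition-responsive genes move both ways. One seeded stream with a
fixed draw order (baselines, offsets, noise) makes runs byte-reproducible.

On this benchmark all four methods place both designed-stable genes in
their top 3 and correlate with the true order at Spearman ≥ 0.8 (seed 42;
nearby seeds behave alike). NormFinder enters this comparison in
ungrouped mode: the truth score is precisely the ungrouped estimand,
whereas the grouped stability value is linear — not quadratic — in the
group shift, so it orders genes by a different (equally legitimate)
criterion; grouped mode is exercised separately for top-3 placement and
drives the consensus recommendation.

What the simulation does *not* emulate: amplification-curve artifacts,
inter-plate effects, efficiency differences between genes (the stability
methods assume one global base, default 2), and non-Gaussian outliers.
Passing the benchmark shows the estimators are implemented correctly and
recover a known additive-Gaussian structure; it does not certify behavior
on data violating those assumptions.

## Problem sizes and numerics

The test suite runs its property checks on matrices of 2–20 genes ×
3–30 samples (hundreds of random instances), the benchmark at 10 × 18,
and the motif oracle on 500 random proteins of ≤ 60 residues — sizes at
which the brute-force oracles are exact and fast. Degenerate inputs are
errors with named cells (< 2 genes, < 3 samples, missing/non-numeric Ct,
singleton groups in grouped NormFinder, < 3 distinct dilution amounts,
zero standard-curve slope); an all-constant Ct matrix is *valid* and
yields zero stability everywhere, the analytic limit.
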