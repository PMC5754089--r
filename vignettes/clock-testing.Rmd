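---
title: "Testing the molecular clock on Bayesian tree ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the molecular clock on Bayesian tree ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksclock)
```

## The model

Under a strict molecular clock with a Poisson substitution process, the
number of substitutions accumulated on a branch is Poisson distributed, and
— for a reasonably balanced topology in which branches span comparable time
intervals — the counts pooled across all branches follow a single Poisson
law with some mean λ. Branch lengths inferred by a Bayesian sampler are
expressed in expected substitutions per site; multiplying by the alignment
length and rounding converts them to integer counts on which the Poisson
hypothesis is testable.

`ksclock` tests this hypothesis on the *posterior ensemble* of trees rather
than on a consensus tree. The ensemble view has two consequences that shape
the whole package:

1. **More information, but not unlimited.** Pooling branch lengths across τ
   trees gives a sample of N = τ·B counts, yet the underlying alignment is
   finite: N can be inflated at will by drawing more MCMC samples, while the
   distance between the empirical CDF and the best Poisson fit converges to
   a positive constant whenever the model is even slightly misspecified.
   Unchecked, every phylogeny would eventually be "rejected". The τ-selection
   rule (below) and the effective-sample-size adjustment keep the test
   honest.
2. **Dependence.** Successive MCMC trees are autocorrelated, and in a
   clock-constrained tree the branch lengths are mutually constrained by
   ultrametricity. Both effects reduce the information content of the
   nominal sample; both are absorbed into the adjustment coefficient
   k = T_ESS/T estimated from the tree-length trace.

### The one-sample (PKS) test

For pooled discretized counts with empirical CDF F_N and mean λ̂, the
statistic is `D_PKS = sup |F_N(x) − P(x, λ̂)|` with P the Poisson CDF.
Because λ̂ is estimated from the same data and the distribution is discrete,
the classical Kolmogorov null distribution does not apply — using it would
be strongly conservative. The package draws the null distribution by
parametric bootstrap: each replicate simulates n IID Poisson(λ̂) counts,
re-estimates the mean, and recomputes the statistic. Critical values are
empirical quantiles; p-values carry a +1/(reps+1) continuity correction so
they are never exactly zero. The default of 10,000 replicates puts the
Monte-Carlo error of a 1% critical value in the third decimal; the
acceptance script uses 100,000 for an extra digit of stability.

### The two-sample (2KS) test

When the topology is unbalanced the pooled counts are a *mixture* of Poisson
laws and the PKS test rejects for the wrong reason. The two-sample route
compares the continuous (undiscretized) branch-length distributions of an
unconstrained ensemble and a clock-constrained one — strict or relaxed —
using `D(N, M) = sup |F_N − G_M|`. At the adjusted sample sizes arising in
practice (hundreds to tens of thousands) the asymptotic Smirnov critical
value `c(α)·√((N+M)/(N·M))`, `c(α) = √(−ln(α/2)/2)`, and the
Kolmogorov-series p-value are accurate; the package uses them rather than
exact small-sample distributions. The package reproduces all six published
1% critical values of this form at their printed precision, which is how
this design choice was validated.

### The likelihood-ratio baseline

For comparison, `run_lr_test()` applies the classical test: 2ΔL = −2(L₁−L₀)
against the χ² quantile with S−2 degrees of freedom. The log-likelihoods of
the clock and non-clock consensus trees are computed upstream by the
phylogenetic software; the package deliberately contains no likelihood
machinery.

## Tunable parameters

* **`burnin`** (fraction of leading trees discarded; default 0.25). Bayesian
  practice discards at least 25%; analyses of well-mixed chains often use
  50%. The first `ceiling(fraction·T)` trees are removed.
* **`alpha`** (default 0.01). The reporting threshold used throughout the
  published tables.
* **`reps`** (default 10,000) — bootstrap replicates; see above.
* **`alignment_length`** — the number of sites; it is the discretization
  scale and must match the alignment the trees were inferred from.
* **`ess_override`** — an externally computed T_ESS (e.g. reported by the
  sampler's diagnostics). When absent, T_ESS is estimated from the
  tree-length trace.
* **`tau_rule`** in `run_ks2_test()` — `"min-d"` applies the same prefix-scan
  rule as the PKS test to the two-sample statistic; `"all"` pools every post
  burn-in tree. The prefix rule is the default for symmetry with the
  one-sample test; the statistic under the null is insensitive to the
  choice, but `"all"` is the natural option when the two chains are known to
  be well mixed.

## τ selection and its consequences

τ is the smallest number of pooled trees satisfying (i) τ ≥ number of taxa
and (ii) the test statistic is minimal over prefixes of the chain in
sampling order. Prefixes (rather than random subsets) make the rule
deterministic and reproducible. Ties favour the smallest τ.

Selecting the minimizing τ makes the realized statistic stochastically
*smaller* than that of a fresh sample of the same size, so the test is
conservative by construction: in calibration runs the type-I error at
nominal 1% and 5% stays at or below the nominal level (within Monte-Carlo
error of 200 seeded runs), rather than centred on it. This is the intended
trade-off — the rule exists to prevent sample-size inflation from
manufacturing rejections, and a conservative strict-clock test errs on the
side of not discarding the clock.

## Numerical choices

* **Rounding.** Discretization rounds half-up (`floor(x·L + 0.5)`): 0.5
  becomes 1. The convention is stated so results are bit-reproducible;
  branch lengths landing exactly on .5 boundaries are measure-zero in
  practice.
* **Supremum evaluation.** The sup of |F − G| between step functions can
  occur just before a jump, so both one-sided limits are evaluated at the
  union of the jump points of both functions. For Poisson and mixture CDFs
  the jump set is truncated at the smallest integer m with
  1 − CDF(m) < 1e-12, which bounds the scan without affecting any reported
  digit. For two empirical samples the classical union-of-order-statistics
  evaluation is exact, including under ties.
* **ESS estimator.** T / (1 + 2·Σρ̂(t)) with the autocorrelation sum
  truncated at the first non-positive lag (initial positive sequence), lags
  capped at 2,000, and the result clamped to (1, T]. A constant trace is an
  error rather than a silent k = 1.
* **Quantiles.** Bootstrap critical values use the default interpolation
  quantile (type 7); at ≥ 10,000 replicates the difference between quantile
  conventions is below reporting precision.
* **Series truncation.** The Kolmogorov p-value series stops when a term
  drops below 1e-10 and the result is clamped to [0, 1]. The Smirnov
  coefficient inverts only the leading series term, so critical value and
  p-value are mutually consistent to about 1e-4 at conventional levels.
* **Degenerate inputs.** λ̂ = 0 (all counts zero) gives a degenerate null:
  critical value 0 and D = 0, so the clock is never rejected on an empty
  signal. Adjusted sizes are floored at 1. Burn-in that would empty the
  ensemble is an error.

## Design decisions that were genuinely open

* **Outgroup pruning.** The outgroup's terminal branch sits on the path to
  the root and is systematically long; it must be excluded. What happens to
  the attachment node is a real choice: merging its two remaining edges
  (summing lengths) changes the branch-length sample, while keeping the node
  as a root preserves the remaining B−1 lengths unchanged. The published
  branch-count arithmetic (15 → 14 branches for the nine-taxon example)
  implies the keep convention, which `prune_outgroup()` implements: the
  outgroup edge's length is discarded, nothing is merged. Users wanting the
  merge convention can pre-process trees with `ape::drop.tip()` directly.
* **Bootstrap rather than published tables.** Printed critical values for
  the Poisson KS test with estimated mean exist (Campbell–Oprian) but are
  table lookups with limited coverage; exact algorithms exist but add heavy
  machinery. The parametric bootstrap is self-contained, applies at any
  (λ, n), and converges to the exact null. The acceptance checks compare
  the bootstrap against published per-dataset critical values: it matches
  0.16 at (λ = 5.36, n = 30) but concentrates near 0.049 where 0.04 is
  printed for (λ = 5.75, n = 343); the discrepancy is consistent with
  table-interpolation error in the source rather than with the bootstrap,
  and is reported, not hidden.
* **Power bound.** The power of a KS-type test against a fixed alternative
  at sup-distance δ from the null CDF is bounded below via the DKW
  inequality: `1 − 2·exp(−2n(δ − D_α)²)` for δ > D_α, else 0. This is the
  bound reported in `pks_result$power_lower_bound`, evaluated at the plug-in
  alternative δ = D_PKS; it is conservative for discrete data.
* **ESS source.** The package recomputes ESS from the tree-length trace so
  that tree files are the only required input; sampler-reported values can
  be injected via `ess_override` when exact agreement with a sampler's
  diagnostics is wanted. Each ensemble in the two-sample test is adjusted by
  the coefficient of its own trace.
* **Degrees of freedom.** The LR test reports ν = S−2 and the matching χ²
  quantile. (Published tables occasionally pair a quantile with an
  off-by-one df label; the package always reports the pair it computed.)

## The synthetic generator

`simulate_clock_ensemble()` and `simulate_mixture_ensemble()` emulate the
features of a posterior ensemble that the tests actually consume: a fixed
topology, integer substitution counts with a controlled marginal law, and
between-tree autocorrelation mimicking an MCMC chain. Counts are generated
per edge by an INAR(1) chain — binomial thinning of the previous count plus
a Poisson innovation — which preserves the Poisson(λ) marginal *exactly*
while giving lag-1 autocorrelation ρ, so the ESS adjustment can be
calibrated against the closed form k = (1−ρ)/(1+ρ). Over-dispersed
alternatives use a negative-binomial marginal with a stated variance-to-mean
ratio; since thinning does not preserve that marginal, over-dispersed
ensembles are generated IID (ρ = 0 only). Given a configuration and seed the
generator is fully deterministic.

What the generator does *not* emulate: sequence-level evolution (no
substitution models, no sites), topology uncertainty (every tree shares the
topology), the ultrametric coupling of branch lengths inside a
clock-constrained posterior, and the posterior correlation between branches
within a tree. Passing calibration on synthetic ensembles therefore shows
that the statistics, null distributions and adjustments behave as designed
on data satisfying their assumptions — not that real posteriors satisfy
those assumptions.

## Problem sizes in the test suite

Calibration tests run at deliberately modest sizes chosen to give stable
Monte-Carlo verdicts: type-I calibration uses 200 runs of 30-tree, 6-taxon
ensembles with 1,000 bootstrap replicates each; power calibration uses 25
runs of the 15-edge bimodal mixture; ESS recovery uses 5,000-tree traces;
the published-value checks use 100,000 bootstrap replicates. The complete
suite runs in about a minute on one core.

## Known limitations

* Critical values and p-values for the PKS test are Monte-Carlo estimates;
  two runs with different seeds differ within bootstrap error. Seeds are
  threaded through every entry point for exact reproducibility.
* The 2KS p-value is asymptotic; below a few dozen observations per sample
  it should not be trusted (the package does not refuse, but the vignette
  does warn).
* The τ-selection rule makes both tests conservative (see above).
* Relaxed-clock ensembles are inputs, not outputs: the package does not fit
  clock models. The "distance-from-root" variant of the one-sample test is
  not implemented.
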