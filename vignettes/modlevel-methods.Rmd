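---
title: "Methods: estimating RNA modification levels from fractionated counts"
author: "modlevel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating RNA modification levels from fractionated counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modlevel)
```

## The estimation problem

Antibody-driven separation of intact RNA splits a pool into an input, an
eluate (modified molecules) and a supernatant (unmodified molecules), each
turned into a gene × sample table of read counts by RNA-seq. Read counts
measure abundance only up to library scale, so the modified proportion of a
gene cannot be read off the eluate/supernatant ratio directly: one must
know how the fractions relate to each other. `modlevel` estimates, per
gene, the proportion α of modified molecules together with the gene's
expression, while simultaneously resolving that cross-fraction scale —
either from the data (spike-in-free mode) or from unmodified spike-ins
added in equal amounts to both fractions after the immunoprecipitation
(spike-in mode).

## Model and assumptions

With μ the log expected input count and γ = logit(α) the log-odds of
modification, expected relative abundances are e^μ (input), e^μα (eluate)
and e^μ(1−α) (supernatant), so eluate and supernatant always recompose the
input. This presumes a high-efficiency pull-down with negligible
cross-contamination between fractions; leakage of unmodified molecules
into the eluate (or vice versa) would bias α toward the contaminating
fraction, and the model has no term to absorb it.

Counts are negative binomial with mean
`depth[sample] × scale[fraction] × abundance` and a single size parameter
θ shared by all genes and samples (Var = m + m²/θ; the size–mean
convention — stated explicitly because the p/r convention differs). A
shared θ is a deliberate simplification: it stabilizes the per-gene fits
at the expense of ignoring gene-specific dispersion.

Fitting works on the (μ, γ) scale rather than (μ, α): both gene
parameters then live on an unbounded logarithmic scale, which plays well
with box-constrained quasi-Newton steps and makes profile likelihoods
close to quadratic for well-covered genes. α is a derived, reported
quantity, and interval bounds for α are the monotone transforms of the γ
bounds.

## Parameters that matter

* `gamma` box ±20 (dimensionless log-odds), so α stays inside
  (≈2e-9, 1−2e-9): a gene with zero counts in one fraction gets a finite,
  flagged boundary estimate instead of ±∞.
* `mu` box [log 0.1, log 1e9] (log counts): generous, but prevents the
  optimizer from wandering to degenerate means.
* θ searched on log scale over [1e-3, 1e12]; the upper decades are
  effectively Poisson.
* Filter threshold 100 (mean read count, strictly greater-than) across
  the input samples, or across all eluate and supernatant samples in
  spike-in mode; genes at exactly the threshold are dropped. Spike-ins
  face their own minimum mean count (default 100) to enter the scale
  factor or the ratio baseline.
* Convergence: relative change of the total log-likelihood below 1e-8,
  at most 50 outer iterations (both configurable). The spike-in-free
  factors are weakly identified when modification levels cluster, so the
  outer loop can legitimately use most of those iterations.

## Fitting procedure

Sequencing-depth factors are computed once up front by median-of-ratios
among samples of the same fraction (geometric-mean reference per gene,
genes with any zero excluded from the reference) and rescaled to
geometric mean 1 within each fraction, then held fixed. Depth and
fraction scale are thus cleanly separated: everything between fractions —
including the between-fraction component of true per-sample depths — is
carried by the fraction scale factors. Recovery checks against simulated
truth must therefore compare fitted scales to
`x_fraction · gm(depth_fraction)/gm(depth_reference)`, the identifiable
combination.

The likelihood is then maximized in blocks: (1) per-gene (μ, γ) by
L-BFGS-B with analytic gradients, normalization and θ fixed; (2) the
eluate and supernatant scale factors jointly on the log scale, input
pinned to 1 (spike-in-free mode only — spike-in-derived factors are
computed once, supernatant pinned to 1, and never refitted); (3) θ by
one-dimensional bounded search on log θ. Each block starts from the
current values and is guarded never to return a worse point, so the
total log-likelihood trace is non-decreasing by construction — an
invariant the test suite asserts per iteration.

Initialization uses moments: μ₀ is the log mean depth-normalized input
count (or log of the eluate + supernatant total when no input is
sequenced), γ₀ the logit of the eluate share clipped to (1e-6, 1−1e-6),
scale factors 1 and θ₀ = 100. Well-placed starts matter more than the
optimizer here: they put every gene in the attraction basin of its
unique interior maximum.

## Confidence intervals

Per-gene intervals come from the profile likelihood of γ: at each fixed
γ the likelihood is maximized over μ (Brent search), with the
normalization factors and θ frozen at their fitted values — their
uncertainty is deliberately neglected, so intervals are exact only
conditionally on the normalization. Bounds solve
2(ℓ_max − ℓ_profile(γ)) = χ²₁(level) by bisection outward from the
estimate; a side that never reaches the cutoff before the γ box is
reported at the box bound and flagged one-sided. Interior bounds satisfy
the cutoff equation to 1e-6 on the deviance scale. On simulated data at
the reference conditions the 95% intervals cover the true log-odds for
94–95% of genes (the acceptance script recomputes this number).

## LAIC-seq baseline

The ratio estimator `m6A = E/(E + S·2^R)` needs the log₂ intercept `R`
relating the two fractions. The sources describe a log–log regression
without stating whether the slope is free; the default here fixes the
slope to 1 (R is then the mean log₂ eluate/supernatant spike-in ratio),
because only then does 2^R carry the exact scale-factor interpretation
the formula assumes. An ordinary free-slope OLS dialect is available
behind `dialect = "free_slope"`. One intercept is fitted per
eluate/supernatant replicate pair from that pair's raw spike-in counts
(≥ 100 in both fractions), and gene-level summaries average the per-pair
proportions. Similarly, the spike-in scale factor aggregates per-spike
ratios by geometric mean rather than by total counts, so one dominant
spike-in cannot drive the factor.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws counts from exactly the fitted model: NB noise
with shared θ = 100, expected input counts log-uniform on [100, 10000]
(the post-filter regime), α uniform on (0.02, 0.98) (optionally Beta),
per-sample depths log-uniform on [0.5, 2], configurable fraction scales
(default 1), and spike-ins that are unmodified, absent from the input,
and equal in expected depth-scaled abundance across eluate and
supernatant up to a mean-preserving lognormal perturbation (sd 0.1 on
the log scale) emulating pipetting/composition variability. Defaults are
sized so a 500-gene × 6-sample study fits in seconds.

Passing tests on these data show that the estimator recovers the
parameters of its own generative law — correct code, calibrated
intervals, identifiable normalization. They do not show robustness to
what real fractionation data add on top: cross-contamination, incomplete
pull-down, gene-specific dispersion, isoform mixtures, mappability
artefacts, or spike-in sets whose composition interacts with library
preparation. Conclusions about real data should lean on the confidence
intervals and on agreement between the two normalization modes, not on
the simulation results alone.

## Numerical choices and known limitations

* Problem sizes used in the shipped validation: 500 genes × 6 samples
  for coverage and parameter recovery (r(γ̂, γ) > 0.98, median
  |α̂ − α| < 0.03), 1000 genes for spike-in-free factor recovery (within
  5%), 50 spike-ins for the spike-in factor (within 5% of a true 1.7).
* The full fit's θ̂ is biased upward (≈160 at a true 100 with 6
  samples): maximum likelihood with two nuisance parameters per gene and
  no adjusted-profile correction. This barely moves (μ̂, γ̂) or the CI
  widths at these depths, and θ estimated with the other parameters held
  at truth is unbiased (the dispersion-block test recovers θ = 10 within
  [8, 12]), but an APL-style correction would be the natural refinement.
* Normalization is per fraction (two shared factors plus fixed
  per-sample depths), the reading adopted for "shared between samples
  from the same fraction"; a per-sample-group alternative would absorb
  replicate-specific IP efficiency differences but costs identifiability
  at two replicates.
* Conditions (e.g., cell lines) are always fitted independently; the
  package offers no formal between-condition test — overlapping
  confidence intervals are the supported, informal comparison.
* Degenerate inputs: all-zero genes are flagged `all_zero` and excluded
  from convergence claims; single-gene factor fitting errors rather than
  silently succeeding; boundary θ solutions are flagged.
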