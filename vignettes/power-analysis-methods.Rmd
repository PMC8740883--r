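---
title: "Methods: simulating and powering differential-abundance studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and powering differential-abundance studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdapower)
```

## The problem

Multi-sample single-cell studies often ask a deceptively simple question: is
some cell state more abundant in cases than in controls? The power to answer
it depends on quantities that are hard to intuit — how much cell-state
frequencies fluctuate between people, how strongly processing batches and
sample identity distort expression, how many samples and cells the budget
allows, and how the samples are multiplexed across batches. `scdapower`
estimates these quantities from a *prototype* dataset (a pilot or public
dataset from a comparable setting), simulates arbitrarily many synthetic
case-control studies that inherit its noise structure, and measures the power
of a standard differential-abundance (DA) analysis on them.

The framework deliberately works in principal-component (PC) space rather
than gene space: PCs capture the gene covariation that drives clustering, the
analysis step most DA pipelines depend on, and make simulation cheap enough
to repeat hundreds of times.

## Step 1: parameter estimation

For each cluster (cell state) $k$ and each of the leading $nPC$ PCs we fit a
linear mixed model with crossed random intercepts for batch and sample,

$$ \mathrm{PC} \sim 1 + (1\,|\,\mathrm{batch}) + (1\,|\,\mathrm{sample}), $$

by REML (`lme4::lmer`). The fitted intercepts across PCs form the cluster
centroid $\mu$; the per-PC random-effect variances $\tau^2$ form the
diagonals of the batch and sample covariances $\Sigma_B$ and $\Sigma_S$
(enforced diagonal); and the empirical covariance of the per-cell residual
matrix is the full residual covariance $\Sigma_C$. Boundary fits (a $\tau^2$
estimated at 0) are kept at 0 and flagged; a cluster observed in a single
batch or sample drops that random effect and records zero variance for it.

Cluster-frequency variation is estimated by counting cells per (sample,
cluster), adding a pseudo-count of 1 so absent states keep positive mass,
converting to within-sample proportions, and taking $\mu_{cf}$ as the natural
log of the mean proportion vector and $\Sigma_{cf}$ as the unbiased
covariance of the per-sample log proportions. Two deliberate choices here:

* proportions are normalized by the pseudo-counted totals, so every sample's
  proportions sum to exactly 1 — this keeps the frequency model internally
  consistent with the resampling step, which renormalizes anyway;
* $\mu_{cf}$ is the log of the mean proportion while $\Sigma_{cf}$ is the
  covariance of the logs. Mixing the two is statistically inelegant (the log
  of a mean is not the mean of logs), but it is the estimation procedure this
  framework is defined by, and the simulation step consumes exactly these
  two objects.

## Step 2: simulation

For each simulated sample a frequency profile is drawn in log space,
$F \sim \exp\,\mathcal N(\mu_{cf},\, \Sigma_{cf} \cdot cf_{scale})$, and
normalized to sum 1; sampling in log space makes negative frequencies
impossible. The scale factors $b_{scale}$, $s_{scale}$, $cf_{scale}$ multiply
the estimated batch, sample, and frequency covariances; 1 reproduces the
prototype's noise, 0 removes that source entirely (and consumes no
randomness, so the zero-noise limits are exact, not approximate).

The design's fold change $fc$ expands one target cluster in case samples:
its frequency becomes $\min(fc \cdot f, 1)$ and the remaining clusters are
rescaled proportionally into the leftover mass (exactly 0 each if the cap
consumed everything). Frequencies then become integer cell counts by
deterministic largest-remainder rounding, ties broken by cluster order. A
multinomial draw would be the obvious alternative; rounding was chosen so
that at $cf_{scale} = 0$ the realized case/control ratio equals the induced
fold change exactly rather than in expectation, which is also what makes the
exactness test in this package meaningful.

Each cluster receives one linear shift per batch,
$b_m \sim \mathcal N(0, \Sigma_B \cdot b_{scale})$, and one per sample,
$s_d \sim \mathcal N(0, \Sigma_S \cdot s_{scale})$. A cell of that cluster
from batch $m$ and sample $d$ finally draws its coordinates from
$\mathcal N(\mu + b_m + s_d,\, \Sigma_C)$.

Randomness uses a single R stream seeded from the design seed, with a fixed
order of operations (profiles, target choice, shifts by sorted cluster then
batch/sample, coordinates by sample then cluster). This gives the same
reproducibility guarantee as per-stage sub-streams — identical seed, identical
dataset — with idiomatic R seeding.

## Step 3: DA testing and power

Simulated cells are re-clustered from scratch: a shared-nearest-neighbor
graph ($k = 30$ Euclidean neighbors, self included; edge weight = Jaccard
similarity of neighbor sets; edges below $1/15$ pruned — the conventions of
the ecosystem these analyses usually run in) followed by Louvain community
detection at a user-set resolution (default 1.2; large blood-like cohorts
are often clustered near 2.0 and coarse tissue atlases near 0.4).

Each re-clustered state is tested with MASC: a logistic mixed model of
per-cell membership with batch and sample random intercepts, comparing

$$ \texttt{member} \sim \mathrm{condition} + (1|\mathrm{batch}) + (1|\mathrm{sample}) $$

against the same model without `condition` by a 1-df likelihood-ratio test,
both fitted by Laplace-approximation ML (REML would invalidate the LRT).
Because condition, batch, and sample are constant within a sample, the
per-cell Bernoulli likelihood collapses *exactly* into per-sample binomial
counts; the package fits the collapsed form, which is two orders of
magnitude faster and identical in its likelihood ratio (verified against
per-cell fits in the test suite). A simple fixed-effects alternative
(per-cluster linear regression of case status on per-sample frequency) is
included for comparison.

Detection is Bonferroni: success when any cluster has $p < 0.05/k$ with $k$
the number of clusters found *in that simulation*. Power is the detection
fraction across simulations with a Wilson score interval (the standard
binomial interval with good small-sample coverage). Each simulation also gets
an interpretability score: the Pearson correlation between the per-cell
indicators "originates from the causal cluster" and "sits in a detected
cluster" — 0 if nothing is detected, and defined as 0 (flagged) in the
degenerate case where an indicator is constant although detections exist.

## The synthetic prototype generator

The generator exists so that every stage can be validated against known
ground truth. It places $k$ centroids along random orthonormal directions
scaled by a single separation knob, assembles the implied parameter set, and
produces cells with the same simulation machinery used everywhere else.
Defaults describe a modest human cohort: 5 states in 20 PCs, 20 samples of
500 cells in 5 batches (4 samples per batch), separation 6 against residual
SD 1, batch and sample shift SD 0.3 per PC, and log-space frequency SD 0.5 —
the order of magnitude seen in human tissue cohorts. The presets (`ra_like`,
`uc_like`: fewer samples, high frequency variance; `tb_like`: many samples,
low frequency variance) encode qualitative contrasts between typical tissue
and blood settings; their numbers are illustrative and deliberately not
calibrated to any particular dataset.

What the generator does *not* emulate: non-Gaussian cluster shapes,
doublets, ambient RNA, depth-dependent noise, or batch effects that warp
rather than shift a cluster. Passing recovery and calibration tests on
synthetic prototypes therefore demonstrates internal consistency of the
estimator-simulator-tester loop, not fidelity to any specific tissue.

## Numerical choices and test sizes

* Variance estimates are clipped at the REML boundary (0); covariance
  matrices get an eigenvalue-clipped square root when Cholesky fails
  (PSD to within $10^{-8}$ jitter is accepted).
* kNN distance ties are broken by cell index, and Louvain runs under the
  caller's seed, so clustering is reproducible bit-for-bit.
* Recovery tests compare *aggregate* variance summaries (means of the
  diagonals over clusters and PCs, centroid RMSE over all coordinates).
  This is deliberate: with $B$ batches a REML variance estimate carries
  Monte-Carlo CV $\approx \sqrt{2/(B-1)}$ (about 32% at 20 batches) before
  the estimator contributes any error of its own, so element-wise bounds at
  that design size would measure noise, not correctness. Aggregation over
  $k \times nPC$ elements shrinks the CV by an order of magnitude.
* The estimated $\Sigma_{cf}$ is biased low relative to the generating
  covariance by the compositional factor $1 - 2p_i + \sum_j p_j^2$ (log
  proportions are logs of *normalized* draws). At balanced frequencies this
  is $1 - 1/k$; recovery fixtures use balanced frequencies so the bias stays
  well inside the tolerance. This bias is a property of the estimation
  procedure itself, not of this implementation.
* Calibration and monotonicity studies in the tests use 100 simulations per
  setting, 5-state prototypes, and 200 or fewer cells per sample; full-size
  analyses (500 simulations, hundreds of samples, thousands of cells) use
  the same code paths and simply take proportionally longer.

## Known limitations

* Only batch and sample are modeled as variance components; other covariates
  (age, sex, site) fold into the residual.
* Frequencies are compositional: inducing an expansion necessarily shrinks
  every other cluster, so at fixed cells per sample even "null" clusters
  show compensatory DA at large fold changes. The interpretability score
  exists precisely to quantify this.
* The fold-change cap makes extreme inductions degenerate (one cluster takes
  the whole sample); realized fold changes above $1/f$ saturate.
* Continuous phenotypes, gene-level counts, and neighborhood-based DA tests
  are out of scope.
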