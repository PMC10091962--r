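---
title: "Quantifying phenotypic variation and transgression in hybrid crosses"
author: "hybridspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phenotypic variation and transgression in hybrid crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridspace)
```

## The scientific question

Interspecific hybridization can generate phenotypic variation beyond the
range of either parental species — *transgressive segregation* — and such
novelty can matter for adaptation and speciation. This package implements a
pipeline for asking, in a reciprocal two-species crossing design (two
parental species, reciprocal F1 and F2 hybrid groups), three questions about
any low-dimensional trait space:

1. **Dispersion** — is a hybrid group's trait cloud larger than the parental
   clouds?
2. **Transgression** — how many hybrid individuals fall outside the trait
   range of *both* parental species?
3. **Mean placement** — does the hybrid group mean deviate from the line
   segment connecting the parental means, and in which way?

The motivating application is brain morphology and cognition in poeciliid
fishes (guppies), where the trait spaces are a 3-D brain morphospace and a
2-D cognitive space, but every statistic is dimension-agnostic.

## Trait spaces

### Brain morphospace (3-D)

Raw measurements per fish are body length, brain weight, and the length,
width and height of six brain regions (telencephalon, optic tectum,
cerebellum, dorsal medulla, hypothalamus, olfactory bulbs). Region volume is
estimated as the ellipsoid $V = (L \times W \times H)\,\pi/6$.

The three axes are "relative" traits — residuals from pooled ordinary
least-squares allometries on the log10 scale:

* axis 1: residual of $\log_{10}$ brain weight on $\log_{10}$ body length;
* axes 2-3: residuals of $\log_{10}$ telencephalon and optic-tectum volume
  on $\log_{10}$ *brain remainder* volume (total brain volume, the sum of
  the six region volumes, minus the focal region — using the remainder
  avoids including the focal region in its own covariate).

Sexes are pooled. A design note: published analyses of this kind state the
trait space as "trait X relative to size" without committing to a specific
construction; this package defines the relative trait as the residual from
one *pooled* common-slope fit across all groups, which keeps all groups in a
common space and makes axis means zero by construction. Group-specific
slopes are deliberately not used inside the trait space (they would bend the
space per group); logarithms are base 10 throughout (the base only rescales
axes). Individuals missing any required measurement are excluded and listed
in an exclusion report rather than silently dropped.

### Cognitive space (2-D)

From trial-level learning logs, the learning criterion is a run of seven
consecutive correct choices; `trialsToCriterion()` scores the 1-based index
of the last trial of the *first* such run, censored at 40 trials
(associative task) and 60 trials (reversal task). The space's axes are
$\log_{10}$ trials-to-criterion in the two tasks, and only individuals that
reached criterion in both tasks enter the space. The protocol's
minimum-trial gates (12/16/24 trials before phase transitions) affect
husbandry, not the score: the raw criterion-completion index is used.

## Dispersion: 95% KDE hypervolumes

Each group's trait cloud is fitted with a Gaussian product-kernel density
estimate with diagonal bandwidth,
$$\hat f(x) = \frac{1}{n}\sum_{i=1}^n \prod_{j=1}^d
  \frac{1}{h_j}\,\phi\!\left(\frac{x_j - p_{ij}}{h_j}\right).$$

**Bandwidth.** $h_j = c\,\sigma_j\,n^{-1/(d+4)}$ with per-axis sample SDs
$\sigma_j$ and a single scale factor $c$ selected by grid search: 25
log-spaced values in $[0.25, 4]$, minimizing the least-squares
cross-validation criterion (both terms of which are closed-form for
Gaussian kernels). A scalar factor rather than a full matrix keeps the
search reproducible and one-dimensional; ties resolve to the smaller
factor, so selection is deterministic.

**Contour threshold.** The 95% region is defined so that it *contains 95%
of the group's individuals*: the threshold is the 5% empirical quantile
(linear interpolation between order statistics) of the fitted density
evaluated at the group's own training points.

**Hypervolume.** The dispersion statistic is the volume of the superlevel
set, measured by counting grid cells whose center density reaches the
threshold, times the cell volume. Default grids use 151 points per axis for
$d \le 2$ and 101 for $d = 3$ (about $10^6$ cells), padding the data range
by 4 bandwidths per axis — enough for the numerically integrated density to
fall in $[0.98, 1.02]$, which is asserted by tests.

**Membership.** Whether a point lies inside a region is decided by the
*exact kernel sum* at that point, never by grid interpolation. (Grid
interpolation is an approximation knob that exact evaluation removes; for
points far from the grid the two conventions can disagree, which is why the
package commits to the exact one.)

## Transgression and its finite-sample chance rate

A hybrid individual is transgressive when it falls outside the 95% regions
of *both* parental species. Individuals are classified independently with
no multiplicity correction, and group results are frequencies, not tests.

The nominal chance expectation is 5%: if hybrids were drawn from the
parental distribution itself, about 5% should fall below a 95% threshold.
`chanceRateSimulation()` measures the *actual* baseline of the convention:
parental and test samples all drawn from one common distribution, parental
KDEs fitted, test points classified. An important numerical fact, computed
by the acceptance checks rather than merely asserted here: with parental
samples of $n = 40$ the measured baseline is roughly twice the nominal 5%,
and it approaches 5% from above as the parental sample grows. The cause is
the in-sample threshold convention — each training point's density includes
its own kernel ($\frac{1}{n}\prod_j (2\pi h_j^2)^{-1/2}$ at the point
itself), inflating training densities relative to out-of-sample points and
therefore raising the threshold. Consumers comparing observed hybrid
transgression frequencies against "5%" should instead compare against this
measured baseline at the study's parental sample size.

## The simulated-hybrid null

To ask whether a hybrid group's statistics are unusual, the package builds
a resampling null: each simulated hybrid is the *midparent value* of a
randomly drawn parental pair (coordinate-wise mean of one individual from
each species, drawn uniformly with replacement), `nSim` individuals per
replicate, `reps` replicates (study-scale defaults: 35/25 individuals, 100
replicates). Per replicate the pipeline records the mean phenotype, the 95%
KDE hypervolume, and the geometry statistics below; observed hybrid groups
are ranked within the null by midrank percentile, flagging values outside
the central 95%. Sampling is with replacement (the alternative is not
materially different at these sizes and with-replacement keeps replicates
i.i.d.); replicate $r$ uses a sub-seed derived deterministically from the
ensemble seed and $r$, so any single replicate can be reproduced alone.

## Parental bias and phenotypic mismatch

With parental means $\mu_1, \mu_2$ (midpoint $m$, unit axis
$u = (\mu_2 - \mu_1)/\lVert\mu_2 - \mu_1\rVert$) and hybrid mean $\bar h$:

* **parental bias** $= |(\bar h - m) \cdot u|$, the deviation along the
  inter-parental axis, reported as an unsigned magnitude plus a direction
  label (toward parent 1 or 2; "none" below $10^{-12}$);
* **phenotypic mismatch** $= \lVert (\bar h - m) - ((\bar h - m)\cdot u)\,u
  \rVert$, the perpendicular distance to the *infinite* line through the
  parental means (not the segment — clamping to the segment would leak bias
  into mismatch for hybrids beyond a parent).

The two satisfy $\text{bias}^2 + \text{mismatch}^2 =
\lVert\bar h - m\rVert^2$ exactly, which the tests assert to $10^{-9}$
alongside brute-force line-distance minimization.

## Synthetic data: what the generators state, and what they do not

The package is fully testable without external data via three generators,
each a pure function of its config (seed included).

* `generateTraitCohort()` draws the six crossing groups from multivariate
  normals: parents at their configured means; F1 at the midparent mean plus
  optional heterosis and mismatch, with covariance
  $(\Sigma_1 + \Sigma_2)/4$ — the variance of a midparent of independent
  parental draws; F2 at the same mean *without* heterosis (hybrid vigor is
  F1-specific) and covariance inflated by a scalar segregation factor. The
  configured mismatch vector is projected orthogonal to the true
  inter-parental axis before injection, so the ground-truth mismatch
  magnitude is exact. A stated fraction of hybrids can be displaced by a
  fixed vector to inject known transgression.
* `generateMorphometricCohort()` emits raw trait-table records: body length
  around 22 mm, brain weight from a slope-1.17 log-log allometry anchored
  at ~4.5 mg, region volumes as fixed realistic fractions of a latent total
  brain volume (optic tectum 45%, telencephalon 15%, ..., olfactory bulbs
  5%) with log-normal noise (0.03 dex) and configurable per-group offsets,
  and dimension triples with a fixed 1.25 : 1 : 0.8 anisotropy whose
  ellipsoid volume reproduces the target volume exactly.
* `generateTrialLog()` draws Bernoulli learning curves
  $P(\text{correct at } t) = \mathrm{logistic}(a + u_i + b\,t)$,
  $u_i \sim N(0, \sigma^2)$, stopping each sequence at criterion or the
  censoring bound, and running the reversal task only for associative
  passers (as the assay protocol does). Defaults ($a = 0$, $b = 0.12$,
  $\sigma = 0.5$) were chosen once so that most simulated females reach
  criterion within 40 trials, emulating the observed 79-100% success range.

What the generators do *not* emulate: genetics (no loci, dominance or
epistasis — phenotype-level models suffice to exercise every statistic),
session structure in trials, measurement error in dissection, or any
difference between reciprocal cross directions (both F1 groups share one
distribution). A green parameter-recovery test therefore establishes that
the estimators recover what the generative model injects — not that real
data satisfy the model.

## Numerical choices and degenerate inputs

* Quantiles use linear interpolation between order statistics (R type 7),
  cross-checked against a hand-written sort-and-interpolate oracle.
* Zero-variance axes, too-few points ($n < d + 2$), non-positive-definite
  covariances, coincident parental means, grids that fail to cover the
  data, and empty parental matrices are all hard errors, not warnings.
* An empty superlevel set yields volume 0 with a warning.
* Percentages in count tables round half-up (19/24 prints as 79%); a zero
  denominator reports an undefined (NA) percentage rather than 0.
* All RNG flows from explicit integer seeds; derived sub-seeds stay below
  $2^{31}$.

## Limitations

* Hypervolumes depend on grid resolution; the defaults keep the refinement
  error under a few percent (asserted by a grid-doubling test), but
  absolute volumes should always be compared at matched grids.
* LSCV bandwidth selection is variable at small $n$; the scale-factor grid
  bounds ($[0.25, 4]$) prevent collapse but the selected factor is noisy.
* The in-sample threshold convention's finite-sample transgression bias
  (above) means raw transgression frequencies at small parental $n$ are not
  comparable across sample sizes without the measured baseline.
* Regression-style inference on group differences (LMs/GLMMs, post-hoc
  comparisons) is intentionally out of scope; standard modeling packages
  handle those well.
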