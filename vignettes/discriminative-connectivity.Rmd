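---
title: "Methods: discriminative resting-state connectivity analysis"
author: "restfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminative resting-state connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restfc)
```

# Overview

`restfc` implements a complete multivariate pattern-analysis pipeline for
two-group discrimination from regional resting-state fMRI time series:
edge-feature construction, cross-group Kendall-tau feature selection,
PCA + linear-SVM classification under leave-one-out cross-validation
(LOOCV), label-permutation significance testing, and back-projection of
classifier weights into per-edge and per-region discriminative weights.
This vignette records the model, its assumptions, the numerical
conventions, and the design decisions taken where more than one reasonable
choice existed.

# The model

## Edge features

Each subject contributes a $T \times R$ matrix of regional time courses.
After cleaning (below), the Pearson correlation between every pair of
regions is computed, Fisher z-transformed ($z = \mathrm{arctanh}\, r$, a
variance-stabilizing map that spreads correlations near $\pm 1$), and the
strict upper triangle is vectorized. The edge order is fixed once and for
all: row-major over pairs $(i, j)$ with $i < j$, i.e. $(1,2), (1,3),
\dots, (1,R), (2,3), \dots$ With $R = 90$ this yields $D = 4005$ features.
A fixed order is not cosmetic: fold-wise feature selections, consensus
sets and serialized feature tables are only comparable because every part
of the package indexes edges identically.

## Time-series cleaning

Three linear operations, each idempotent (they are orthogonal
projections):

* **Linear detrend** — per-region least-squares removal of intercept and
  slope; scanner drifts are approximately linear over single runs.
* **Band-pass 0.01–0.08 Hz** — an *ideal* rectangular mask in the discrete
  Fourier domain: bins with $f_{low} < f < f_{high}$ are kept, everything
  else (including DC) is zeroed, with the mask mirrored over negative
  frequencies so the output stays real. The band is treated as an open
  interval: bins exactly at the edges are removed. An ideal mask rather
  than an IIR design (e.g. Butterworth) mirrors the convention of the
  standard resting-state toolkits this pipeline is modelled on, and makes
  the operation exactly idempotent.
* **Nuisance regression** — OLS residuals on user-supplied confound
  columns (motion, global mean, white matter, CSF) plus an internal
  intercept. Rank-deficient confound sets are repaired by dropping
  dependent columns, with a warning rather than an error, since pipelines
  routinely feed near-duplicate regressors.

The default order is detrend → band-pass → confound regression. Published
descriptions of such pipelines often leave the relative order of filtering
and nuisance regression unstated; we default to regressing last (so that
the regression also removes any confound energy re-introduced by edge
effects of filtering) but the order is a parameter of
`preprocessSeries()`.

## Cross-group Kendall tau

For one feature with $m$ patient values (label $-1$) and $n$ control
values (label $+1$), only the $m \times n$ patient–control pairs are
examined: a pair is concordant when the sign of the feature difference
equals the sign of the label difference, discordant when opposite, and
neither when the feature difference is exactly zero. Then

$$\tau = \frac{n_c - n_d}{m\,n}.$$

Ties therefore stay in the denominator but count toward neither $n_c$ nor
$n_d$ — both sign conditions fail at zero, and the denominator is fixed at
$m n$ by construction. Under this label convention $\tau > 0$ iff the
feature tends to be *lower* in patients. $\tau$ is invariant under any
strictly increasing transform of the feature, which is why ranking before
or after the Fisher transform gives identical orderings (a property the
test suite asserts).

Features are ranked by $|\tau|$, ties broken by ascending edge index. The
tie-break is arbitrary but must be fixed: consensus features across LOOCV
folds would otherwise depend on sort stability.

## PCA + linear SVM

Within each training set, the top-$k$ features are reduced by PCA:
$\tilde{x} = U^\top (x - \bar{x})$ with $U$ the leading $d$ eigenvectors
of the training covariance. Two conventions make the basis reproducible:
$d$ is capped at the available rank $\min(k, n_{train} - 1)$ (with a
warning), and each component's sign is fixed so its largest-magnitude
loading is positive — eigenvectors are otherwise defined only up to sign,
and the back-projected weights $\Lambda = Uw$ inherit that ambiguity.

The classifier is the standard soft-margin linear C-SVM, fit with the
deterministic SMO solver of libsvm (via `e1071`), giving the decision
function $Y = w^\top \tilde{x} - b$. $Y > 0$ is classified as control;
$Y = 0$ exactly is assigned to the patient class so the boundary is
deterministic. The solver's internal orientation (libsvm orients its
decision values toward whichever class it encounters first) is normalized
at fit time so that positive always means control.

## LOOCV, metrics and consensus

Each subject is held out once; ranking, selection, PCA and SVM are all
re-fit on the remaining $N - 1$ subjects. The suite verifies directly that
corrupting a held-out subject's data or label changes nothing in that
fold's models. Counts use patients as the positive class: GR (overall
accuracy), SS (sensitivity to patients), SC (specificity to controls). A
metric with a zero denominator is reported as `NA`, never 0. Features
selected in *every* fold form the consensus set; in *any* fold, the union
set.

Hyperparameters $(k, d, C)$ may be chosen by `sweepFeatureNumber()` /
`gridSelect()`, which evaluate the same LOOCV over a grid (defaults: $k
\in \{50, 100, \dots, 800\}$, $d \in \{2, \dots, 20\}$, $C \in \{0.005,
0.055, \dots, 1.955\}$) and break ties toward the smallest $k$, then $d$,
then $C$. This selection is *non-nested*: the same folds pick the
hyperparameters and report GR, which is optimistically biased. It mirrors
the common practice in small-sample neuroimaging studies of reporting the
best operating point; an unbiased protocol would nest the grid search
inside an outer CV, which small $N$ rarely permits. The bias affects the
reported GR, not the identity of the discriminative edges.

## Permutation test

The significance of the observed $GR_0$ is assessed by permuting the full
label vector and re-running the *entire* LOOCV — including per-fold
feature selection — once per permutation, yielding one $GR^*$ each. The
p-value uses add-one smoothing,

$$p = \frac{1 + \#\{GR^* \ge GR_0\}}{n_{perm} + 1},$$

which avoids $p = 0$ at finite $n_{perm}$ and makes the smallest
attainable p-value $1/(n_{perm}+1)$. Alternative schemes (permuting within
each fold's training set independently) do not produce a single
well-defined $GR^*$ per permutation; the whole-vector scheme does, and is
the one implemented.

## Reconstruction

Because $Y = w^\top U^\top (x - \bar{x}) - b = (Uw)^\top (x - \bar{x}) -
b$, the vector $\Lambda = Uw$ assigns one weight per selected feature;
$|\lambda_j|$ is that feature's contribution to the decision score. Each
fold's $\Lambda_i$ is embedded into the full $D$-length space (zeros at
unselected features — fold selections differ, so averaging must happen in
a common space) and the absolute values are averaged:
$\bar{\Lambda} = (|\Lambda_1| + \dots + |\Lambda_N|)/N$. Region weights
assign half of each edge weight to each endpoint and sum; total region
weight equals total edge weight, an algebraic identity the suite checks
numerically. The edge report recomputes $\tau$ on the *full* dataset (the
per-fold taus differ slightly; a single table needs a single value) and
labels each edge "decreased" (in patients) iff $\tau > 0$.

# The cohort simulator

No scan data ship with the package; the simulator provides ground-truth
cohorts with the structure of a two-group resting-state study:

* A base correlation matrix from a sparse latent-factor model: regions are
  assigned round-robin to a few latent components with uniform loadings,
  giving block-like correlation reminiscent of resting-state networks.
  `baseDensity` scales the shared variance (0 = identity).
* The patient covariance equals the base with chosen edge correlations
  shifted by `delta`, then repaired: symmetrize, floor eigenvalues at
  $10^{-6}$, rescale to unit diagonal. The repair is deterministic and its
  perturbation of non-planted edges is small (the suite bounds it at
  0.05 for a single planted edge); shifts that would push $|r|$ beyond
  0.99 are rejected outright.
* Subject series are multivariate-normal draws, optionally band-limited to
  0.01–0.08 Hz by the same ideal filter (applying one filter to all
  regions leaves expected cross-correlations unchanged, so planted effects
  survive), plus a per-subject random linear drift (exercising the detrend
  stage) and white measurement noise.

Defaults mirror the target study design: 22 + 22 subjects, 90 regions,
175 timepoints at TR = 2 s, band 0.01–0.08 Hz. The nuisance amplitudes
(`driftAmplitude = 0.5`, `noiseSd = 0.2` in units of signal SD, and
`baseDensity = 0.3`) are free parameters of the simulator — no study
reports them — set once to values a resting-state analyst would call mild
but non-negligible. Planted effect sizes default to $|\Delta r| = 0.5$ in
the validation scenarios, with decreased edges in the majority, matching
the qualitative observation that most altered connectivity in such
patients is reduced.

What the simulator does **not** emulate: hemodynamic autocorrelation
beyond band-limiting, spatial structure within parcels, subject motion
artifacts, site or scanner effects, or heavy-tailed noise. Passing the
recovery tests therefore demonstrates that the *pipeline* is correct and
sensitive under its own assumptions — not that real patient cohorts would
classify at similar rates.

# Numerical conventions

* Correlations are clipped to $|r| \le 1 - 10^{-7}$ before
  $\mathrm{arctanh}$, so numerically perfect correlations stay finite.
* Zero-variance regions abort the correlation step with the offending
  region named; silently producing `NA` columns would poison every
  downstream stage.
* All simulator and permutation randomness flows through a single integer
  seed (`withr::with_seed`), making cohorts and p-values bit-reproducible.
* Exact determinism is asserted in the suite for: repeated simulation,
  repeated model fits, and the identity permutation reproducing $GR_0$.

# Validation problem sizes

The test suite validates parameter recovery at the full study scale
(22 + 22 subjects, 90 regions, $T = 175$, 30 planted edges at $|\Delta r|
= 0.5$, 20 seeded replicates for the hub-region analysis) and calibrates
the permutation test on 20 replicate *null* cohorts of 10 + 10 subjects
over 15 regions with 100 permutations each — a size at which 2,000 full
LOOCV runs remain a routine test-suite workload while the add-one smoothed
p-values still resolve the 0.05 threshold. On null cohorts the empirical
p-values are approximately uniform (the discrete GR distribution and the
smoothing make them mildly conservative), and the suite requires that no
more than 2 of 20 fall below 0.05.

# Known limitations

* Pearson correlation only — no partial correlation, wavelet or
  sliding-window connectivity.
* Linear kernel only; no probability calibration of the SVM.
* Non-nested hyperparameter selection is the default (see above); a
  nested protocol would require more subjects than the target design has.
* The permutation test re-runs the full LOOCV per permutation and scales
  accordingly ($O(n_{perm} \cdot N)$ model fits).
* Group sizes enter the tau denominator directly; heavily unbalanced
  designs compress the attainable $|\tau|$ resolution.
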