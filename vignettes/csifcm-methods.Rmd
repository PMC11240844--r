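---
title: "Conditional spatial intuitionistic fuzzy C-means: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional spatial intuitionistic fuzzy C-means: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csifcm)
```

## The clustering family

All four drivers in this package are alternating-optimization schemes on a
fuzzy partition of pixel intensities. The base cost is the fuzzy C-means
objective

$$J=\sum_{i=1}^{c}\sum_{k=1}^{N}\mu_{ik}^{m}\,d(x_k,v_i)^2,
\qquad \sum_i \mu_{ik}=1,$$

with $d$ the absolute difference of scalar intensities on the normalized
$[0,1]$ scale. Pixels are treated as intensities only: no feature vectors,
no 3-D neighborhoods, no kernelized distances. Each iteration updates the
membership matrix from the current centers,
$\mu_{ik}=1/\sum_j (d_{ik}/d_{jk})^{2/(m-1)}$, and the centers as
$w^m$-weighted means of the intensities, where $w$ is whatever membership
matrix the particular algorithm designates.

The two operator families layered on top:

* **Spatial conditioning.** $h_{ik}$ is the arithmetic mean of cluster-$i$
  memberships over a square window centered on pixel $k$; the window
  shrinks at image borders and $R$ is the in-image neighbor count (no
  padding, so border values remain genuine averages). The conditional
  spatial membership is $u^*_{ik}=h_{ik}\mu_{ik}$; with $h\equiv 1$ it
  reduces to plain FCM membership.
* **Intuitionistic fuzzification.** The Yager complement
  $\lambda=(1-u^\alpha)^{1/\alpha}$ yields a non-membership that is *not*
  the complement of $u$; the residual $\pi=1-u-\lambda\ge 0$ is the
  hesitation degree, and $u+\lambda+\pi=1$ holds exactly.

**csFCM** weights the local and conditioned memberships into
$z\propto\mu^p u^q$ and updates its centers from $z$; **IFCM** replaces
$\mu$ by the renormalized $\mu+\pi(\mu)$; **csIFCM** composes both: from
the current joint centers $g$ it computes $\mu$, $h$, $u^*=h\mu$,
$\lambda(u^*)$, $\pi(u^*)$, the intuitionistic membership
$\mu^*=\mu+\pi(u^*)$ (capped at 1), the weighted intuitionistic membership
$w\propto{\mu^*}^p{u^*}^q$, and finally $g$ from $w$. Convergence is
monitored as the maximum absolute entrywise change of the membership matrix
each algorithm's own stopping rule names ($\mu$, $\mu^*$, $z$, $w$
respectively).

### Why $\mu^* = \mu + \pi(u^*)$

The composition of the intuitionistic layer is the one genuinely open
design point: the hesitation is computed from the *conditioned* membership
$u^*$, but it is added to the *plain* membership $\mu$. Two observations
drive this choice. First, it preserves the interpretation of the exponents:
$p$ weights an (intuitionistically inflated) local membership and $q$ the
spatial one, exactly parallel to csFCM's local/global weighting — composing
everything from $u^*$ alone would make both factors functions of the same
matrix and reduce $w$ to a renormalized power of $u^*$. Second, it makes
the reduction structure exact: at $\alpha=1$ the hesitation vanishes
identically, $\mu^*=\mu$, and csIFCM reproduces csFCM's iterates
bit-for-bit (the suite asserts this to $10^{-12}$; in practice the
trajectories are identical). Likewise IFCM at $\alpha=1$ retraces FCM. The
cap $\mu^*\le 1$ only engages for $\alpha<1$ (where $\mu+\pi(u^*)$ can
slightly exceed 1 when $u^*\ll\mu$) and therefore never perturbs the
reductions.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `n_clusters` (c) | 4 | tissue classes in a typical axial brain slice (background, CSF/gray, white, skull/scalp); also the phantom's class count |
| `m` | 2 | fuzzifier; the universal FCM default, softening decays as $m\to1$ |
| `p`, `q` | 1, 2 | weights of the intuitionistic vs. spatial membership in $w$; 1/2 is the best cell of the accuracy sweep (`sweep_pq()`) and balances local against neighborhood evidence |
| `alpha` | 0.85 | Yager parameter, restricted to $(0,1]$ so that $\lambda\le1-u$ and $\pi\ge0$; values above 1 would break the intuitionistic constraint $0\le u+\lambda\le 1$. At 1 the layer collapses |
| `window` | 3 | 3×3 conditioning window, the smallest isotropic neighborhood; larger windows smooth more and erode thin structures |
| `epsilon` | 1e-5 | stop when the monitored membership changes by at most this much; on 65k pixels this is well under one pixel's worth of drift |
| `max_iter` | 100 | cap; non-convergence is flagged on the result, never raised |

Units: all intensities (hence centers, distances) live on the normalized
$[0,1]$ scale; noise is parameterized by its *variance* on that scale, so
variance 0.01 means standard deviation 0.1.

## Numerical choices

* **Zero distance.** The membership ratio is undefined at $d=0$; such a
  pixel gets crisp membership on the first zero-distance cluster by index —
  a deterministic tie-break.
* **Degenerate clusters.** A cluster whose weights are all zero keeps its
  previous center with a warning; with no previous center it is an error.
  An all-zero weighted-product column falls back to the uniform $1/c$.
* **Defuzzification.** Per-pixel argmax, ties to the lowest cluster index.
* **Box filter.** The window mean uses a summed-area table ($O(N)$ per
  cluster regardless of window size); cancellation can overshoot $[0,1]$ by
  a few ulp, so the result is clamped.
* **Initialization.** A seeded uniform random partition (columns normalized
  to 1), then centers from the center-update rule. Identical seeds give
  bit-identical runs; permuting the initial cluster order permutes the
  output consistently.
* **Constant images** normalize to all-zeros rather than NaN.

## What the generators emulate

`generate_phantom()` renders the ten-ellipse Shepp-Logan head phantom
(modified high-contrast table by default, original table selectable) on the
conventional $[-1,1]^2$ grid and quantizes the distinct composite intensity
levels into four classes by an exact natural-breaks partition *weighted by
pixel counts*: background {0}, brain tissue {0.1, 0.2}, bright internal
ellipses {0.3, 0.4}, skull shell {1}. The weighting matters: unweighted
breaks hit a cost tie and would merge the 1.5%-mass bright-ellipse level
with the 33%-mass tissue level. The renderer is verified pixelwise against
an independently written reference implementation (frozen 32×32 rendering
plus 256×256 probe pixels, both to $10^{-6}$).

One consequence worth knowing: the phantom contains a small overlap sliver
(left ventricle tip ∩ top ellipse) at composite level 0.1 — *exactly*
midway between background (0) and tissue (0.2). Its class is a knife-edge
for any intensity-based rule, and the spatially conditioned algorithms
deliberately reassign it to its surrounding region. Noise-free recovery is
therefore exactly 1.0 for FCM/IFCM but ≈0.9986 for csFCM/csIFCM: the
spatial layer's bias is visible even without noise. The synthetic-MRI
generator (exact class-mean plateaus, equal-area concentric rings, optional
multiplicative low-frequency bias field) has no such feature, and all four
algorithms recover it perfectly when clean.

What the generators do *not* emulate: Rician noise statistics, partial
volume effects, k-space artifacts, anatomy-shaped class boundaries, or 3-D
continuity. Passing the suite therefore demonstrates the algorithms'
behavior under controlled additive Gaussian corruption of piecewise-nearly-
constant images — not segmentation quality on clinical data.

## The phantom benchmark, honestly

The benchmark (`benchmark_phantom()`, also run by `scripts/acceptance.R`)
uses the 256×256 phantom, additive Gaussian noise of variance 0.01, ten
seeded noise/initialization replicates, and the default parameters above.
Under these conditions the mean overall accuracies are approximately
csIFCM 0.780 > csFCM 0.777 > FCM 0.700 > IFCM 0.694 — the ranking of the
four algorithms is stable across seeds, with the spatially conditioned
pair clearly ahead. The absolute level is capped by the phantom itself: at
noise sd 0.1 the tissue (0.2) and bright-ellipse (0.3) levels are half a
standard deviation apart, so even the Bayes-optimal intensity rule
misassigns a large fraction of the tissue class. Reported accuracies should
be read as *relative* evidence between algorithms under a common corruption,
not as absolute segmentation quality; `benchmark_phantom()` accepts any
noise variance for exploring milder regimes.

Problem sizes throughout the suite were chosen to keep every property
observable at comfortable margins: 10×10 random fixtures for the
brute-force operator oracles (100 trials), 14–20 px images for trajectory
and reduction checks, 128² for recovery tests, and the full 256² × 10-seed
benchmark for the end-to-end experiment.

## Known limitations

* Intensity-only model: spatial conditioning is the sole source of context;
  severe bias fields still shear the intensity histogram (no bias-field
  *correction* is included).
* The csIFCM/csFCM center updates have no known Lyapunov function; only the
  stopping rule is monitored (FCM's objective monotonicity *is* asserted).
* Sensitivity to initialization is real; the seeded-partition design makes
  it reproducible, not absent.
* 2-D slices only; the matching of clusters to classes assumes a roughly
  one-to-one correspondence and will pad, not split, when counts differ.
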