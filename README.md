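# csifcm

Unsupervised segmentation of 2-D grayscale (MR) images with fuzzy C-means
clustering and three noise-robust extensions, in R:

* **FCM** — classic fuzzy C-means on pixel intensities;
* **IFCM** — intuitionistic FCM: each membership μ is augmented by a
  non-membership λ from the Yager complement and a hesitation degree
  π = 1 − μ − λ that models uncertainty in the data;
* **csFCM** — conditional spatial FCM: each membership is conditioned on its
  neighborhood through the windowed mean h, and a weighted membership
  z ∝ μ^p·u^q (u = h·μ) drives the center updates;
* **csIFCM** — the combination: the conditional spatial membership u\* is
  passed through the intuitionistic layer (λ, π, μ\*), and the weighted
  intuitionistic membership w ∝ μ\*^p·u\*^q with joint centers
  g_i = Σ w^m x / Σ w^m defines the final partition.

Intensity-only clustering misclassifies noisy pixels; conditioning each
pixel's membership on its spatial neighborhood rectifies isolated flips, and
the hesitation degree absorbs ambiguity near class boundaries. The package
is aimed at methodologists who want the four algorithms, their shared
primitives and their evaluation stack in one tested, scriptable place.

## The model

All four drivers minimize variants of the fuzzy C-means cost

J = Σᵢ Σₖ μᵢₖᵐ d(xₖ, vᵢ)²,  subject to Σᵢ μᵢₖ = 1,

with d the absolute intensity difference, fuzzifier m > 1, and alternating
updates

μᵢₖ = 1 / Σⱼ (dᵢₖ/dⱼₖ)^{2/(m−1)},  vᵢ = Σₖ μᵢₖᵐ xₖ / Σₖ μᵢₖᵐ.

The spatial layer averages memberships over a square window
(hᵢₖ = Σ_{j∈N(k)} μᵢⱼ / R, shrinking at borders), the intuitionistic layer
uses the Yager generator λ = (1 − u^α)^{1/α} with α ∈ (0, 1], and the two
are combined per pixel by w ∝ μ\*^p u\*^q. Iteration stops when the monitored
membership matrix changes by at most ε (default 1e-5).

Also included:

* min–max normalization, seeded Gaussian noise injection, PNG/TIFF/NIfTI
  readers;
* a modified/original **Shepp-Logan head phantom** generator with a
  deterministic 4-class quantized ground truth, pixel-for-pixel checked
  against an independent reference renderer;
* a **synthetic MRI** generator (concentric tissue rings, optional smooth
  multiplicative bias field, Gaussian noise);
* **evaluation**: optimal (Hungarian) cluster-to-segment matching, Dice
  similarity, false positive/negative ratios, TPR/FPR, overall accuracy;
* **harnesses**: the noisy-phantom benchmark and the p–q weight sweep, plus
  `tidy()`/`glance()`/`autoplot()` methods and a command-line interface
  (`inst/scripts/csifcm` with subcommands `segment`, `evaluate`,
  `benchmark`, `sweep-pq`, `make-fixtures`).

## Worked example

```r
library(csifcm)

ph    <- generate_phantom(128)                       # image + ground truth
noisy <- add_gaussian_noise(ph$image, variance = 0.01, seed = 1)
cfg   <- clustering_config("csifcm", n_clusters = 4, seed = 1)
res   <- segment_image(noisy, cfg)
res
#> <segmentation_result> csifcm (128x128 image, c = 4)
#>   centers: 0.02123, 0.1731, 0.3317, 0.96
#>   55 iteration(s), converged (last max delta 9.01e-06)

evaluate_segmentation(res, ph$labels)
#> <evaluation_report> overall segmentation accuracy: 0.7796
#> # A tibble: 4 × 9
#>   segment n_true n_pred similarity    fpr   fnr   tpr fpr_rate undefined
#>     <int>  <int>  <int>      <dbl>  <dbl> <dbl> <dbl>    <dbl> <lgl>
#> 1       1   9590   9047      0.895 0.0733 0.130 0.870   0.103  FALSE
#> 2       2   5375   4618      0.643 0.261  0.402 0.598   0.128  FALSE
#> 3       3    715   2015      0.375 2.10   0.284 0.716   0.0959 FALSE
#> 4       4    704    704      1     0      0     1       0      FALSE
```

The four converged centers sit at the four phantom intensity levels
(background ≈ 0, gray tissue ≈ 0.2, bright internal ellipses ≈ 0.3, skull
shell ≈ 1). Per-segment rows report Dice overlap (`similarity`), the
surplus-pixel ratio `fpr` (relative to the segment size, deliberately not
clipped at 1), the omitted-pixel ratio `fnr`, and one-vs-rest `tpr`/
`fpr_rate`; `overall segmentation accuracy` is the fraction of pixels whose
optimally matched cluster equals the ground-truth class. At this noise level
(variance 0.01 on the [0, 1] scale) the gray and bright-ellipse classes are
only half a noise standard deviation apart, which is what limits the
attainable accuracy — compare `autoplot(benchmark_phantom())` across the
four algorithms, where the spatially conditioned variants lead.

`tidy(res)` exposes the per-iteration trace, `glance(res)` a one-row
summary, and `autoplot(res)` the label map.

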