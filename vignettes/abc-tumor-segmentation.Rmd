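---
title: "Methods: ABC-optimised clustering for brain tumor segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ABC-optimised clustering for brain tumor segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

A bright tumor in a 2-D grayscale brain MR slice is, to a clustering
algorithm, one of a small number of intensity modes: dark background,
mid-intensity brain tissue, bright tumor. K-means can separate these modes,
but Lloyd iterations converge to a local optimum that depends entirely on
the starting centroids. `abcseg` removes that dependence by treating the
centroid locations themselves as the search variables of a global
optimiser: an Artificial Bee Colony (ABC) minimises a clustering objective
over the concatenated centroid vector, and the final segmentation is a
single nearest-centroid labelling with the best centroids found. No Lloyd
polish is applied afterwards; the optimiser owns the centroids.

The clustering objective balances two goals. For a candidate centroid set
$\{h_1,\dots,h_K\}$ and pixel features $Z$,

$$f = y_1\,\bar d_{\max} + y_2\,(Z_{\max} - d_{\min}),$$

where $\bar d_{\max}$ is the **worst-case average intracluster distance**
(assign every pixel to its nearest centroid, average the distances within
each cluster, take the largest cluster average), $d_{\min}$ is the smallest
pairwise distance between centroids, and $Z_{\max}$ is the maximum feature
value in the image. Minimising the first term makes every cluster compact;
minimising the second pushes centroids apart. The single-objective variant
uses only the compactness term ($y_1=1, y_2=0$); it is cheaper but, as the
comparison below shows, more prone to misclassification when noise blurs
the intensity modes — the separation term exists precisely to suppress
those misclassifications. Both weights default to 0.5 in the multiobjective
configuration: the two sub-objectives are given equal priority unless the
user has a reason to prefer one, and both are expressed in intensity units
so an unweighted sum is already scale-consistent.

## Why the search objective is guarded

Two safeguards are applied to $f$ before it is handed to the optimiser
(`segmentation_objective()`); both are inactive in the 1-D gray-level
setting where the objective is usually stated, and both are necessary in
an RGB feature box.

**Clamped separation reward.** On a 1-D intensity axis, two centroids in
$[0,255]$ can never be further apart than $Z_{\max}\le 255$, so
$Z_{\max}-d_{\min}\ge 0$ always. In a $d$-dimensional box, however,
$d_{\min}$ can reach $255\sqrt d\approx441$ for RGB, and the reward for
driving centroids into opposite corners then grows without bound: moving
both centroids apart gains $d_{\min}$ at twice the rate it costs
$\bar d_{\max}$, so for $y_1=y_2$ the corner pull always wins and the
"optimal" segmentation is garbage. The pipeline therefore minimises
$y_1\bar d_{\max}+y_2\max(0,\,Z_{\max}-d_{\min})$: once clusters are
separated by more than $Z_{\max}$ there is no further reward. In 1-D the
clamp never triggers, so this is the exact property the original setting
guarantees implicitly, generalised rather than altered.

**Empty clusters are infeasible.** $\bar d_{\max}$ gives an empty cluster
a compactness contribution of zero (the function stays defined everywhere),
but a candidate that leaves a cluster empty is not a $K$-cluster
segmentation, and an unguarded optimiser exploits it as the extreme form of
the corner solution. Such candidates receive a finite penalty strictly
above every feasible objective value, so the search treats them as
infeasible without ever seeing a non-finite number.

## Preprocessing and the colormap

The pipeline first stretches the observed intensity range to $[0,255]$
(affine remap with endpoint clipping; a constant image maps to 0 by
convention), then converts intensities to RGB through a fixed 256-entry
lookup table, and clusters the RGB triples. Clustering colour triples
rather than raw intensities lets the colormap *shape the feature geometry*:

* **dark range (0–160)**: short arc (~0.5 colour units per intensity unit)
  — background and brain tissue are compressed toward similar colours;
* **gap (160–200)**: long arc (~4 per unit) — the no-man's-land between
  tissue and tumor intensities is stretched;
* **tumor range (200–255)**: short arc again (~0.7 per unit) — the tumor
  stays a compact colour cluster even when noise spreads its intensities.

This profile matters for K = 2. The worst-case-average compactness term is
a minimax: it focuses on the most expensive cluster. If the bright range
were mapped to a long colour arc, a noisy tumor would *be* that expensive
cluster, and the single-objective optimum would split the tumor arc between
both centroids instead of separating tumor from tissue — the objective
would actively prefer a misclassifying solution, and a better optimiser
would then produce a worse segmentation. With the plateau profile the
tumor cluster stays cheap, the tumor-separating partition remains the
optimum well past the noise levels used in the tests, and optimiser
quality translates into segmentation quality with the expected sign.
The tumor cluster is finally identified as the one with the brightest
centroid (highest mean channel value), ties toward the lower index.

## The optimiser

The ABC colony holds `sn = 20` food sources (candidate centroid vectors)
in the box $[0,255]^{K\cdot d}$. Each cycle runs three phases:

* **employed**: each source gets one candidate built by perturbing a single
  random dimension toward a random partner, $v_j = x_j+\phi(x_j-x_{k,j})$
  with $\phi\sim U[-1,1]$, clipped to bounds; the candidate replaces the
  source only on strict improvement, otherwise a failure counter grows.
  Ties count as failures so counters can reach the limit on plateaus
  (the clamped separation term creates genuinely flat regions).
* **onlooker**: `sn` roulette-wheel selections proportional to the nectar
  transform $1/(1+f)$ for $f\ge0$, $1+|f|$ otherwise; each selected source
  gets one more greedy trial.
* **scout**: the single worst source whose counter exceeds
  `limit = sn * K * d` is re-drawn.

The **modified** variant strengthens exploitation in two places, both
behind the `variant` switch: neighbour moves add a global-best guidance
term $\psi(\text{best}_j-x_j)$ with $\psi\sim U[0,1.5]$, and the scout
re-draw is replaced by a deterministic jump to the 50/50 blend of the
abandoned position's opposition point ($\text{lower}+\text{upper}-x$) and
the global best. These concretise the variant's two advertised
modifications — neighbour construction and the scout technique — as a
best-guided search with opposition-based restarts, a combination whose
ingredients are standard in the swarm-optimisation literature.

Defaults `sn = 20`, `t_max = 100`, `limit = sn * D` follow common ABC
practice; one dimension is perturbed per move, one scout acts per cycle.
The best-so-far objective is non-increasing by construction, every
position stays in bounds after every phase, and a run is bit-reproducible
given a seed.

## The phantom generator

Real tumor-segmentation MRI collections are rarely redistributable, so the
package ships a generator whose output exercises every pipeline stage with
an exact ground truth: an elliptical "brain" (default semi-axes 30 x 36 px
in a 128 x 128 frame, level 120) on dark background (level 10) containing a
brighter elliptical "tumor" (semi-axes 13 x 16 px, level 220), plus additive
Gaussian noise clipped to $[0,255]$. Ellipses are rasterized by a
centre-of-pixel point-in-ellipse test, so the mask is unambiguous and
independently checkable by brute force. Batch generation jitters the tumor
centre (±6 px) and semi-axes (×0.8–1.2) under a single seeded stream.

What the phantom does *not* emulate: Rician noise statistics, bias fields,
partial-volume voxels, skull/scalp structures, anatomical texture, or 3-D
continuity. Passing the phantom suite therefore demonstrates that the
optimisation and clustering machinery does what it claims on images with
the assumed three-mode structure — not that the pipeline is clinically
validated. The three intensity levels are chosen to be K-means-recoverable
modes; noise sd 10 (the "noisy" test condition) leaves the modes distinct
in colour space, and the variant-comparison batch uses the same sd 10,
where the compactness-only objective is still aligned with ground truth
but weak optimisers begin to fail on unlucky draws — the regime where the
three configurations genuinely differ.

## Numerical choices and degenerate inputs

* Nearest-centroid ties go to the lowest cluster index (deterministic).
* An empty cluster during a Lloyd update keeps its previous centroid
  (the mean of zero pixels is undefined; keeping the centroid preserves
  the SSE-descent property).
* A constant image enhances to all-zeros, clusters into a single occupied
  cluster, and yields an empty tumor mask with a warning.
* Zero-denominator evaluation ratios (e.g. precision with no positive
  predictions) report 0 and are flagged `undefined` rather than NaN, so
  CSV summaries stay numeric while degeneracies remain detectable.
* Summary tables can truncate (floor) means to a chosen number of
  decimals, matching how the reference benchmark figures are printed;
  full precision is kept internally.
* The evaluation adds the Dice coefficient alongside the confusion-matrix
  metrics; it is the standard overlap score for mask-vs-mask comparison
  and is the quantity the phantom tests threshold.

## Problem sizes used by the test and acceptance suites

Formula-level checks run about a thousand randomised micro-instances
(≤ 12 pixels) against independent brute-force oracles. Optimiser checks
use the 2-D sphere function (100 seeds, 200 cycles). Pipeline checks use
one noiseless and ten noisy 128 x 128 phantoms plus a jittered ten-phantom
batch for the three-variant comparison — thirty full segmentations, a few
seconds each. These sizes make the whole suite comfortably reproducible on
a single CPU.

## Known limitations

* 2-D slices only; no volumetric aggregation.
* K defaults to 2; the brightest-centroid tumor rule assumes the tumor is
  the brightest coherent region after enhancement.
* The ABC here is the plain colony plus the two documented modifications —
  no adaptive parameter control, parallel colonies, or constraint handling
  beyond bound clipping and the infeasibility penalty.
* Input formats are PNG and TIFF (8-bit scale); DICOM files should be
  converted upstream.
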