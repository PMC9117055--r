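# abcseg

Segmentation of bright tumor regions in 2-D grayscale brain MR images by
K-means-style pixel clustering whose centroids are located with an
**Artificial Bee Colony (ABC)** optimiser.

Plain K-means is sensitive to its starting centroids: Lloyd iterations stop
at whatever local optimum the initialisation falls into. `abcseg` instead
searches for the centroids globally. A colony of candidate centroid vectors
$x = (h_1,\dots,h_K)$ is refined through the ABC's employed / onlooker /
scout phases to minimise the clustering objective

$$f(x) \;=\; y_1\,\bar d_{\max}(Z, x)\;+\;y_2\,\bigl(Z_{\max}-d_{\min}(x)\bigr),$$

where $\bar d_{\max}$ is the largest per-cluster average distance between
pixels and their nearest centroid (compactness), $d_{\min}$ the smallest
pairwise centroid distance (separation), and $Z_{\max}$ the maximum pixel
feature value. The final labelling is a single nearest-centroid pass with
the best centroids found; the cluster with the brightest centroid is the
tumor. Three configurations are provided and compared throughout:

| configuration | optimiser | objective |
|---|---|---|
| multiobjective modified (proposed) | best-guided ABC | $y_1 = y_2 = 0.5$ |
| single-objective modified | best-guided ABC | compactness only |
| single-objective basic | plain ABC | compactness only |

Around the core sit the supporting stages: intensity-range enhancement,
colour labelling through a fixed 256-entry colormap whose arc-length
profile compresses tissue and tumor intensities while stretching the gap
between them, a synthetic brain-phantom generator with exact ground-truth
masks, and confusion-matrix evaluation (precision, sensitivity,
specificity, F-measure, accuracy, plus Dice overlap). The methods
vignette (`vignettes/abc-tumor-segmentation.Rmd`) explains the model,
the safeguards on the search objective, and every numerical choice.

## Worked example

```r
library(abcseg)

spec <- phantom_spec(noise_sd = 10, seed = 11)   # 128x128, three levels
ph   <- generate_phantom(spec)
fit  <- segment_tumor(ph, variant = "modified", objective = "multi", seed = 21)
print(fit)
summary(fit)
dice_coefficient(fit$tumor_mask, ph$mask)
```

prints

```
tumor segmentation (modified ABC, multi objective, k = 2)
  image: 128 x 128, tumor cluster: 1, tumor pixels: 651
  objective: 6.7862 after 100 cycles, elapsed 12.76 s
Tumor segmentation summary (modified ABC, multi objective)
 cluster  size centroid_1 centroid_2 centroid_3 tumor
       1   651     144.17       98.0      61.80  TRUE
       2 15733       0.00        4.9      94.83 FALSE
objective value: 6.7862 (elapsed 12.76 s)
[1] 1
```

The 651 pixels of the bright cluster are exactly the phantom's tumor
ellipse (Dice 1.0 against the ground-truth mask); its centroid sits at the
copper end of the colormap, the background/brain cluster at the navy end.
The objective value is the guarded search objective at the returned
centroids — re-evaluating `segmentation_objective()` there reproduces it.

The fitted object supports `print`, `summary`, `coef` (the centroid
matrix), `predict` (label a new image with the fitted centroids), `plot`
(label map and mask panels) and `residuals` (per-pixel distance to the
assigned centroid). `run_comparison()` runs the three standard
configurations over an image batch and tabulates per-run metrics with
mean/min/max summaries, and `reference_metrics()` loads the packaged
per-sample benchmark tables for the three configurations.

A thin CLI wraps the same functions:

```sh
exec/abcseg phantom --out-dir phantoms --n 4 --noise-sd 10 --seed 1
exec/abcseg segment --input phantoms/phantom_001.png --variant modified \
    --objective multi --seed 7 --out-prefix case1
exec/abcseg compare --out results.csv --n 10 --seed 3
```

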