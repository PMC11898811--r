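# forceseg

Weakly supervised cell-instance segmentation for stained cytology images,
with force-map boundary refinement and extreme-point supervision — as an R
package with a seeded synthetic-scene generator, so the whole method is
testable end-to-end without any external imagery.

## The problem and the method

Cytology smears contain touching, overlapping cells with faint boundaries,
and dense pixel-wise annotation is expensive. forceseg implements a
segmentation workflow that needs only weak supervision:

* **Pseudo-labels** — seeded k-means colour clustering in CIELAB (k = 3),
  a border-contrast rule to pick the foreground clusters, Gabor/LBP texture
  refinement, morphological cleanup (3×3 open, 5×5 close) and 8-connected
  components give coarse instance masks with no annotation at all.
* **Extreme points** — each cell's topmost, bottom-most, leftmost and
  rightmost pixels act as sparse spatial anchors. The point distance loss
  `L_pd = Σ_{p∈{top,bottom,left,right}} min_{q∈B} ‖p − q‖` penalises
  predicted boundaries `B` that drift from the anchors, and a boundary
  alignment loss `L_boundary = (1/|B|) Σ_{q∈B} min_{g∈G} ‖q − g‖` keeps the
  whole predicted contour near the target contour `G`.
* **Force map** — every instance pixel `p` gets an inward unit vector
  `F_p = −α (p − C)/‖p − C‖` toward its cell centroid `C`; the two-channel
  field is injected into the network after multi-scale aggregation, pushing
  touching cells apart. At inference a first pass runs with zero force, and
  its thresholded components supply the field for a refined second pass.
* **Lightweight network** — an inverted-residual encoder with taps at
  strides 4/8/16/32, softmax-weighted multi-scale aggregation
  `F_agg = Σ_l α_l F_l`, cross-scale attention
  `softmax(Q K^T/√d) V` between the stride-4 (queries) and stride-32
  (keys/values) taps, and a small bilinear-upsampling decoder. The default
  model keeps well under a 5.2 M trainable-parameter budget that is
  enforced at construction.
* **Training** — Adam (lr 0.001, weight decay 1e-5), cosine annealing,
  ±15° rotation / flip / elastic / gamma augmentation, and the combined
  loss `L_total = L_seg + 0.5·L_boundary + 0.3·L_pd` with
  `L_seg = BCE + 0.5(1 − Dice)`; the boundary and point weights ramp in
  over the first half of training.
* **Metrics** — Dice, IoU, precision, recall, F1 and boundary F1 within a
  pixel tolerance, all tested against brute-force oracles.

See `vignettes/forceseg-methods.Rmd` for the full methods account.

## Worked example

```r
library(forceseg)

# a seeded synthetic scene: 4 overlapping cells, exact ground truth
sc <- generate_scene(96, 96, n_cells = 4, overlap_target = 0.25,
                     staining_jitter = 0.1, seed = 3)
sc$overlap_fraction
#> [1] 0.2248322

# unsupervised preprocessing: pseudo-instances + extreme points
pp <- preprocess_image(sc$image, k = 3, seed = 1)
pp$pseudo_labels$n
#> [1] 3
pp$extreme_points[["1"]]$top
#> row col
#> 138  79

# the inward force field of the ground-truth labels
ff <- compute_force_field(sc$labels, alpha = 1, mode = "unit")
ff$field[round(ff$centers$row[1]) + 6, round(ff$centers$col[1]) + 1, ]
#> [1] -0.99929529 -0.03753554

# train a small model on synthetic scenes and evaluate
ds  <- synth_dataset(60, list(height = 64, width = 64, n_cells = 4,
                              overlap_target = 0.15, staining_jitter = 0.1),
                     seed = 11)
fit <- train(ds, train_config(n_epochs = 8, seed = 1, ablation = "full"))
seg <- segment(fit$model, ds$scenes[[1]]$image, two_pass = TRUE)
region_metrics(confusion(seg$labels > 0, ds$scenes[[1]]$labels > 0))$dice
#> [1] 0.8703297
```

The scene realises a pre-arbitration overlap fraction of ~0.22 against the
requested 0.25. Unsupervised preprocessing (at its 256×256 working
resolution) recovers 3 pseudo-instances from the 4 cells — the deliberately
overlapping pair merges into one component, which is exactly the failure
mode the force map and extreme points address. The force vector five rows
below a cell centroid points up with unit magnitude (row component ≈ −1;
the small column component reflects the continuous centroid).

## Command line

A thin CLI over the same functions lives at `inst/cli/forceseg.R`:

```sh
Rscript inst/cli/forceseg.R synth   --out data --n 50 --seed 1
Rscript inst/cli/forceseg.R train   --data data --out run --epochs 15 --seed 1
Rscript inst/cli/forceseg.R segment --model run/model.rds --in data --out seg --two-pass
Rscript inst/cli/forceseg.R evaluate --pred seg --truth data --out metrics.csv
Rscript inst/cli/forceseg.R ablate  --data data --out ablation --seed 1
```

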