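---
title: "forceseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{forceseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

forceseg implements a weakly supervised instance-segmentation workflow for
stained cytology images: coarse pseudo-labels from unsupervised colour and
texture analysis, sparse extreme-point annotations instead of dense masks, a
lightweight encoder–decoder with multi-scale aggregation and cross-scale
attention, and an inward-directed force field that separates touching cells.
This vignette records the model, its assumptions, the parameters that matter,
and the design decisions taken where the method left room.

## The segmentation problem and the weak-supervision model

Cytology smears show cells as roughly elliptical bodies (cytoplasm plus a
darker nucleus) on a lighter, noisy background; cells touch and overlap, and
boundaries fade where contrast is low. Dense pixel-wise annotation is
expensive, so supervision here is sparse: for each cell only its four
*extreme points* — topmost, bottom-most, leftmost and rightmost pixels — are
annotated, plus whatever a pseudo-labelling stage can recover without any
annotation at all.

The pipeline has four method components:

1. **Preprocessing to pseudo-labels.** The image is resized to 256×256,
   contrast-normalised, converted to CIELAB, and clustered with seeded
   k-means (k = 3, k-means++ initialisation, Lloyd iterations to
   convergence). The cluster farthest in LAB distance from the median colour
   of the 1-px image border is declared foreground (the border is assumed
   background-dominant), together with any cluster beyond half that maximum
   distance. A texture step keeps only pixels whose Gabor energy
   (4 orientations × wavelengths {4, 8} px) and uniform-LBP response
   (radius 1, 8 points) exceed Otsu thresholds computed within the current
   mask — a pure restriction that strips background speckle leaking through
   the colour gate. Morphology (3×3 opening, then 5×5 closing, in that
   order) cleans the mask; 8-connected components at least 20 px in area
   become pseudo-instances, and extreme points are extracted with fixed tie
   rules (top: minimum row then minimum column; bottom: maximum row then
   maximum column; left: minimum column then minimum row; right: maximum
   column then maximum row).

2. **The force field.** Each instance pixel `p` receives the vector
   `F_p = -α (p - C) / ||p - C||` toward its instance centroid `C`
   (`compute_force_field`, mode `"unit"`, default α = 1; a `"distance"` mode
   scales the magnitude by the centre distance instead). Pixels within
   0.5 px of their centroid carry the zero vector, avoiding 0/0. The field
   is injected into the network as two extra feature channels. At inference
   the instance map is not known, so a two-pass scheme is used: pass 1 runs
   with zero force channels, its thresholded components define centroids and
   a force field, and pass 2 runs with that field.

3. **The network.** A stride-2 stem followed by five inverted-residual
   stages (expansion 3) with taps at strides 4/8/16/32. Each tap is
   projected by a 1×1 convolution to a common width (64 channels), the
   stride-4 tap queries the stride-32 tap through scaled dot-product
   cross-scale attention (one token per spatial position, temperature √d,
   d = 64, residual add), and the four maps are resized to the stride-4 grid
   and summed with softmax-normalised learnable weights. The decoder runs a
   3×3 head convolution on the aggregated stride-4 features, upsamples to
   stride 2 where a skip connection from the stem joins, applies two more
   3×3 convolutions (32/16/8 channels, batch normalisation throughout,
   dropout 0.1 after the head), and finishes with a bilinear upsample to
   full resolution and a 1×1 sigmoid output convolution — the widest layers
   never run at full resolution, which keeps single-core CPU training
   practical. The default model has
   ~94k trainable parameters, well under the 5.2 M budget enforced at
   construction; the widths were chosen for single-core CPU training, via
   `model_config(width_mult = ...)` they scale up.

4. **Losses.** Training optimises
   `L_total = β_seg L_seg + β_bound(t) L_boundary + β_pd(t) L_pd` with raw
   weights 1.0 / 0.5 / 0.3 and λ = 0.5 inside
   `L_seg = BCE + λ(1 − soft Dice)`. The boundary/point weights follow a
   curriculum: they ramp linearly from 0 to their raw values over the first
   half of training (`min(1, 2·epoch/n_epochs)`), so the network first
   learns foreground/background and only then boundary refinement.

## Discrete losses, differentiable surrogates, and what the trainer optimises

The *evaluation-time* losses are discrete set distances: the point distance
loss sums, over the four extreme points, the Euclidean distance to the
nearest predicted-boundary pixel; the boundary alignment loss is the
directed mean distance from predicted to target boundary pixels. Both are
exact, tested against exhaustive double loops, and both use a sentinel
penalty (the image diagonal, ×4 for the four points) when a boundary is
empty, so degenerate predictions are penalised finitely.

These discrete minima are not differentiable in the predicted
probabilities. `differentiable_surrogates()` provides soft counterparts: a
soft boundary map `b = max(ŷ − minpool3(ŷ), 0)` (differences below 0.1 are
treated as flat so probability noise carries no boundary mass), the
boundary surrogate `Σ b·D / Σ b` with `D` the distance transform of the
target boundary, and a log-sum-exp soft minimum (temperature 1 px) of each
extreme point's distance to the soft boundary mass. Both reduce to the
discrete losses within 1 px on hard masks.

The training loop, however, does **not** optimise the normalised surrogate:
its gradient `(D − L)/Σb` concentrates on the prediction's transition ring
at roughly two orders of magnitude above the mean-BCE gradient, and in
controlled runs it *reduced* both Dice and boundary F1 below the
no-refinement baseline. Instead the trainer uses distance-transform-weighted
misclassification penalties with the same zeros and the same intent:
`L_boundary = mean(ŷ·φ_out + (1 − ŷ)·φ_in)` where `φ` is the distance to the
true boundary — normalised by the image diagonal so the term is
dimensionless — restricted to outside/inside the true mask (predicted mass
is penalised by how far from the true boundary it is wrong), and `L_pd` is
the misclassification rate under Gaussian windows (σ = 3 px) centred on the
four extreme points (errors at the anchors are penalised specifically).
Both are zero exactly at the true mask, and their per-pixel gradients sit
at or below the mean-BCE gradient, so they refine the segmentation rather
than dominate it (without the diagonal normalisation the asymmetry between
large background distances and small cell interiors measurably shrank the
predicted masks). The logged `train_l_boundary` / `train_l_pd` columns are
these quantities.

## Force channels: why training is two-pass

Teacher-forcing the force channels from ground-truth labels was implemented
first and measurably failed in both directions: trained with a 50% zero-force
dropout, the network learned to ignore the channels entirely (the output
changed by at most ~0.02 under a ground-truth field), while the split
training regime starved the zero-force pathway that inference pass 1
depends on. Training therefore mirrors inference exactly: every sample runs
a zero-force pass and a second pass whose force field is derived from the
first pass's own thresholded prediction; both passes carry the full loss.
This keeps pass-1 fully trained and exposes the force-reading pathway only
to fields of the kind it will actually see. The injected force magnitude
follows the same curriculum ramp as the refinement losses: in the earliest
epochs, when first-pass predictions are still noise, the derived fields
would be misleading, so they are scaled in gradually as the segmentation
basics consolidate.

## The synthetic scene generator

Real cytology data is not required anywhere: `generate_scene()` draws
elliptical cells (semi-major axis 11–18% of the image side, aspect ratio
0.6–0.95, uniform orientation) with a round nucleus occupying 30–55% of the
minor axis, colours them with Pap-stain-like palettes (light pink-grey
background, cyan-blue cytoplasm, dark purple nucleus, per-cell colour
jitter), and renders granular cytoplasm texture (so cells are texturally
distinct from the additive-noise background — the property the Gabor/LBP
step keys on), coarse background blotches, per-scene staining gain/shift
jitter (default magnitude 0.1), Gaussian blur (σ = 0.8 px) and additive
noise (σ = 5 of 255). Overlapping ellipse pixels are arbitrated to the
nearest analytic centre (ties to the lower instance id) — the same
centre-based worldview as the force map — and extreme points are extracted
from the final arbitrated masks, not the analytic ellipses. Placement either
rejection-samples disjoint cells (overlap target 0, 2 px margin) or
binary-searches the centre distance to a random anchor so each new cell
shares `n·t/((n−1)(1+t))` of its own area with earlier cells, which makes
the realized scene-level shared fraction land near the target `t`.

What the generator does *not* emulate: slide artefacts, debris,
out-of-focus regions, mucus, true staining protocols, instrument vignetting,
or the morphometric differences between the five cytological categories
(the category field is a label only — no per-class shape model is published
for them). Passing tests on these scenes therefore demonstrate mechanical
correctness and the qualitative value of each component, not clinical
performance.

Default study conditions used by the test-suite ablation: 300 scenes of
64×64 px with 4 cells each, overlap target 0.15, staining jitter 0.1, split
60/20/20 by largest-remainder rounding with a seeded shuffle. Training runs
15 epochs, batch 8, Adam (learning rate 10⁻³, weight decay 10⁻⁵, the
aggregation weights in their own group at 0.1× the learning rate with decay
10⁻⁴), cosine annealing, early-stopping patience 10. These sizes keep a
full four-mode ablation tractable on one CPU core while leaving measurable
headroom below a Dice of 1.

## Numerical and convention choices

* All coordinates are 0-based `(row, col)` pairs, matching the JSON
  annotation schema; the force field's channels are (Δrow, Δcol).
* Every parameter group of the network is initialised from its own derived
  sub-seed (common random numbers): configurations that differ only in one
  group — e.g. the ablation modes, where the force channels change the head
  convolution's input width — share identical initial weights everywhere
  else. Without this, mode comparisons carried ±0.02 Dice of pure
  initialisation noise, the same order as the component effects being
  measured.
* Label maps are written as single-channel 16-bit PNG (encoder included, as
  the installed PNG bindings write only 8-bit); images as 8-bit RGB PNG;
  manifests as JSON lines.
* Minibatches are processed as single batched passes (activations carry a
  batch dimension), so batch-norm statistics are computed over batch and
  spatial positions together during training; running averages are used at
  inference, where images are processed one at a time. When the product of
  batch and grid positions falls below 4 (deep taps on tiny single-image
  inputs) normalisation degenerates, so those layers fall back to a
  per-channel affine transform.
* Histogram normalisation is a per-channel 1st–99th percentile stretch and
  contrast enhancement is CLAHE (clip 2, 8×8 tiles) applied through the
  luminance channel at half strength; full per-channel equalisation was
  rejected because it stretches the majority background across the whole
  range and destroys the colour separation the clustering relies on.
* k-means uses k-means++ seeding under a caller-supplied seed and Lloyd
  iterations; images with fewer distinct colours than k return fewer
  populated clusters rather than failing. A minimum LAB contrast of 8
  against the border colour guards foreground designation: below it the
  image is declared degenerate and the mask is empty.
* Augmentation: rotation ±15°, horizontal flip p = 0.5, elastic deformation
  from a 4×4 control grid with σ = 3 px displacements (bilinear sampling
  for the image, nearest for labels), gamma jitter in [0.8, 1.2]. Extreme
  points are always re-extracted from the transformed label map. An
  optional ±10% scale jitter sits behind `aug_params(scale_jitter = )`.
* ε-clipping at 10⁻⁷ inside BCE; Dice smoothing 1.0; loss sentinel
  `√(H² + W²)`; probability threshold 0.5 for instances; boundary-F1
  tolerance 2 px at the working resolution (the tolerance is configurable —
  no canonical value exists for it).
* Validation total loss is computed with the raw (fully ramped) weights at
  every epoch so that early stopping compares like with like; the training
  loss columns use the ramped weights actually applied.

## Known limitations

* Semantic evaluation: Dice/IoU/precision/recall/F1/BF are computed on the
  binary foreground, as the formulas define them; instance-level matching
  metrics (AP, PQ) are out of scope.
* The encoder is a width-reduced inverted-residual design, not a published
  pretrained backbone, and no pretrained weights are used — reproducibility
  is preferred over absolute accuracy.
* On easy, high-contrast scenes the baseline saturates and the refinement
  components have little room to improve; their benefit concentrates in
  scenes with overlap and faint boundaries, consistent with their purpose.
* The generator's realism limits (above) mean absolute scores on synthetic
  scenes do not transfer to clinical data.
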