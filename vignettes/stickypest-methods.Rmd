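---
title: "Saliency-based insect pest counting: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saliency-based insect pest counting: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stickypest)
```

## The problem and the model

Trap-based pest monitoring produces images with an unusually benign
structure: a near-uniform yellow card and small dark insects, typically
10–40 px across at working resolution. Sliding-window and anchor-grid
detectors spend most of their proposals on empty background, which both
wastes computation and floods the classifier's training with easy
negatives. `stickypest` instead lets the image itself nominate
candidate locations through a frequency-tuned saliency map.

For an image converted to CIELAB with planes $L, a, b$, blurred planes
$\tilde L, \tilde a, \tilde b$ (isotropic Gaussian, standard deviation
$\sigma$) and the vector of plane means
$\mu = (\bar L, \bar a, \bar b)$, the saliency of a pixel is

$$S(r, c) = \left\lVert \mu - \big[\tilde L(r,c),\, \tilde a(r,c),\,
\tilde b(r,c)\big] \right\rVert_2 .$$

Because the card dominates the image, $\mu$ is essentially the card
colour, and $S$ measures each pixel's (smoothed) colour distance from
the card. $S$ is rescaled to unit maximum, thresholded at $\alpha$
into a mask, and the mask's connected components become *activation
regions*. Regions smaller than $\beta$ px² are dropped; the rest pass
a background/foreground gate (classifier C1 at inference, an
overlap-with-annotation rule at training time) and then emit
proposals: the region's own box plus $k$ *tune-up boxes* of preset
scales centred on the region centroid. A category classifier C2 labels
every proposal; non-background labels become detections; an improved
non-maximum suppression (INMS) reduces them to one box per insect; the
count is the number of boxes.

### INMS

Conventional NMS ranks by confidence and deletes overlapping
lower-confidence boxes. With several proposals per anchor and
high inter-class similarity, a confidently misclassified partial view
can delete the correct detection. INMS first runs a *merge phase*:
boxes are processed in ascending area; the smallest box is merged into
the first same-class box it overlaps with IoU above
`merge_iou_threshold`, where merging averages coordinates weighted by
confidence and combines confidences as a noisy-OR,
$c = 1 - (1-c_0)(1-c_1)$, so agreement strictly increases confidence.
Only then is conventional NMS applied, followed by the confidence cut
$\gamma$. The merged correct-class box can now outrank the wrong-class
box and survive.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `sigma` | 3 | px | Saliency blur scale. Small enough that 10–40 px insects survive smoothing. |
| `alpha` | 0.10 | – | Mask threshold on the normalized saliency in $[0,1]$. Lower values grow activations (more background noise), higher values fragment objects. |
| `beta` | 30 | px² | Minimum activation-region box area; removes specks and very small non-targets. |
| `connectivity` | 8 | – | Component linking; 8 keeps thin appendages attached. |
| `iogt_threshold` | 0.5 | – | Training-mode foreground gate on intersection-over-ground-truth. |
| `scales` | (24,24), (32,32), (44,44) | px | Tune-up box sizes, bracketing the default synthetic insect range (12–36 px). |
| `iou_label_threshold` | 0.5 | – | Category-label assignment for training examples. |
| `merge_iou_threshold` | 0.5 | – | Minimum overlap for merging same-class detections. |
| `nms_iou_threshold` | 0.3 | – | Final suppression threshold (see below). |
| `gamma` | 0.5 | – | Minimum surviving confidence. |
| `patch_side` | 64 | px | Classifier input side. |

All are collected in `pest_config()`, which rejects unknown keys and
out-of-range values.

## Numerical and design choices

**NMS threshold 0.3, not 0.5.** Proposals for one insect are
concentric boxes of different scales. Consecutive scales overlap just
above 0.5 and merge, but the merged (averaged) box often overlaps the
next scale at IoU ≈ 0.4: a 0.5 suppression threshold then leaves two
boxes on one insect and inflates both the count and the FDR. The
stricter 0.3 — a standard operating point in the detection literature —
suppresses these concentric leftovers while being far below the
overlap of boxes on *distinct* insects at the generator's default
spacing. Both thresholds are configurable.

**NMS confidence ties prefer the tighter box.** With a deterministic
test classifier every detection has confidence 1.0, and the suppression
order among ties decides which box represents the insect. Ties are
broken by ascending box area (then `xmin`, `ymin`): the tightest box is
the best localization, and a loose duplicate — possibly with the wrong
class, from a diluted wide crop — can never suppress it. The rule is
deterministic, so detection output is byte-reproducible.

**Merged geometry and confidence.** Merging uses the
confidence-weighted coordinate average (rounded to integer pixels) and
noisy-OR confidence. The average keeps the merged box inside the
convex hull of its parents; the noisy-OR is the natural "independent
evidence" combination and guarantees the merge never lowers
confidence. If both confidences are zero the plain average is used.

**Normalization floor.** A featureless image has zero saliency in
exact arithmetic, but the blur leaves rounding residue of order
1e-13. `normalize_saliency()` treats any map with maximum below 1e-8
as identically zero rather than rescaling noise into structure.

**Zero-denominator conventions.** Precision, recall and F1 are 0 when
their denominators vanish; MAE/MSE require at least one image.

**Matching.** A detection may be "correct" for several ground truths;
it is assigned to the one it overlaps best before the per-ground-truth
best-`iogt` selection, so no detection is counted twice.

**VOC convention.** PASCAL VOC stores 1-based inclusive pixel indices;
internally boxes are 0-based half-open. `read_voc()` maps
$(x_{min}, y_{min}, x_{max}, y_{max}) \to
(x_{min}-1,\, y_{min}-1,\, x_{max},\, y_{max})$ and `write_voc()`
inverts it; the round trip is the identity and is tested.

## The lightweight CNN

The included patch classifier is a five-stage network: convolutions
$(k,s,n)$ = (7,2,40), (5,2,60), (3,2,120), each with sigmoid
activation and 2×2 max-pooling, then dense sigmoid stages of 100 and
50 units and a softmax output. With same-padding convolutions the
64 px input runs the spatial ladder 64→32→16→8→4→2→1, leaving 120
flat features. Training is mini-batch cross-entropy with adaptive
moment estimation ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$). Forward and backward passes are implemented
with im2col matrix algebra and verified against central finite
differences in the test suite.

Weight initialization defaults to a zero-mean Gaussian with standard
deviation 1, which is kept as the historical default but saturates the
sigmoid stages badly; `init_sd = 0.05` trains reliably and is what the
tests and the acceptance script use. The same architecture serves both
the background/foreground gate C1 (classes background/foreground) and
the category classifier C2; variably sized proposals are resized
bilinearly to the 64 px input, and crops beyond the image border are
padded with white pixels `[255,255,255]` to preserve the apparent
object size on the light card.

## What the synthetic generator emulates — and what it does not

`generate_scene()` draws a 320×320 card in sticky-trap yellow
(RGB 230, 200, 40) with Gaussian pixel noise (sd 5) and 3–8 insects as
filled rotated ellipses with per-insect colour jitter: the target
class in dark grey-brown (60, 50, 40) and `"others"` near black
(20, 20, 20), axes 12–36 px. Isolated insects keep a 60 px minimum
centre spacing — more than one body length, so distinct insects never
share an activation region. An `adjacency_fraction` of the insects is
instead placed touching or nearly touching a partner of the same
class, reproducing the documented miss mode in which close insects
fuse into one connected component and are counted as one. Ground-truth
boxes are the drawn pixels' tight bounding boxes, written as PASCAL
VOC XML; everything is deterministic given the seed.

The generator deliberately omits much of what makes real trap images
hard: wings, legs and body texture, specular glue highlights, uneven
illumination, debris, image compression, and insects of genuinely
similar colour across classes. Passing the synthetic end-to-end tests
therefore shows that the *pipeline machinery* — saliency, gating,
proposal geometry, suppression, counting, fusion — behaves correctly,
not that any particular classifier reaches field-grade accuracy.

The deterministic oracle classifier used in tests predicts from the
mean colour of a patch's central half. Its rule ranges were fixed once
against the generator's colour model: the two classes' colour mixtures
toward the yellow background genuinely overlap in per-channel boxes,
so a residual ~1% confusion between a heavily diluted dark insect and
a dark-brown one is intrinsic to this stand-in, and the upper bounds of
the target-class rule deliberately admit the diluted crops of fused
insect pairs so that clusters still produce a detection for the fusion
rule to anchor on.

## Problem sizes

The test suite and acceptance script run the full pipeline on 30
scenes per scenario (roughly 170–180 insects), check the component
labeller against a flood-fill oracle on 200 random 32×32 masks and the
saliency map against its per-pixel definition on 50 random 16×16
images, exercise the suppression invariants on 500 random instances of
up to 8 boxes, and train the CNN for 200 steps on 400 patches. These
sizes give stable rates (binomial standard error on DR at n ≈ 175 is
about 1.5 points) while keeping a full run in a few minutes on one
core.

## Known limitations

* Insects of different classes that touch each other form one
  activation region whose crop matches neither colour rule well; with
  the oracle classifier such clusters can be dropped entirely.
  (The generator therefore models same-class clusters, the documented
  failure mode.)
* The merge phase is greedy in area order; a different merge order can
  give different (rarely worse) boxes. The scan order is fixed and
  documented, and a literal re-implementation guards it in the tests.
* The saliency stage assumes a near-uniform background; it is not
  expected to work on cluttered field imagery without retuning
  $\alpha$, $\beta$ and $\sigma$.
* `iogt`-based matching is intentionally lenient about localization
  (a box containing the whole insect scores 1 regardless of slack), in
  line with counting accuracy being the goal rather than tight
  localization.
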