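---
title: "Two-stage vertebral landmark detection: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage vertebral landmark detection: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spinemark)
```

## The problem

Lateral lumbar radiographs are the workhorse of first-line spine
diagnostics, but they are projections: ribs, bowel gas and the pelvis
routinely occlude parts of the lumbar spine, and the L5/S1 junction is
notoriously ambiguous. Quantitative indices (lordosis angle,
spondylolisthesis grade, compression ratios) all start from the same
primitives — the center of each vertebral body and the corner points of
its end plates. `spinemark` implements a two-stage detector for those
primitives on grayscale lateral lumbar images: six vertebral centers
(L1–L5 and the upper end plate of S1) in a first pass, then the four
corner landmarks of each lumbar vertebra and the two end-plate endpoints
of S1 from per-vertebra crops in a second pass. The lower end plate of
S1 is deliberately not annotated: it is usually impossible to localize
reliably on these projections.

## Stage one: center detection

**Preprocessing.** Inputs are scaled uniformly by `512 / max(h, w)`,
anchored top-left and zero-padded right/bottom to 512×512, then Gaussian
blurred and CLAHE-equalized (`enhance()`, defaults σ = 1 px, clip 2,
8×8 tiles — the operators are standard, the parameter values are package
defaults). Padding placement is a genuine free choice; anchoring
top-left makes every frame transform a pure scale with zero offset,
which keeps the coordinate bookkeeping (`frame_transform()`,
`map_points()`) exactly invertible and trivially testable. Anyone
comparing per-point coordinates against a pipeline that pads
symmetrically must account for this.

**Targets.** Each center generates a Gaussian confidence map
$C_i(x) = \exp(-\lVert x - c_i\rVert^2 / 2\sigma^2)$ on the 64×64
heatmap grid, with σ equal to half the vertical extent of the L5 corner
landmarks expressed in heatmap pixels, computed per image. Two details
are worth stating. First, the annotated point is snapped to its nearest
pixel center before the closed form is evaluated, so the map peaks at
exactly 1 *and* matches the closed form at every pixel — without the
snap these two properties are incompatible. Second, the maps are not
renormalized to unit mass; peak value 1 is the contract, and the decoder
is a per-channel argmax with row-major tie-breaking.

**Network.** The center detector (`build_centernet()`) is a U-shaped
encoder–decoder: three stride-2 pre-activation blocks (instance norm →
ReLU → convolution) take the 512 input to the 64 heatmap scale, an
optional fourth stage descends to 32 where two wide 13×13 convolutions
form the bottleneck, and a nearest-neighbour upsample plus skip fusion
returns to 64. An intermediate branch pre-predicts the L5 map and is
concatenated back into the trunk before the 6-channel head. The wide
bottleneck kernels matter because adjacent vertebral centers sit only
about 7 heatmap pixels apart: a 13-pixel kernel (26 heatmap pixels of
span at the 32 scale) sees both neighbours of a vertebra while scoring
its center. The loss is
$L = \lVert \hat C_5 - \bar C_5 \rVert^2 + \tfrac{1}{6}\sum_i \lVert \hat C_i - C_i \rVert^2$,
supervised jointly in a single backward pass. Output heads carry no
terminal nonlinearity; values are clipped only at decode time.

The engine behind these networks is a compact CPU implementation:
im2col + GEMM convolutions in C++ (RcppArmadillo) with analytic backward
passes, instance normalization, ReLU, nearest upsampling and Adam. Every
backward pass is validated against central finite differences in the
test suite; that check, not an external framework, is the correctness
anchor.

**Random spine cutout.** During training a rectangle covering 60% of the
width and height of one vertebra chosen uniformly from {L1, L2, L3, L4}
— the vertebrae that real occlusions hit, and the darkest interiors on
our intensity calibration — is zeroed, at a position uniform over
placements fully inside that vertebra's box. The conventional cutout
(`conventional_cutout()`) is kept as a baseline; it masks an arbitrary
image position and therefore mostly hits background. The application
rate (probability 0.5 per sample) and the uniform placement are package
choices; only the 60% size and the L1–L4 candidate set are fixed by the
method.

**Gap check and repair.** When occlusion pushes the channel-1 detection
up to T12, every channel up to some index j shifts one vertebra up. The
decoder computes the Euclidean gaps $d_i$ between consecutive channel
maxima and flags the set when $\max d > 1.4 \cdot \text{mean}(d$ except
its maximum$)$. Repair (`repair_centers()`) sums all six channels,
keeps only the rows between the two maxima bounding the widest gap with
a 0.4·gap exclusion band on each side, takes the argmax of the masked
sum as the recovered center, drops the topmost original maximum and
splices the recovered point into the ordered set. Both constants (1.4,
0.4) are exposed in the configuration. Two asymmetries are preserved
deliberately because they are part of the method as specified: the gaps
use the full Euclidean norm while the repair band uses y-distance only,
and only the upward-shift mode is repaired — a spurious *bottom* point
is flagged and warned about, never guessed at. If the masked sum is
identically zero the repair is abandoned with a warning and the original
maxima are returned.

## Stage two: landmark detection

**Crop geometry.** Square windows are centered on each detected center
with side $1.5\,|y_1 - y_2|$ for L1, $0.75(|y_{i-1}-y_i| + |y_i-y_{i+1}|)$
for L2–L4, and $1.5\,|y_4-y_5|$ for both L5 and S1 — the L5–S1 spacing
itself is too variable to be a stable scale. Crops are zero-filled
outside the raster, resized to 256×256 and lightly blurred. At training
time crops are built from ground-truth centers; at inference they come
from stage one. That asymmetry is intentional (it decouples the two
training problems) and is enforced by construction in
`make_landmark_dataset()` versus `infer_image()`.

**Networks.** Two M-shaped encoder–decoders with identical trunks
(`build_landmarknet()`): four stride-2 encoder stages with downsampled
copies of the raw crop injected at each scale, a decoder with skip
connections back to 256, and a single head emitting 4 + 1 channels
(lumbar) or 2 + 1 channels (sacrum). The first two encoder stages
concatenate constant coordinate channels normalized to (−1, 1)
(`coord_channels()`): crops are centered on their vertebra, so landmark
positions have a tight location prior, and breaking translation
invariance lets the network use it — including for landmarks that are
invisible under occlusion. The test suite demonstrates the mechanism
directly: with zero coordconv stages a random-weight network is
shift-equivariant to interior translations within 1e-4; with two stages
it is not.

**Part affinity fields.** The extra head channel predicts a scalar
indicator field marking the upper and lower end-plate segments (both
plates share the one channel; the sacrum has a single segment). A pixel
belongs to the band when its perpendicular offset lies in
[−w/2, w/2) and its projection falls within the segment span; w defaults
to 4 px, where a width-4 band covers exactly 4 rows for an axis-aligned
segment. The half-open convention is a rasterization choice the method
itself leaves undefined. Landmark map σ is 1/10 of the mean diagonal of
the four corners (lumbar) or 1/6 of the inter-landmark distance
(sacrum), per crop. The losses weight the affinity term by α = 0.001
(lumbar) and β = 0.01 (sacrum); since the affinity band has far more
support than the Gaussian peaks, the small weights keep landmark
localization the primary objective while still teaching the trunk the
plate geometry.

**Decoding.** Per-channel argmax in the crop, mapped through the crop
transform back to the original frame. A quadratic sub-pixel refinement
exists in principle but is off: maximum-only decoding is the contract.
Degenerate (constant) channels fall back to the intensity centroid with
a warning rather than failing.

## Evaluation

Center distance errors are reported at the 512 input scale, separately
for inlier images and all images. An image is a center-stage *outlier*
when the crops built from its predicted centers exclude at least one of
the corresponding ground-truth landmarks — a definition about downstream
usability, not distance. Landmark errors are reported as pixel distance
D and relative distance RD (%), where the x/y errors are normalized by
the lengths of the ground-truth edges incident to that corner (the plate
edge for h, the side edge for v; "nearby landmarks" could also be read
across vertebrae, so the within-vertebra reading is stated here and kept
configurable in the code). A vertebra is a landmark-stage outlier when
its mean RD exceeds 20%, and the reported accuracy is 100 minus the
outlier percentage.

## The phantom generator

All tests and the acceptance experiment run on synthetic phantoms
(`generate_phantom()`): six filled convex quadrilaterals on a darker
background, stacked with inter-center spacing defaulting to 1/9 of the
image height (which lands the spacing near 7 heatmap pixels, matching
the geometry the detector is designed around), S1 drawn as a tilted
wedge whose two annotated points are its upper end-plate endpoints,
interior mean intensities defaulting to the caudally brightening
sequence measured on real lateral radiographs (L1 137.11 … L5 163.02;
S1, for which no measurement exists, is set once to 168 to continue the
ordering), Gaussian pixel noise, and an optional full-width darkening
band over a random run of L1–L4 emulating rib/diaphragm occlusion. The
default occlusion probability (0.35) is a free parameter: no occlusion
statistics exist for the real data, so it was fixed once at a rate that
makes occlusion common but not dominant. The default raster is 640×512
so the pad/resize path is always exercised on non-square input.

What the phantom does *not* emulate matters for interpreting green
tests: no projective shading, no trabecular texture, no neighbouring
anatomy (ribs, iliac crests), no pathology beyond tilt jitter, and an
idealized L5/S1 intensity separation. Passing the phantom suite
therefore demonstrates that the pipeline's mechanics — coordinate
bookkeeping, target construction, augmentation contracts, repair
algorithm, training loop, metric accounting — are correct; it does not
certify clinical accuracy on radiographs, which requires the real
datasets and full-scale training.

## Numerical choices and degenerate inputs

* Coordinates are 0-based pixel centers everywhere; the heatmap→input
  scale is exactly 8 with no half-pixel offset, and the in-package
  bilinear resize uses the same pure-scale convention so images and
  points share one geometry.
* Argmax ties break row-major (reading order), documented and tested.
* `crop_sizes()` refuses coincident neighbour y-coordinates (zero
  side); the inference path catches this and substitutes a fallback
  window of 0.15× image height with a warning, so one bad prediction
  still yields a full, flaggable output. The evaluation path instead
  counts such images as outliers.
* Instance normalization uses ε = 1e-5; weights initialize
  He-style (`sd = sqrt(2 / fan_in)`), biases at zero, under an explicit
  seed — two builds from the same seed are bit-identical. The output
  convolutions (the 6-channel center head, the L5 branch, and the
  landmark heads) initialize at exactly zero, so training starts from
  the zero-map prediction whose loss is the target's own mass rather
  than from initialization noise; this removes the wasted early phase
  and makes short training runs much less sensitive to the seed.
* Training uses Adam with a linearly decaying learning rate and early
  stopping on validation loss (full-scale defaults: lr 1e-4, batches
  16/32, up to 200/250 epochs, patience 30/25 for the two stages). The
  decay's end point is configurable (`lr_floor`): decaying to zero is
  appropriate over hundreds of epochs, while short desk-scale runs keep
  a floor of half the initial rate so the final epochs still learn.

## The desk-scale experiment

`smoke_experiment()` fixes a reproducible end-to-end run used by the
acceptance tests and `scripts/acceptance.R`: 200 training phantoms in
the easy condition (no occlusion, fixed spacing), 20 validation and 50
held-out test phantoms; a 4-channel-base center net trained at full 512
resolution for 14 epochs; and a 4-channel-base lumbar M-net trained for
10 epochs on the ground-truth-centered crops of 40 training phantoms
(200 crops). Both stages train with single-sample batches and learning
rate 5e-3: the easy-condition samples are nearly identical, so gradient
noise is negligible and the extra optimizer updates per epoch buy
convergence directly — at desk scale the update count, not the batch
size, is the binding constraint. These sizes are the package's own
desk-scale choice: large enough that a wiring error anywhere in the
chain (frames, targets, gradients, decoding, metrics) fails the run,
small enough to train on one CPU in minutes. The thresholds it is
checked against (center crop-outlier ratio ≤ 10%, mean center distance
≤ 8 px at 512 scale, lumbar mean RD ≤ 20%) are deliberately lenient:
they test that the mechanism works, not that a tiny network matches
full-scale accuracy.

## Known limitations

* Only the upward-shift center failure is repaired; lumbosacral
  transitional anatomy that makes L5 look like S1 remains a failure
  mode by design.
* The affinity decoder is not used to *recover* landmarks (only to
  regularize training); a post-processing decoder over the affinity
  field would be a natural extension.
* Multi-missing-center repair is out of scope; the gap statistic flags
  such stacks but the splice handles one missing center.
* The CPU engine is single-image (no batched GEMM across samples) and
  intended for desk-scale experiments, not production training.
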