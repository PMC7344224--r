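---
title: "Generalizable short-axis CMR segmentation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalizable short-axis CMR segmentation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Segmentation networks for cine cardiac MR are usually trained on one
cohort — one scanner, one site, one acquisition protocol — and then degrade
when applied to images from other scanners and sites, which differ in pixel
spacing, contrast, noise, heart pose and patient population. `cmrseg`
implements a training and inference pipeline built around the idea that
most of this domain gap is *geometric and can be normalized or augmented
away*: resample every image to a common pixel spacing, standardize its
intensities, and train with label-preserving geometric transforms (flips,
rotation, scaling, random cropping) so the network sees at training time the
variation it will meet across sites.

The segmentation target is the standard short-axis triple: left-ventricular
(LV) blood pool, LV myocardium (MYO) and right-ventricular (RV) blood pool,
encoded 1/2/3 over background 0.

## Data model

Images are handled as `VolumeImage` objects — one 3D stack of slices per
cardiac frame (end-diastole or end-systole), indexed `(z, y, x)` with
voxel-center-to-center spacing in mm — and annotations as `LabelMap` objects
on the same grid. A `SubjectStudy` pairs the ED and ES frames with optional
labels and per-structure availability flags; the flags carry partially
annotated cohorts (e.g. LV at ED and ES plus MYO at ED only) through
training and evaluation without ever treating a missing annotation as an
empty one. NIfTI I/O goes through RNifti; the on-disk `(x, y, z)` order is
adapted at the boundary so that exactly one index convention exists inside
the package. Header orientation codes are read but volumes are not
reoriented on load: pose variation is handled by augmentation, not by
registration.

## Normalization applied at train and test time

Three deterministic steps are shared between training and inference:

1. **In-plane resampling** to 1.25 × 1.25 mm (bilinear for images,
   nearest-neighbor for labels). Slice thickness is never changed. The
   output shape is `round(shape × spacing / target)` with
   half-away-from-zero rounding — the rounding rule and the zero padding
   value are this package's choices (recorded in the `GeometryRecord`), so
   inversion is exact by construction.
2. **Central crop or symmetric zero-pad** to a fixed network grid
   (256 × 256 at full scale).
3. **Per-slice intensity standardization** to mean 0, population standard
   deviation 1, computed per cropped 2D slice, with σ = 0 slices
   (e.g. fully padded ones) mapping to zeros rather than raising. Computing
   statistics per slice rather than per volume changes contrast behaviour
   across a stack; it is the deliberate choice here.

At test time the same geometry runs in reverse: per-class scores are
un-cropped/un-padded (regions that were cropped away receive zero score for
every class), bilinearly rescaled to the original in-plane grid, and only
then arg-maxed — restoring scores before class assignment keeps boundaries
subpixel-consistent. Argmax ties resolve to the lowest class index, so
undecided pixels fall to background deterministically on every platform.

## Augmentation

Training draws one augmentation event per slice per epoch (online): a
horizontal and a vertical flip each with probability 0.5, a rotation angle
uniform on [−30°, +30°], an isotropic scale factor uniform on [0.7, 1.4],
and a random placement of the fixed-size crop window. Cropping always comes
last; rotation and scaling share one warp about the image center (bilinear
for images, nearest for labels, zero fill), mirroring the resampling kernel
rule. Flips are applied before the warp; the composition order among the
non-crop transforms is a package choice. Gamma contrast
(x ↦ x^γ on [0, 1]-rescaled intensities, γ uniform on [0.7, 1.5]) is
implemented but **disabled by default**: it brings only minor improvements
and is excluded from the standard pipeline, matching the pipeline this
package reproduces. One R random stream drives all draws, so a fixed seed
reproduces an augmented epoch bit-exactly.

## The network

The segmentation model is a 2D U-Net over 4 classes, modified in two ways:
batch normalization after every hidden convolution, and dropout (rate 0.2)
after each of the four skip concatenations. With base filter count *f* the
encoder channels are (f, 2f, 4f, 8f, 8f) with two 3×3 conv–BN–ReLU blocks
per level and 2×2 max-pooling between levels; the decoder has four stages of
parameter-free bilinear 2× upsampling, skip concatenation, dropout and two
conv–BN–ReLU blocks with output channels (4f, 2f, f, f); a 1×1 convolution
(bias, no BN, no activation) produces the logits. Hidden convolutions carry
no bias — batch norm absorbs it.

This decoder layout is a *reconstruction*: the published description
specifies only "U-Net with BN and dropout" plus total convolution-weight
counts of ≈13.4 million (f = 64) and ≈0.84 million (f = 16), and the
classic U-Net decoder would give ~31 M weights at f = 64. The scheme above
reproduces both printed counts exactly (13,382,464 and 836,560 kernel
weights, ratio 16.00), which is why it was adopted.
`unetDescription()`/`countConvWeights()` expose the layer table and the
count; counts include kernel elements only, excluding biases and BN
parameters, matching how the published totals are labeled.

The forward/backward passes are implemented in this package with
RcppArmadillo kernels (im2col + GEMM convolutions, fused BN+ReLU, pooling,
bilinear upsampling); evaluation mode uses running BN statistics and no
dropout, so inference is deterministic and identical whether slices are
batched or processed one at a time.

## Training and model selection

Batches of 20 2D slices, pixelwise cross-entropy, SGD with initial learning
rate 0.001 halved every 50 epochs — these defaults reproduce the full-scale
protocol. Epochs iterate over all slices of all labeled training frames in
shuffled order. After each epoch the validation mean IoU is computed on
*augmented* validation slices — the same augmentation strategy as training,
drawn from a fixed seed each epoch so the selection signal is comparable
across epochs (the seeding is this package's choice; the protocol it
follows augments validation data but does not specify seeding). The snapshot
with the highest validation mean IoU is returned; ties go to the earliest
epoch, which acts as earlier stopping. Mean IoU averages per-class IoU over
the classes present in prediction or reference; classes absent from both
are excluded rather than scored 1. Background-only slices stay in training;
plain (unweighted) cross-entropy is used.

`trainConfig()` also exposes heavy-ball momentum, default 0 (plain SGD, the
published setting). The desk-scale runs in this package's tests use
momentum 0.9: with only a few hundred gradient steps available, plain SGD
at a feasible learning rate does not reliably leave the
all-background/class-collapse region, while momentum makes the same budget
converge stably. This is an optimizer hyperparameter of the reduced-scale
protocol, not a change to the full-scale defaults.

## Evaluation

Per structure, overlap is the 3D Dice score 2|A∩B|/(|A|+|B|) per frame (ED
and ES each as one 3D comparison), pooled over frames and subjects into
mean (sd) summaries — the pooling rule is a package choice since published
tables report one number per structure. A structure missing from a
subject's annotations contributes no entry (never a 0). Clinical parameters
are voxel-count volumes (LV and RV EDV/ESV in mL) and LV mass,
myocardial ED volume × 1.05 g/mL. Agreement uses Bland–Altman analysis with
limits MD ± 1.96 SD (sample SD, n−1) after removing pairs whose
*mean* falls outside [Q1 − 1.5 IQR, Q3 + 1.5 IQR] of the mean distribution;
quartiles use the Hazen estimator (`quantile` type 5), a choice this
package documents because the source protocol does not define its quartile
rule. Rank correlation is Spearman's ρ (Pearson on mid-ranks), reported as
ρ rather than ρ²: the protocol's tables label the quantity ambiguously, and
ρ is what "rank correlation coefficient" denotes.

## The phantom: what it emulates and what it does not

Real multi-site cohorts in this problem are access-restricted, so the
package ships an analytic short-axis phantom. Per slice, the LV cavity is a
disk whose radius tapers linearly toward the apex, the myocardium an
annulus of fixed thickness, and the RV cavity an annular crescent abutting
the epicardium; the ES frame contracts cavity radii by a factor c while
conserving myocardial cross-sectional area per slice (wall thickening
inward — an incompressibility approximation that makes LV mass
frame-independent by construction). Intensities are class means plus
Gaussian noise, with an optional contrast exponent. Geometry depends only on
the configuration; the seed drives noise, so labels are exact generating
masks and all volumes have closed forms — an oracle real data cannot give.

Two named domains mimic the cross-site setting:

* **Domain A** (training): fixed 1.8 mm in-plane spacing and 8 mm slices,
  fixed pose and contrast, noise sd 12, anatomical variation only (basal
  endocardial radius 20–27 mm, wall 6–9 mm, contraction 0.55–0.75, small
  center offsets) — a homogeneous single-scanner cohort.
* **Domain B** (shifted test): in-plane spacing uniform on 1.0–2.3 mm,
  slice thickness 5–10 mm, pose within ±45°, heart size 15–30 mm, altered
  class-mean contrast and gamma, noise sd 8–20 — the spacing range spans the
  cross-site range the pipeline is designed for.

Where neither a published value nor a protocol constraint fixed a phantom
default, values were chosen once at physiologically plausible magnitudes
(e.g. defaults give LV EDV ≈ 77 mL, LV mass ≈ 76 g, ejection fraction
≈ 58%) and not revisited. The phantom claims geometric and statistical
realism only: no MR physics (k-space, coils, banding), no papillary
muscles, no RV free wall, no inter-slice motion. Passing tests on phantoms
therefore demonstrate that the pipeline's geometry, metrics, optimization
and ablation machinery behave as designed — not clinical-grade accuracy on
patient data, which requires the restricted cohorts and GPU-scale training.

## Desk-scale study sizes

Everything in the test suite runs on one CPU. The end-to-end check trains a
base-filters-8 U-Net on a 96 × 96 grid with 34 training / 6 validation
domain-A subjects for 8 epochs (batch 20, learning rate 0.05, momentum 0.9)
and evaluates 10 held-out subjects; the ablation trains one model per
configuration row (full, no-resample, no-rotation, no-flip, no-scale) with
12/2 subjects (batch 10, up to 22 epochs with validation-plateau early
stopping, patience 6) and evaluates 6 held-out domain-A and 6 domain-B
subjects. Convolution kernels run their GEMMs in single precision — ample
for network activations and gradients and substantially faster on CPU;
parameters and all geometry/evaluation code stay in double precision.
Every ablation row shares the same weight initialization and training
stream, so the removed operation — not seed noise — drives row
differences. These sizes are the package's reduced-scale protocol,
mirroring the published strategy of running ablations at a fraction of the
full training budget.

What the phantom ablation can and cannot show: in-domain scores move
little across rows (spread below 0.05), and removing *resampling* or
*scale* augmentation clearly hurts on the shifted domain — resolution and
heart-size shifts are exactly what the phantom's domain B expresses. The
*rotation* and *flip* effects, by contrast, are the two smallest in the
full-scale setting and do not reproduce on the phantom, whose anatomy is
the structural blind spot here: a disk inside an annulus with an
annular-sector crescent is nearly invariant under in-plane rotation (only
the crescent's angular position moves, and its local appearance is
angle-independent), and the shifted domain contains no mirrored anatomy
for flip augmentation to cover. On this geometry those two augmentations
act mainly as extra task variety, which at small capacity can cost a
little rather than help — the capacity/augmentation interaction the
full-scale study itself notes. Real short-axis anatomy is not rotationally
symmetric, so this is a limit of the phantom, not of the pipeline.

## Numerical choices and degenerate inputs

* Rounding of resampled shapes: half away from zero; recorded so inversion
  is exact.
* Padding value 0 (the mean of standardized intensities); labels pad with
  background.
* Argmax ties: lowest class index.
* σ = 0 slices standardize to zeros.
* BN: ε = 1e-5, running-statistics momentum 0.1.
* Weight init: He-scaled Gaussians from the R stream; seed before
  `buildUnet()` for reproducibility.
* `seedFor()` hashes one master seed into per-stream 32-bit seeds (data
  generation, initialization, training) so partial reruns reproduce.
* Degenerate geometry (wall thicker than the cavity radius, heart extent
  beyond the field of view, RV overlap) is rejected at `phantomConfig()`
  time with a named error.

## Known limitations

The 2D slice-wise design cannot use through-plane context (the argument for
it: heterogeneous slice thickness, inter-slice motion, 2D annotations). No
test-time augmentation, no post-processing (connected components,
anatomical constraints) — predictions are raw argmax restorations. The FCN
baseline this pipeline was originally compared against is out of scope, as
are uncertainty estimates and automated quality control. Training here is
CPU-bound R/RcppArmadillo: adequate for desk-scale studies and exact
correctness tests, not for the full 1000-epoch, ~4000-subject regime.
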