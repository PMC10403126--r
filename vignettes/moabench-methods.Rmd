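---
title: "moabench: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{moabench: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moabench)
```

`moabench` compares image modalities and feature representations for
mechanism-of-action (MoA) classification in high-content screening, on
synthetic screens whose ground truth is fully known. This vignette is the
package's account of its models: what the generator emulates, what each
analysis stage assumes, which tunable parameters matter, and what passing
tests at desk scale do and do not demonstrate about real microscopy data.

## The synthetic screen

### Design structure

`screen_config()` describes a screen the way a screening facility would: a
number of 384-well plates, ten MoA classes plus the DMSO solvent control,
per-class compound counts (default 18, 20, 33, 24, 21, 21, 23, 19, 32, 20 —
231 compounds in total, a realistic imbalance), six replicate wells per
compound laid out as three technical replicates on each of two
biological-replicate plates, several imaging sites per well, and a fixed
set of DMSO control wells on every plate. `generate_layout()` assigns
compounds to plate pairs stratified by MoA and places replicates at seeded
random coordinates, with the constraint that a compound's wells occupy
different coordinates on the two plates of a pair. Real facilities use
constraint-programming layout designers for this; seeded stratified
randomization with the coordinate constraint exercises all downstream code
paths (position-decorrelated replicates, per-plate controls) without
reimplementing a layout solver.

### Phenotype model

Each site image is a field of Gaussian "cells" — a soft cytoplasm blob plus
a sharper nucleus at one third of the cell radius — shared across channels.
Treatment acts multiplicatively on per-channel amplitude:

\[
I_{c}(x) \;=\; 0.1 + b_c \, e^{\,0.5\,e\,(0.8\,u_c + 0.2\,v_c)}
  \big(w^{cyto}_c \mathrm{cyto}(x) + w^{nuc}_c \mathrm{nuc}(x)\big)
\]

where \(e\) is the compound's effect size, \(u\) a fixed unit direction per
MoA in channel space, and \(v\) a smaller fixed direction per compound, so
compounds within a class are similar but not identical (the
`compound_offset_frac` parameter, default 0.3, sets the mixing weight).
Cell density is mildly modulated by the class so that site-normalized
images retain some class signal. MoA directions are chosen maximally
spread — antipodal pairs of randomly rotated orthogonal axes — mirroring
the fact that a benchmarking assay deliberately picks classes it believes
are separable; with ten classes in five or six channel dimensions, random
directions would instead collide and put an arbitrary ceiling on every
classifier.

On top of the biology sit the injected nuisances, all logged by
`plate_effects()` so recovery is assertable: a per-plate, per-channel gain
\(\mathcal N(1, 0.1)\) and offset \(\mathcal N(0, 0.1)\); for brightfield
only, a smooth low-frequency illumination field (product of sines with
random frequency and phase, amplitude 0.2); and i.i.d. pixel noise
(sd 0.05). DMSO wells have effect zero. Rendering is deterministic per
(seed, plate, well, site).

The engineered feature table (`generate_feature_table()`) is the
feature-space counterpart — class mean + compound offset + additive plate
vector + isotropic noise in 50 dimensions — standing in for a
segmentation-and-measurement pipeline's per-site profiles. Its noise
default (`feature_noise_sd = 0.5` against unit-scale effects) puts
replicate-well correlations around 0.2–0.5, the regime typical of
morphological profiling, so grit and matching statistics are informative
rather than saturated.

### What the generator does not emulate

No photorealism: no segmentation targets, debris, saturation artefacts,
focus drift, well-edge effects, or dose–response structure. Cells are
isotropic blobs, so shape- and texture-specific phenotypes (spindle
poisons, cytoskeletal reorganization) are reduced to intensity/density
shifts. Consequently, passing tests demonstrate that the *pipeline* is
correct and that its statistics recover injected structure — not that any
particular accuracy level transfers to real assays.

## Preprocessing

Brightfield illumination inhomogeneity is corrected per z-plane by
subtracting a large-kernel Gaussian smooth of the plane
(`correct_background()`). The kernel is parameterized as a fraction of the
image side; the default fraction 101/2160 ≈ 0.047 corresponds to a
101-pixel kernel on a full-resolution 2160-pixel field. The Gaussian sd is
kernel side / 4 and boundaries are reflected, which makes the smoother
exactly averaging (rows sum to one): constant planes map to exactly zero
and constant offsets cancel. At desk-scale resolutions the same *fraction*
puts the kernel below the rendered cell size, and the high-pass then
removes the cells along with the background; pipeline configurations at 48
or 96 pixels therefore set `kernel_frac` so the kernel spans about two cell
diameters (0.25 by default in the demo). This is a resolution artefact of
downscaling, not a free dial: at full resolution the two coincide.

Two normalization strategies are compared, as both are in routine use:

* `normalize_dmso_plate()` standardizes each channel by the plate's pooled
  DMSO pixel statistics — plate effects shrink while each treatment's
  intensity *relative to its plate's controls* is preserved
  (a shift of δ becomes δ/σ).
* `normalize_site()` standardizes each image by its own per-channel
  statistics — any per-channel affine distortion is removed entirely, and
  with it all relative intensity information.

DMSO pixel statistics pool all pixels of all control sites of a plate
(rather than averaging per-well statistics); with balanced sites per well
the two differ only through site-size weighting, and pooling matches how
the statistics are consumed (pixel-level standardization). Channels with
control-pixel sd below 1e−8 raise an error rather than dividing: a
degenerate synthetic plate should fail loudly.

## Splits

`make_splits()` partitions at the compound level: per MoA, compounds are
dealt into disjoint test folds whose sizes differ by at most one (remainders
distributed round-robin over splits, walking MoAs in seed-shuffled order),
so five folds exactly tile the compound set while a single split still
holds out ~20%. Non-test compounds are assigned 80/20 to train/validation,
stratified per MoA. DMSO wells are assigned once per plate — five training,
one validation, two test wells — and the same physical wells are reused by
every split, so control pixels never leak across partitions either.
`audit_split()` re-checks, at the site-record level, that no test compound
is reachable from the training loader.

## Classifiers

No deep-learning framework is assumed: the networks are implemented in the
package on base-R matrix algebra (im2col convolutions lowered to BLAS
matrix products, Adam, batch normalization), which keeps training
bit-reproducible for a fixed seed on a fixed machine and keeps the
dependency footprint at zero.

* The image backbone (`model_config(backbone = "smallcnn")`) is a
  three-stage strided convolutional network (default 16/32/64 filters,
  kernels 5/5/3, stride 2) with global average pooling, a fully connected
  feature layer (default 64 units; its post-ReLU output is the
  "penultimate-layer" embedding used by all feature diagnostics) and a
  softmax over the 11 classes. A ResNet-scale backbone is a capacity choice
  behind the same configuration surface, not a different code path; the
  comparisons this package supports are modality- and
  normalization-comparative, not architecture-comparative.
* The feature benchmark (`backbone = "mlp"`) is one hidden layer (default
  512 units) with ReLU and batch normalization on DMSO-plate-normalized
  feature vectors.

Training minimizes multi-class cross-entropy with Adam (default learning
rate 2e−3, 20 epochs, batch 32); the checkpoint is the epoch with the best
validation macro-F1, and early stopping uses a patience of 6 epochs.
Validation-selected checkpoints mean a model can be "done" long before its
training loss converges — the package's toy-problem tests are constructed
so that validation perfection implies the property under test.
Augmentation is horizontal/vertical flips only, applied on the fly;
rotations beyond flips and blur augmentation are deliberately left out of
the default because the synthetic phenotype is isotropic. Non-finite losses
abort with diagnostics rather than continuing.

## Evaluation

Macro-F1 weights every class equally regardless of support; per-class F1
with a zero denominator is defined as 0, the standard convention that keeps
the macro average defined. Pooled per-MoA F1 concatenates the five test
sets' records before computing per-class scores. Compound-level accuracy is
the fraction of a compound's test images classified as its MoA; DMSO is a
control, not a compound, and is excluded from the compound-level scatter.
Cross-modality agreement reports Pearson correlations of compound
accuracies and the "consistently better/worse" boxes thresholded at 0.6 and
0.4, with *consistently* meaning both comparisons at once (intersection).

## Grit, sphering and matching

The grit score of a profile is its replicate correlations standardized
against its control-correlation distribution (formula in `?grit`). Whether
the control statistics should be per-profile or pooled across controls is
genuinely underdetermined in common usage, so the function exposes a
`control_stats` switch; per-profile is the default and the only variant
used elsewhere in the package. Scores are undefined for singleton groups or
zero control spread and are returned as missing with a reason, never
silently dropped. Accuracy-versus-grit uses ten equal-count bins (remainder
to the lowest bins).

Sphering is ZCA whitening with a trace-scaled ridge,
\(W = (\Sigma_c + \lambda\,\mathrm{tr}(\Sigma_c)/d \cdot I)^{-1/2}\),
fitted on control wells only and applied as \(x' = W(x - \mu_c)\). λ sweeps
over 1e−3…1 mirror the matching analysis; small λ whitens hard (and risks
amplifying control-estimation noise), large λ degenerates to centering plus
uniform scaling. W is computed by symmetric eigendecomposition and kept
exactly symmetric.

Mean average precision ranks, for every reference well, all other wells by
cosine similarity (ties broken by stable well identifier, so results are
deterministic), counts a hit when the query's MoA matches, and averages
precision over hit positions until all same-label wells are found. Controls
are excluded as queries and references (they fit the transform instead);
labels with a single well are excluded with a warning. mAP computed on
cosine similarities is invariant under any rotation about the origin but
*not* under recentering — the tests assert exactly the rotation invariance.

## Study conditions for the recovery analyses

The parameter-recovery analyses (`graded_screen_config()`,
`grit_recovery_run()`, `map_effect_sweep()`) fix these desk-scale
conditions: 10 MoA classes × 2 compounds at each of five effect levels
0, 0.3, 0.6, 1.0, 1.5 (levels decoupled from class identity); 96-pixel
images at one imaged site per well with pixel noise 0.15, placing the
classifier's accuracy transition mid-range rather than at the extremes;
compound offset fraction 0.2; feature profiles taken at five sites per
well (features are cheap where images are not). Grit is computed from the
feature-table profiles — the stable, segmentation-style representation —
while accuracy comes from the image classifier, mirroring how
phenotype-strength analyses pair an independent profile statistic with
model performance. Three seeded replicates are pooled before binning.
Under these conditions accuracy rises from near-chance in the lowest grit
bins to ~1 in the highest, and feature-space grit and sphered mAP are both
monotone in the injected effect size.

Null screens (all effects zero) are the negative control: test macro-F1
stays within the permutation band of label-shuffled predictions, and mAP
stays inside its label-permutation null band.

## Numerical choices and degenerate inputs

* Seeds: every stream (layout, per-site rendering, per-plate nuisances,
  splitting, training) derives from one user seed through an integer mixing
  function, so stages can be varied independently and all results are
  bit-reproducible on a fixed machine.
* Division guards: σ floors at 1e−8 in normalization raise errors;
  zero-variance accuracy vectors make Pearson agreement an explicit error;
  zero vectors make cosine similarity an explicit error.
* Eigenvalues in sphering are strictly positive for any λ > 0 because the
  ridge is scaled to the covariance trace.
* Tie-breaks: cosine-ranking ties resolve by well identifier; equal-count
  binning assigns remainders to the lowest bins.
* The TIFF adapter stores 16-bit pages with an affine scaling recorded in a
  JSON sidecar (baseline TIFF tags cannot carry negative-intensity
  scaling); values on the 16-bit grid round-trip exactly.

## Problem sizes

The shipped configurations are sized for a single CPU: the demo pipeline
(2 plates, 40 compounds, 48-pixel images, 2 splits, both modalities plus
the feature benchmark) completes in under a minute; the recovery analyses
(three 100-compound screens at 96 pixels plus null screens) in a few
minutes; the full test suite, including the end-to-end determinism check
that runs the demo pipeline twice, in roughly a quarter of an hour. The
18-plate, 231-compound default `screen_config()` generates layouts and
feature tables in seconds; rendering all of its images is possible but
unnecessary for any shipped analysis.

## Known limitations

* The phenotype model carries class information chiefly in channel
  amplitude; conclusions about *which* modality is better on real data do
  not transfer from synthetic screens.
* Grit depends on having enough control profiles; with very few control
  wells its control-correlation sd is itself noisy.
* Batch correction is linear (sphering); nonlinear batch effects are out of
  scope, as is providing plate identity to the classifier during training.
* Model selection maximizes validation macro-F1; no calibration of
  predicted probabilities is attempted.
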