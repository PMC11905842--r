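---
title: "Methods: postmortem hemisphere morphometry with exvivomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: postmortem hemisphere morphometry with exvivomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exvivomorph)
```

## The problem

Brain banks scan formalin-immersed hemispheres with paired T1- and
T2-weighted MRI before dissection. Postmortem scans defeat the standard
neuroimaging toolchain in three ways: the brain is surrounded by fluid
rather than skull (bright in T2, dark in T1, with only smooth
centimetre-scale artifacts where tissue carries voxel-scale texture); the
cerebellum detaches and floats several millimetres from the forebrain,
which breaks diffeomorphic registration to whole-brain atlases; and the
tissue maps must be derived from T2-weighted contrast, where white-matter
hyperintensities (WMH) masquerade as grey matter and corrupt regional
volumes. `exvivomorph` implements the processing stages that address each
of these, plus the robust statistical models applied to the resulting
regional volumes, and a phantom generator that provides complete ground
truth for every stage.

The package deliberately excludes the steps a practitioner delegates to
dedicated external tools — bias-field correction (N4), denoising, rigid
and deformable registration, tissue segmentation, super-resolution
synthesis. The pipeline declares those as input slots.

## Dual-modality patch autoencoder brain extraction

Brain extraction is a binary segmentation of 2-channel (T1, T2) images.
Three small convolutional autoencoders operate on 16x16 patches sliced
along the axial, sagittal, and coronal directions respectively. Each
model: three convolutional layers of twelve 5x5 kernels (batch
normalization, leaky rectifier with slope 0.1), spatial plan
16 -> 8 -> 4 -> 4 so the flattened code has exactly 192 features; a dense
192 -> 192 bottleneck with dropout 0.25; and three transposed-convolution
layers mirroring the encoder, the last one a single 5x5 kernel with no
normalization and no activation, emitting 16x16 logits. The model has
52,657 parameters (52,537 trainable, 120 batch-norm running statistics),
small enough to train on one CPU.

Training uses Adam (beta1 0.9, beta2 0.999, amsgrad), batch size 250, and
a staged schedule: 25 epochs at each learning rate in 0.02, 0.01, 0.005,
0.002, 0.001 at full-study settings, with 25,000 patches sampled per scan
per axis; a leave-one-out study over ten annotated scans therefore trains
each directional model on 225,000 patches. The loss is binary
cross-entropy computed from logits.

At inference a patch is evaluated at every slice along the model's
through-plane axis and on a stride-5 grid in-plane; logits of all
overlapping patches of all three models are summed per voxel and the mask
keeps strictly positive sums. Cleanup fills interior holes and removes
spurious clusters.

Design points the architecture description leaves open, resolved as
follows:

* **Downsampling.** Strides (2, 2, 1) in the encoder with "same"-style
  padding (asymmetric, smaller pad first), mirrored (1, 2, 2) in the
  decoder. Parameter counts are stride-independent; the 192-feature
  flatten pins the spatial plan.
* **Input normalisation.** Each volume is rescaled so its 1st/99th
  intensity percentiles map to [0, 1], identically at training and
  inference. Raw scanner units are arbitrary and the percentile rule is
  robust to the bright formalin tail.
* **Patch anchoring.** Patches are addressed by their minimal in-plane
  corner; training positions are uniform over valid corners; the
  inference grid appends the last valid position per axis so borders are
  always covered.
* **Cleanup.** Hole filling treats background 6-connected; clusters are
  26-connected. "Removing disconnected clusters" keeps every component at
  least 5% of the largest rather than only the largest: a postmortem
  sample is two substantial objects (hemisphere + floating cerebellum),
  and keep-largest would delete the cerebellum outright, capping the true
  positive rate near 0.88 on phantoms.
* **Batch normalization.** eps 1e-3 and running-statistics momentum 0.99,
  the common deep-learning defaults; evaluation mode uses running
  statistics only.

Masks are scored by Dice = 2TP/(2TP+FP+FN), TPR = TP/(TP+FN),
TNR = TN/(TN+FP); "pulled" metrics recompute these from confusion counts
summed across all held-out samples.

## Intensity correction and session combination

Residual low-frequency inhomogeneity in the masked T2 is estimated by
normalized convolution: smooth the masked signal and the mask with the
same Gaussian (sigma 2 mm, truncated at 4 sigma, separable), divide, and
restrict to the mask. The correction divides the original signal by this
field and rescales by one scalar so the mask mean is exactly preserved.
Dividing by the field — rather than returning the smoothed image itself —
is what "cut low spatial frequency components without altering tissue
contrast" requires: a constant image is a fixed point, and the output is
equivariant to positive rescaling of the input.

For clinical sessions with repeated anisotropic scans, every scan is
intensity-matched onto the first and the voxel-wise mean is returned.
Matching samples 100,000 voxel locations, sorts the source samples, cuts
them into consecutive batches of 29 (the trailing partial batch is
dropped), takes per batch the median of the co-located target values,
anchors it at the source intensity of the batch's median-closest pair,
and interpolates the control points piecewise-linearly with clamped
extrapolation. Target ordinates are forced non-decreasing (cumulative
maximum) so the mapping is monotone; which member of the median-closest
pair anchors the abscissa is ambiguous in prose, and the source member is
used. The result depends on which scan is first: the first scan is the
intensity reference, and callers order the session accordingly.

## Restricted atlases

Whole-brain atlases are adapted to single-hemisphere samples: ventricle
labels are removed, labels of the discarded hemisphere are removed, and
bilateral regions are cut at the midline plane — a first-axis voxel index
(90 in the MNI152 grid of the source atlases), exposed as configuration
together with the kept side because the index base and left/right sense
of the scanner frame are conventions, not facts about the method. The
template intensity is erased on the whole discarded side. Finally all
cerebellar label voxels within 2 voxels Chebyshev distance (two
dilations with a 3x3x3 element) of a cortical label are erased, opening a
seam that deformable registration can stretch to reach a cerebellum
floating away from the forebrain. Both operations only remove labels;
they are idempotent and machine-checkable.

## Tissue-constrained label fusion

Warped atlas parcellations are first cleaned against the subject tissue
map: white-matter labels cannot sit on grey-matter voxels and vice versa;
cerebellar labels are fixed by swapping the cerebellar grey/white ids to
match the tissue; each non-cerebellar label keeps its largest connected
component; cerebellar white matter regrows into unlabeled white matter
through 3x3x3 adjacency; and unlabeled grey-matter voxels with strictly
more than five cerebellar-WM voxels in their 7x7x7 box become cerebellar
grey (counteracting the atlas erosion above).

Fusion then proceeds white matter first: plain per-voxel majority over
the cleaned parcellations, per-label component pruning, and synchronous
region growing that assigns the most frequent already-selected label in
the 7x7x7 box until convergence; white-matter islands the growing cannot
reach are treated as tissue-segmentation failures and handed to the
grey-matter stage. Grey matter votes with all labels in the 5x5x5
neighborhood weighted by exp(-d^2/4) of the Euclidean distance d
(sigma = sqrt(2) voxels); the heaviest label wins. A grey-matter voxel
marked cerebellar grey in strictly more than a quarter of the cleaned
parcellations is set to cerebellar grey directly. CSF and background stay
unlabeled, as do grey-matter voxels that no vote reaches (their count is
reported). All ties break to the smallest label id, and region growing is
synchronous, so the output is deterministic and independent of scan
order; identical tissue-consistent inputs are a fixed point.

The cerebrum white matter is finally split by a Voronoi tessellation:
each white-matter voxel takes the non-cerebellar grey-matter region
nearest in Manhattan (L1) distance, computed exactly by a multi-source
6-connected breadth-first search (unit grid steps realise L1 distance;
equal-distance ties resolve to the smallest region id, mirrored by the
brute-force oracle the tests compare against). Sub-region ids are
`offset + parent id` (offset 3000), so the pairing with the parent region
stays invertible.

## Hyperintensity accounting

WMH volumes are measured per region and divided by the region volume.
Because tissue maps come from T2 contrast, hyperintense white matter is
systematically parcellated into adjacent grey-matter regions; the
corrective swap moves, for each grey-matter region g with hyperintensity
volume w, that volume from g to its Voronoi partner V(g) — volumes and
hyperintensity bookkeeping both — conserving totals exactly and making a
second pass a no-op. Donors without delineated masks receive the mean of
the volumes swapped by same-sex donors with masks, clipped at the
available region volume (clips are reported); the same per-region deltas
are replicated onto the donor's in vivo table when one exists. The swap
is table-level bookkeeping, not voxel relabeling: only volumes are
exchanged, which is also the only semantics available for the imputed
variant. Only the grey-to-white direction is implemented; a reverse flow
(white-matter volume misassigned into a grey-matter region's partner) is
not defined by the procedure.

## Morphometry and neuropathology models

Regional volumes aggregate as voxel count times voxel volume; the five
model targets are total brain, cerebrum white matter, deep grey matter
(sum of protocol labels 10, 11, 12, 13, 17, 18, 26), hippocampus (17)
and cerebellum (7 + 8); aggregates of two scans of one donor are
averaged, and an aggregate with missing member labels is NA, never 0.

All models are robust linear regressions under Huber's loss with tuning
constant 1.345 (the standard 95%-efficiency choice; the loss family is
named but its constant and the inference method are not, so asymptotic
normal two-sided p-values are reported). The volume model is
`vol ~ age + sex(F) + invivo + AD + FTD + OD + VD + M`, with M an
indicator for a missing diagnosis (diagnoses are not mutually exclusive;
M = 1 forces the others to 0). The age-neuropathology trend is fitted in
two robust steps on the sum of scores s = Thal + Braak + CERAD (range
0-14): `age ~ s + s^2`, then `|age - predicted| ~ s + s^2`; the predicted
absolute error, floored at zero (floored points are counted and
reported), is added and subtracted to draw the spread band. The quadratic
age model is printed in the source with one coefficient symbol repeated
for s and s^2; that is treated as a typographical slip and two free
coefficients are fitted, consistent with the two-step procedure. The
descriptive battery (Welch t-tests men vs women, Fisher exact tests
subgroup vs cohort, Wilcoxon rank-sum per Voronoi region, Spearman
correlations) calls the standard `stats` routines, with Bonferroni
correction over a caller-declared family size (e.g. 46 Voronoi regions)
rather than an inferred one.

Implementation note: the Huber fits delegate to `MASS::rlm`; the
hand-written components of this package are the ones that are the
method's own contribution (the patch autoencoders and their training
loop, fusion, tessellation, the swap) plus small exact utilities
(connected components, L1 BFS) for which no suitable 3D implementation
was available in the dependency set.

## The phantom generator

Phantoms emulate exactly the properties the algorithms exploit, on a
64-cubed, 0.5 mm isotropic grid by default:

* compartment intensities (arbitrary units): formalin T2 0.95 vs grey
  0.55 / white 0.35, formalin T1 0.15 vs white 0.75 — the
  bright-in-T2 / dark-in-T1 fluid signature;
* voxel-scale Gaussian texture (SD 0.03) in tissue, nearly none in fluid
  (0.01), plus a smooth artifact of scale 12 voxels (6 mm; at least 10
  voxels, i.e. centimetre-wide at this resolution) and amplitude 0.06 in
  the fluid, and an optional multiplicative bias field (amplitude 0.1,
  scale 16 voxels) over everything;
* geometry by ellipsoids: a fluid container, a forebrain (cortical shell
  over a white-matter core seeded with seven deep-grey nuclei at the
  protocol label ids, cut at the midplane to mimic a dissected
  hemisphere, cortical shell split into octant regions), and a detached
  cerebellum (grey shell, thin white branches) at least 6 voxels (3 mm)
  of fluid away from the forebrain — enforced at generation time;
* WMH blobs: spheres of radius 2-4 voxels seeded at least 2 voxels
  inside the cerebrum white matter and clipped to it, with T2 drawn at
  the grey-matter mean — reproducing the misclassification the swap
  corrects. `phantom_observed_tissue()` converts the ground-truth tissue
  map into the "as-segmented" map with WMH as grey matter;
* pseudo-atlases: the truth parcellation pulled back through independent
  Gaussian-smoothed random displacement fields (scale 4 voxels, nearest
  -voxel lookup) normalised to a requested RMS amplitude; amplitude 0 is
  exact, and a deformation that erases a label entirely is an error, not
  a silent degradation.

What the phantom does *not* model: MRI physics (no k-space, no Rician
noise), anatomy (no gyri, no partial-volume mixtures), skull or bag
interfaces, and registration failure modes beyond smooth small-amplitude
warps. Passing phantom tests therefore demonstrates algorithmic
correctness under the stated contrast/texture/topology assumptions, not
clinical performance.

The cohort generator draws neuropathology scores uniformly per component
(Thal 0-5, Braak 0-6, CERAD 0-3), ages from the quadratic trend
62 + 4s - 0.22 s^2 (years, SD 6 — rising to a plateau near s = 9 and
bending down for extreme burdens), sex 1:1, a missing-diagnosis rate of
0.16 with independent AD/FTD/OD/VD indicators otherwise (prevalences
0.45/0.08/0.15/0.12), an in vivo observation for a third of donors, and
regional volumes from the published significant coefficients of the five
aggregate models with residual SDs of a few percent of each mean volume.
These defaults are the study conditions; they are fixed, not tuned.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen once: 64-cubed phantoms; the segmentation study uses six phantoms
in two complementary leave-three-out folds with 4,000 patches per scan
per axis and a reduced two-stage schedule (0.02 and 0.01, eight epochs
each) — enough for the optimiser to converge on high-contrast phantoms
while keeping a full study under ten minutes on one CPU; fusion uses 20
pseudo-atlases at 1 mm RMS deformation; Voronoi oracle checks use 12-cubed
random parcellations; cohort models use n = 200 donors and 50 replicates.
Gradients of the hand-written network are verified against central finite
differences at relative tolerance 1e-4; grid compatibility is exact in
dims and 1e-6 mm in spacing; volumes are stored as 32-bit floats and
labels as 32-bit integers in NIfTI.

## Known limitations

* The brain extractor is 2D-patch based by design; no 3D context beyond
  the three orthogonal logit sums.
* Fusion leaves grey-matter voxels unlabeled when no vote reaches them
  within the 5x5x5 window; they are counted and reported rather than
  imputed.
* The imputed swap can clip at the available region volume; clipped
  donors are reported and their totals are then not exactly conserved by
  construction.
* `combine_session` is order-sensitive (first scan is the reference).
* The canonical orientation after manual reorientation is a configuration
  constant (`reorient()` + grid orientation metadata), not something the
  package infers from the data.
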