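# exvivomorph

Morphometry of formalin-immersed postmortem brain hemispheres imaged with
paired T1- and T2-weighted MRI.

Postmortem hemisphere scans break the standard neuroimaging toolchain: the
sample floats in fixation fluid that is bright in T2 and dark in T1 (so
skull-stripping tools fail), the cerebellum detaches and floats millimetres
away from the forebrain (so diffeomorphic registration to whole-brain
atlases tears), and tissue maps must come from T2 contrast, where
white-matter hyperintensities (WMH) look like grey matter and corrupt
regional volumes. `exvivomorph` implements a complete, tested toolchain for
these samples:

* **Brain extraction** by three compact convolutional patch autoencoders
  (one per slice direction, 16x16 two-channel patches, 52,657 parameters
  each), fused by summing per-voxel logits over overlapping stride-5 tiles
  and keeping strictly positive sums:

  `mask = { v : sum over models, patches covering v of logit(v) > 0 }`

  followed by hole filling and spurious-cluster removal. Metrics:
  Dice = 2TP/(2TP+FP+FN), TPR = TP/(TP+FN), TNR = TN/(TN+FP), per held-out
  sample and "pulled" over summed counts.
* **Intensity correction** of the masked T2 by normalized convolution
  (Gaussian sigma 2 mm): divide by the smoothed-signal / smoothed-mask
  field, then rescale so the mask mean is exactly preserved.
* **Restricted atlases** for hemisphere registration: ventricles removed,
  contralateral labels removed, bilateral regions cut at the midline plane
  (x = 90 in the source template grid), cerebellar labels eroded within 2
  voxels of cortex.
* **Tissue-constrained multi-atlas fusion**: per-atlas cleaning against the
  tissue map (with cerebellar grey/white label swapping and region
  growing), white-matter majority voting + 7x7x7 region growing, Gaussian
  -weighted (sigma sqrt(2)) 5x5x5 grey-matter voting, and a strict
  quarter-fraction cerebellar override.
* **L1 Voronoi tessellation** of the cerebrum white matter onto the nearest
  grey-matter regions (exact multi-source BFS), giving the sub-regions used
  for WMH quantification.
* **WMH accounting**: per-region fractions, the corrective volume swap
  between a grey-matter region and its Voronoi partner, the sex-averaged
  imputed swap for donors without masks, and replication of the deltas onto
  in vivo tables.
* **Robust morphometry**: Huber regressions (k = 1.345) of regional volume
  on age, sex, an in vivo indicator and diagnosis indicators
  (`vol ~ age + sex(F) + invivo + AD + FTD + OD + VD + M`), and the
  two-step robust quadratic trend of age on the sum of neuropathology
  scores with its absolute-error band. Fits expose broom-style `tidy()` /
  `glance()` and `autoplot()`.
* **Phantoms**: a synthetic-data module generating two-modality
  hemisphere-in-formalin volumes with full ground truth (mask, tissue map,
  parcellation, WMH), pseudo-atlases with controlled registration error,
  and simulated donor cohorts — every stage is testable without any
  subject data.

See the methods vignette (`vignettes/exvivomorph-methods.Rmd`) for the
model details and design decisions.

## Worked example

```r
library(exvivomorph)

# a phantom hemisphere-in-formalin sample with ground truth
ph <- make_phantom(phantom_spec(seed = 1))
ph
#> <phantom_sample> 64 x 64 x 64 at 0.5 mm, 11282 brain voxels, 382 WMH voxels

# 20 pseudo-atlases with 1 mm registration error, cleaned and fused
atlases <- make_atlas_set(ph, 20, deformation_amplitude = 1, seed = 7)
cleaned <- lapply(atlases, function(a)
  clean_warped_parcellation(a$labels, ph$truth_tissue, ph$label_table))
fused <- fuse_parcellations(cleaned, ph$truth_tissue, ph$label_table)

# Voronoi tessellation of the cerebrum white matter, volumes, WMH swap
vor <- voronoi_tessellate_wm(fused, ph$label_table)
agg <- aggregate_volumes(vor$parcellation, vor$table)
round(agg$aggregates, 1)
#>       brain cerebrum_wm     deep_gm hippocampus  cerebellum
#>      1407.1       564.0        68.1        12.8       165.4

rt <- regional_wmh_fractions(ph$wmh_mask, vor$parcellation, vor$table)
swapped <- corrective_swap(rt)
sum(rt$volume_mm3) == sum(swapped$volume_mm3)   # volume conserved
#> TRUE
```

The aggregates are in cubic millimetres (a 64-cubed phantom at 0.5 mm is a
miniature: its "brain" is ~1.4 cm^3). After the swap, every grey-matter
region's WMH volume is zero and its Voronoi partner carries it instead.

Training and applying the brain extractor:

```r
sets <- lapply(c(axial = "axial", sagittal = "sagittal", coronal = "coronal"),
               function(ax) sample_training_patches(ph$t1, ph$t2,
                                                    ph$truth_mask, ax,
                                                    4000, seed = 1))
triplet <- train_triplet(sets, train_config(learning_rates = c(0.02, 0.01),
                                            epochs_per_rate = 8))
mask <- clean_mask(infer_mask(triplet, ph$t1, ph$t2)$raw_mask)
evaluate_mask(mask, ph$truth_mask)
```

A thin command-line wrapper over the same functions lives at
`inst/cli/exvivomorph.R` (`Rscript exvivomorph.R phantom --out dir --seed 1`,
`... fuse`, `... wmh`, etc.).

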