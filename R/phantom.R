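#' Phantom specification
#'
#' Describes a synthetic two-modality "hemisphere in formalin" volume. The
#' phantom reproduces the intensity/texture/topology properties the pipeline
#' exploits, not anatomy: an air shell around a formalin ellipsoid containing
#' a forebrain (cortical grey-matter shell over a white-matter core holding
#' deep grey nuclei) and a detached cerebellum separated from the forebrain
#' by several millimetres of fluid. In T2 the formalin is markedly brighter
#' than brain tissue and in T1 darker than white matter; tissue texture lives
#' at the voxel scale while formalin carries only a smooth, centimetre-scale
#' artifact. White-matter-hyperintensity blobs take grey-matter-like T2
#' values inside the white matter, reproducing the tissue-misclassification
#' failure mode the corrective volume swap addresses.
#'
#' @param dims,spacing grid size (voxels) and isotropic voxel size (mm).
#' @param t1_means,t2_means named per-compartment mean intensities
#'   (air, formalin, gm, wm, cgm, cwm, wmh).
#' @param texture_sd named per-compartment voxel-scale noise SD.
#' @param artifact_amplitude,artifact_scale amplitude (intensity units) and
#'   Gaussian scale (voxels, >= 10) of the smooth formalin artifact.
#' @param bias_amplitude,bias_scale multiplicative bias field amplitude
#'   (fraction) and scale (voxels); 0 disables the field.
#' @param cerebellum_gap minimum formalin gap (voxels) between cerebellum and
#'   forebrain.
#' @param wmh_count,wmh_radius number of hyperintensity blobs and the
#'   (min, max) blob radius in voxels.
#' @param csf add a thin cerebrospinal-fluid shell around the cortex
#'   (off by default; the postmortem pipeline discards CSF).
#' @param forebrain_semi,cerebellum_semi ellipsoid semi-axes in voxels
#'   (defaults scale with `dims`).
#' @param hemisphere_cut cut the forebrain at its midline plane to mimic a
#'   single dissected hemisphere.
#' @param seed integer seed; phantoms are pure functions of (spec, seed).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(64L, 64L, 64L), spacing = 0.5,
                         t1_means = c(air = 0.02, formalin = 0.15, gm = 0.55,
                                      wm = 0.75, cgm = 0.55, cwm = 0.75,
                                      wmh = 0.70),
                         t2_means = c(air = 0.02, formalin = 0.95, gm = 0.55,
                                      wm = 0.35, cgm = 0.55, cwm = 0.35,
                                      wmh = 0.55),
                         texture_sd = c(air = 0.005, formalin = 0.01,
                                        gm = 0.03, wm = 0.03, cgm = 0.03,
                                        cwm = 0.03, wmh = 0.03),
                         artifact_amplitude = 0.06, artifact_scale = 12,
                         bias_amplitude = 0.1, bias_scale = 16,
                         cerebellum_gap = 6L,
                         wmh_count = 3L, wmh_radius = c(2, 4),
                         csf = FALSE,
                         forebrain_semi = NULL, cerebellum_semi = NULL,
                         hemisphere_cut = TRUE, seed = 1L) {
  dims <- as.integer(dims)
  spec <- list(dims = dims, spacing = spacing,
               t1_means = t1_means, t2_means = t2_means,
               texture_sd = texture_sd,
               artifact_amplitude = artifact_amplitude,
               artifact_scale = artifact_scale,
               bias_amplitude = bias_amplitude, bias_scale = bias_scale,
               cerebellum_gap = as.integer(cerebellum_gap),
               wmh_count = as.integer(wmh_count), wmh_radius = wmh_radius,
               csf = csf,
               forebrain_semi = forebrain_semi %||% (dims * c(0.28, 0.27, 0.24)),
               cerebellum_semi = cerebellum_semi %||% (dims * c(0.12, 0.105, 0.095)),
               hemisphere_cut = hemisphere_cut, seed = as.integer(seed))
  if (t2_means["formalin"] <= max(t2_means[c("gm", "wm")])) {
    abort("T2 formalin mean must exceed the T2 tissue means")
  }
  if (t1_means["formalin"] >= t1_means["wm"]) {
    abort("T1 formalin mean must be below the T1 white-matter mean")
  }
  if (artifact_scale < 10) {
    abort("the formalin artifact scale must be >= 10 voxels (centimetre-wide)")
  }
  if (spec$cerebellum_gap < 1L) abort("`cerebellum_gap` must be positive")
  structure(spec, class = "phantom_spec")
}

# squared normalised ellipsoid radius field ((x-c)/a)^2 summed over axes
ellipsoid_rho2 <- function(dims, center, semi) {
  g <- lapply(1:3, function(a) ((seq_len(dims[a]) - center[a]) / semi[a])^2)
  outer(outer(g[[1]], g[[2]], `+`), g[[3]], `+`)
}

unit_smooth_field <- function(dims, scale) {
  f <- smooth_gaussian(array(rnorm(prod(dims)), dims), scale)
  f / sd(f)
}

# deep grey nuclei: DKT-protocol ids, offsets as fractions of the forebrain
# semi-axes (all on the kept side of the hemisphere cut), radii in voxels
DEEP_NUCLEI <- data.frame(
  label = c(10L, 11L, 12L, 13L, 17L, 18L, 26L),
  name = c("thalamus", "caudate", "putamen", "pallidum",
           "hippocampus", "amygdala", "accumbens"),
  fx = c(-0.35, -0.15, -0.60, -0.12, -0.30, -0.12, -0.35),
  fy = c(0.10, 0.35, 0.05, -0.10, -0.35, -0.40, 0.40),
  fz = c(0.05, 0.15, -0.05, 0.25, -0.15, 0.15, -0.25),
  radius = c(2.0, 2.2, 2.4, 1.8, 2.4, 2.0, 1.6)
)

CORTICAL_LABELS <- c(1002L, 1003L, 1005L, 1006L, 1008L, 1009L, 1011L, 1012L)

phantom_label_table <- function(csf = FALSE) {
  tbl <- rbind(
    data.frame(label = 2L, name = "cerebrum_white_matter", tissue_class = "WM",
               is_cerebellum = FALSE, is_cortical = FALSE),
    data.frame(label = 7L, name = "cerebellum_white_matter", tissue_class = "WM",
               is_cerebellum = TRUE, is_cortical = FALSE),
    data.frame(label = 8L, name = "cerebellum_grey_matter", tissue_class = "GM",
               is_cerebellum = TRUE, is_cortical = FALSE),
    data.frame(label = DEEP_NUCLEI$label, name = DEEP_NUCLEI$name,
               tissue_class = "GM", is_cerebellum = FALSE, is_cortical = FALSE),
    data.frame(label = CORTICAL_LABELS,
               name = sprintf("cortex_octant_%d", seq_along(CORTICAL_LABELS)),
               tissue_class = "GM", is_cerebellum = FALSE, is_cortical = TRUE)
  )
  if (csf) {
    tbl <- rbind(tbl, data.frame(label = 24L, name = "csf",
                                 tissue_class = "ventricle_CSF",
                                 is_cerebellum = FALSE, is_cortical = FALSE))
  }
  label_table(tbl$label, tbl$name, tbl$tissue_class, "left",
              tbl$is_cerebellum, tbl$is_cortical)
}

#' Generate a phantom sample
#'
#' Builds the paired T1/T2 volumes of a [phantom_spec()] together with the
#' complete ground truth: brain mask, tissue map, parcellation with its label
#' table, and the hyperintensity mask. Deterministic given the spec seed.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_sample` with elements `t1`, `t2`,
#'   `truth_mask`, `truth_tissue`, `truth_parcellation`, `label_table`,
#'   `wmh_mask` and `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(dims = c(32, 32, 32), wmh_count = 1,
#'                                 cerebellum_gap = 3))
#' mean(ph$t2$values[ph$truth_mask$values == 1])
#' @export
make_phantom <- function(spec = phantom_spec()) {
  set.seed(spec$seed)
  d <- spec$dims
  grid <- vox_grid(d, spec$spacing)
  center <- (d + 1) / 2

  container <- ellipsoid_rho2(d, center, d * 0.46) <= 1

  fb_center <- center + d * c(0, 0.05, 0.10)
  fb_rho2 <- ellipsoid_rho2(d, fb_center, spec$forebrain_semi)
  forebrain <- fb_rho2 <= 1
  if (spec$hemisphere_cut) {
    i1 <- slice.index(fb_rho2, 1)
    forebrain <- forebrain & (i1 <= fb_center[1])
  }
  forebrain <- forebrain & container
  fb_wm <- forebrain & fb_rho2 <= 0.8^2
  fb_gm <- forebrain & !fb_wm

  cb_center <- center + d * c(-0.06, -0.18, -0.31)
  cb_rho2 <- ellipsoid_rho2(d, cb_center, spec$cerebellum_semi)
  cerebellum <- cb_rho2 <= 1 & container
  cb_core <- cerebellum & cb_rho2 <= 0.45^2
  i2 <- slice.index(cb_rho2, 2)
  i3 <- slice.index(cb_rho2, 3)
  i1 <- slice.index(cb_rho2, 1)
  rod1 <- cerebellum & cb_rho2 <= 0.75^2 &
    abs(i2 - cb_center[2]) <= 1 & abs(i3 - cb_center[3]) <= 1
  rod2 <- cerebellum & cb_rho2 <= 0.75^2 &
    abs(i1 - cb_center[1]) <= 1 & abs(i3 - cb_center[3]) <= 1
  cb_wm <- cb_core | rod1 | rod2
  cb_gm <- cerebellum & !cb_wm

  # detachment check: the cerebellum must stay >= gap voxels from the forebrain
  near_fb <- box_count(forebrain, spec$cerebellum_gap) > 0
  if (any(near_fb & cerebellum)) {
    abort("cerebellum gap cannot be realised with these dims/semi-axes")
  }

  brain <- forebrain | cerebellum
  csf_shell <- array(FALSE, d)
  if (spec$csf) {
    csf_shell <- (fb_rho2 <= 1.12^2) & !forebrain & container
    if (spec$hemisphere_cut) {
      csf_shell <- csf_shell & (slice.index(fb_rho2, 1) <= fb_center[1])
    }
  }
  formalin <- container & !brain & !csf_shell

  # parcellation -------------------------------------------------------------
  parc <- array(0L, d)
  parc[fb_wm] <- 2L
  parc[cb_wm] <- 7L
  parc[cb_gm] <- 8L
  # cortical shell split into octants around the forebrain center
  oct_id <- 1L + (slice.index(parc, 1) > fb_center[1]) +
    2L * (slice.index(parc, 2) > fb_center[2]) +
    4L * (slice.index(parc, 3) > fb_center[3])
  parc[fb_gm] <- CORTICAL_LABELS[oct_id[fb_gm]]
  for (k in seq_len(nrow(DEEP_NUCLEI))) {
    nc <- fb_center + spec$forebrain_semi *
      c(DEEP_NUCLEI$fx[k], DEEP_NUCLEI$fy[k], DEEP_NUCLEI$fz[k])
    ball <- ellipsoid_rho2(d, nc, rep(DEEP_NUCLEI$radius[k], 3)) <= 1
    parc[ball & fb_wm] <- DEEP_NUCLEI$label[k]
  }
  if (spec$csf) parc[csf_shell] <- 24L

  tissue <- array(TISSUE_BACKGROUND, d)
  tissue[parc == 2L | parc == 7L] <- TISSUE_WM
  tissue[parc == 8L | parc %in% c(DEEP_NUCLEI$label, CORTICAL_LABELS)] <- TISSUE_GM
  tissue[csf_shell] <- TISSUE_CSF

  # hyperintensity blobs inside the cerebrum white matter --------------------
  wmh <- array(FALSE, d)
  if (spec$wmh_count > 0) {
    # centers sit at least 2 voxels inside the cerebrum WM (1 voxel on small
    # grids whose WM core is too thin); larger blobs are clipped to the WM
    # compartment below
    cand <- which(box_count(parc == 2L, 2L) == 125)
    if (length(cand) == 0) cand <- which(box_count(parc == 2L, 1L) == 27)
    if (length(cand) == 0) abort("`wmh_radius` exceeds the white-matter extent")
    centers <- sample(cand, spec$wmh_count,
                      replace = length(cand) < spec$wmh_count)
    radii <- runif(spec$wmh_count, spec$wmh_radius[1], spec$wmh_radius[2])
    for (k in seq_len(spec$wmh_count)) {
      cc <- arrayInd(centers[k], d)
      wmh <- wmh | (ellipsoid_rho2(d, as.numeric(cc), rep(radii[k], 3)) <= 1)
    }
    wmh <- wmh & parc == 2L
  }

  # intensities ---------------------------------------------------------------
  comp <- array("air", d)
  comp[formalin] <- "formalin"
  comp[parc == 2L] <- "wm"
  comp[tissue == TISSUE_GM & !cb_gm] <- "gm"
  comp[cb_gm] <- "cgm"
  comp[cb_wm] <- "cwm"
  comp[wmh] <- "wmh"
  if (spec$csf) comp[csf_shell] <- "formalin"  # CSF rendered fluid-like

  t1 <- array(spec$t1_means[comp], d) +
    array(rnorm(prod(d)), d) * array(spec$texture_sd[comp], d)
  t2 <- array(spec$t2_means[comp], d) +
    array(rnorm(prod(d)), d) * array(spec$texture_sd[comp], d)
  if (spec$artifact_amplitude > 0) {
    t2[formalin] <- t2[formalin] +
      (spec$artifact_amplitude * unit_smooth_field(d, spec$artifact_scale))[formalin]
    t1[formalin] <- t1[formalin] +
      (spec$artifact_amplitude * unit_smooth_field(d, spec$artifact_scale))[formalin]
  }
  if (spec$bias_amplitude > 0) {
    t1 <- t1 * (1 + spec$bias_amplitude * unit_smooth_field(d, spec$bias_scale))
    t2 <- t2 * (1 + spec$bias_amplitude * unit_smooth_field(d, spec$bias_scale))
  }
  t1 <- pmax(t1, 0)
  t2 <- pmax(t2, 0)

  structure(list(
    t1 = scalar_volume(t1, grid),
    t2 = scalar_volume(t2, grid),
    truth_mask = binary_mask((brain) * 1L, grid),
    truth_tissue = tissue_map(tissue, grid),
    truth_parcellation = label_volume(parc, grid),
    label_table = phantom_label_table(spec$csf),
    wmh_mask = binary_mask(wmh * 1L, grid),
    spec = spec
  ), class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %d x %d x %d at %.2g mm, %d brain voxels, %d WMH voxels\n",
              x$spec$dims[1], x$spec$dims[2], x$spec$dims[3], x$spec$spacing,
              sum(x$truth_mask$values), sum(x$wmh_mask$values)))
  invisible(x)
}

#' Observed tissue map with hyperintensity misclassification
#'
#' The study tissue maps come from T2-weighted intensities, where white
#' matter hyperintensities resemble grey matter; this helper converts the
#' phantom's ground-truth tissue map into the corresponding "observed" map by
#' relabeling WMH voxels as grey matter.
#'
#' @param sample a [make_phantom()] result.
#' @return A `tissue_map`.
#' @export
phantom_observed_tissue <- function(sample) {
  t <- sample$truth_tissue$values
  t[sample$wmh_mask$values == 1L] <- TISSUE_GM
  tissue_map(t, sample$truth_tissue$grid)
}

#' Generate pseudo-atlases with controlled registration error
#'
#' Emulates a set of atlas parcellations warped onto the subject with small,
#' smooth registration errors: each atlas is the ground-truth parcellation
#' pulled back through an independent Gaussian-smoothed random displacement
#' field of the requested root-mean-square amplitude (nearest-voxel lookup),
#' paired with the template intensity image deformed the same way. Amplitude
#' 0 reproduces the truth exactly.
#'
#' @param sample a [make_phantom()] result.
#' @param n_atlases number of atlases.
#' @param deformation_amplitude RMS displacement in millimetres.
#' @param seed integer seed.
#' @param field_scale Gaussian scale of the displacement fields, voxels.
#' @return A list of `n_atlases` elements, each
#'   `list(labels = label_volume, template = scalar_volume)`.
#' @export
make_atlas_set <- function(sample, n_atlases, deformation_amplitude = 1,
                           seed = 1L, field_scale = 4) {
  if (n_atlases < 1) abort("`n_atlases` must be >= 1")
  if (deformation_amplitude < 0) abort("`deformation_amplitude` must be >= 0")
  set.seed(seed)
  d <- sample$truth_parcellation$grid$dims
  spacing <- sample$truth_parcellation$grid$spacing
  truth <- sample$truth_parcellation$values
  template <- sample$t1$values
  base_idx <- list(slice.index(truth, 1), slice.index(truth, 2),
                   slice.index(truth, 3))
  present <- setdiff(unique(as.vector(truth)), 0L)
  out <- vector("list", n_atlases)
  for (k in seq_len(n_atlases)) {
    src <- vector("list", 3)
    for (a in 1:3) {
      disp <- if (deformation_amplitude > 0) {
        unit_smooth_field(d, field_scale) * deformation_amplitude / spacing[a]
      } else {
        array(0, d)
      }
      src[[a]] <- pmin(pmax(round(base_idx[[a]] + disp), 1L), d[a])
    }
    lin <- src[[1]] + d[1] * (src[[2]] - 1L) + d[1] * d[2] * (src[[3]] - 1L)
    warped <- truth[lin]
    dim(warped) <- d
    lost <- setdiff(present, unique(as.vector(warped)))
    if (length(lost) > 0) {
      abort(sprintf("deformation amplitude erased label(s) %s entirely",
                    paste(lost, collapse = ", ")))
    }
    wtemp <- template[lin]
    dim(wtemp) <- d
    out[[k]] <- list(labels = label_volume(warped, sample$truth_parcellation$grid),
                     template = scalar_volume(wtemp, sample$t1$grid))
  }
  out
}
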