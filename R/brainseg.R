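AXIS_INDEX <- c(sagittal = 1L, coronal = 2L, axial = 3L)

axis_index <- function(axis) {
  if (!axis %in% names(AXIS_INDEX)) {
    abort("`axis` must be one of axial, sagittal, coronal")
  }
  AXIS_INDEX[[axis]]
}

# extract / add a p x p patch in the slice plane orthogonal to voxel axis `a`;
# (i0, j0) is the 0-based minimal corner in the two in-plane axes (ascending)
patch_window <- function(a, s, i0, j0, p) {
  ri <- (i0 + 1L):(i0 + p)
  rj <- (j0 + 1L):(j0 + p)
  switch(a, list(s, ri, rj), list(ri, s, rj), list(ri, rj, s))
}

extract_patch <- function(arr, a, s, i0, j0, p) {
  w <- patch_window(a, s, i0, j0, p)
  out <- arr[w[[1]], w[[2]], w[[3]]]
  dim(out) <- c(p, p)
  out
}

#' Sample training patches
#'
#' Draws `n` two-channel (T1, T2) square patches at uniformly random in-bounds
#' positions in the slice direction `axis`, paired with the corresponding
#' windows of the annotated brain mask. Patch positions are defined by their
#' minimal in-plane corner; each patch lies fully inside the volume. Both
#' input volumes are percentile-normalised per volume before extraction.
#'
#' @param t1,t2 co-registered `scalar_volume`s on one grid.
#' @param mask the annotated [binary_mask()] on the same grid.
#' @param axis `"axial"`, `"sagittal"` or `"coronal"` (through-plane voxel
#'   axes 3, 1 and 2).
#' @param n number of patches.
#' @param seed integer seed; sampling is deterministic given the seed.
#' @param patch_size patch side, voxels.
#' @return An object of class `patch_set`: `inputs` (p x p x 2 x n),
#'   `targets` (p x p x 1 x n), `locations` (tibble of slice and corners).
#' @export
sample_training_patches <- function(t1, t2, mask, axis, n, seed = 1L,
                                    patch_size = 16L) {
  stop_if_grid_mismatch(t1, t2, "T1 and T2")
  stop_if_grid_mismatch(t1, mask, "scans and mask")
  a <- axis_index(axis)
  p <- as.integer(patch_size)
  d <- t1$grid$dims
  inplane <- setdiff(1:3, a)
  if (any(d[inplane] < p)) {
    abort(sprintf("in-plane dimensions must be >= %d voxels", p))
  }
  n <- as.integer(n)
  v1 <- normalize_intensity(t1)$values
  v2 <- normalize_intensity(t2)$values
  mv <- mask$values
  inputs <- array(0, c(p, p, 2L, n))
  targets <- array(0, c(p, p, 1L, n))
  set.seed(seed)
  slices <- if (n > 0) sample.int(d[a], n, replace = TRUE) else integer(0)
  i0 <- if (n > 0) sample.int(d[inplane[1]] - p + 1L, n, replace = TRUE) - 1L else integer(0)
  j0 <- if (n > 0) sample.int(d[inplane[2]] - p + 1L, n, replace = TRUE) - 1L else integer(0)
  for (t in seq_len(n)) {
    inputs[, , 1L, t] <- extract_patch(v1, a, slices[t], i0[t], j0[t], p)
    inputs[, , 2L, t] <- extract_patch(v2, a, slices[t], i0[t], j0[t], p)
    targets[, , 1L, t] <- extract_patch(mv, a, slices[t], i0[t], j0[t], p)
  }
  structure(list(axis = axis, inputs = inputs, targets = targets,
                 locations = tibble(slice = slices, i0 = i0, j0 = j0)),
            class = "patch_set")
}

bind_patch_sets <- function(sets) {
  if (length(sets) == 1) return(sets[[1]])
  ns <- vapply(sets, function(s) dim(s$inputs)[4], integer(1))
  p <- dim(sets[[1]]$inputs)[1]
  inputs <- array(0, c(p, p, 2L, sum(ns)))
  targets <- array(0, c(p, p, 1L, sum(ns)))
  at <- 0L
  for (s in sets) {
    k <- dim(s$inputs)[4]
    if (k > 0) {
      inputs[, , , (at + 1L):(at + k)] <- s$inputs
      targets[, , , (at + 1L):(at + k)] <- s$targets
    }
    at <- at + k
  }
  structure(list(axis = sets[[1]]$axis, inputs = inputs, targets = targets,
                 locations = dplyr::bind_rows(lapply(sets, `[[`, "locations"))),
            class = "patch_set")
}

#' Patch budget of a leave-one-out fold
#'
#' Each directional model of a fold is trained on the patches of all scans
#' except the held-out one, so a leave-one-out study over `n_scans` annotated
#' scans at `per_scan` patches per scan per axis trains every model on
#' `(n_scans - 1) * per_scan` patches (225,000 at the full-study settings of
#' 10 scans and 25,000 patches).
#'
#' @param n_scans number of annotated scan pairs.
#' @param per_scan patches sampled per scan and per axis.
#' @return Integer patch count per directional model.
#' @export
loo_patch_budget <- function(n_scans, per_scan) {
  (as.integer(n_scans) - 1L) * as.integer(per_scan)
}

tile_positions <- function(n, p, stride) {
  pos <- seq.int(0L, n - p, by = stride)
  if (pos[length(pos)] != n - p) pos <- c(pos, n - p)
  pos
}

#' Tiled inference: logit-sum brain mask
#'
#' Applies each directional model to a patch at every slice along its
#' through-plane axis and on a stride grid in-plane (the final row/column
#' position is appended so the volume is fully covered). Per-voxel logits
#' from all overlapping patches of all models are summed; the raw mask keeps
#' the voxels with a strictly positive logit sum.
#'
#' @param triplet a [train_triplet()] result.
#' @param t1,t2 co-registered `scalar_volume`s; every dimension must be at
#'   least the patch size.
#' @param stride in-plane tiling stride, voxels.
#' @param axes which directional models to apply (all three by default; a
#'   subset yields that subset's logit sum, used to check fusion linearity).
#' @param chunk patches per forward batch.
#' @return A list with `logit_sum` (`scalar_volume`) and `raw_mask`
#'   (`binary_mask`).
#' @export
infer_mask <- function(triplet, t1, t2, stride = 5L,
                       axes = c("axial", "sagittal", "coronal"),
                       chunk = 1024L) {
  stop_if_grid_mismatch(t1, t2, "T1 and T2")
  d <- t1$grid$dims
  p <- triplet$spec$patch_size
  if (any(d < p)) abort(sprintf("every dimension must be >= %d voxels", p))
  probs <- triplet$normalization$probs
  v1 <- normalize_intensity(t1, probs)$values
  v2 <- normalize_intensity(t2, probs)$values
  logit <- array(0, d)
  for (axis in axes) {
    a <- axis_index(axis)
    model <- triplet$models[[axis]]
    inplane <- setdiff(1:3, a)
    combos <- expand.grid(s = seq_len(d[a]),
                          i0 = tile_positions(d[inplane[1]], p, stride),
                          j0 = tile_positions(d[inplane[2]], p, stride))
    for (start in seq(1L, nrow(combos), by = chunk)) {
      rows <- start:min(start + chunk - 1L, nrow(combos))
      xb <- array(0, c(p, p, 2L, length(rows)))
      for (t in seq_along(rows)) {
        r <- combos[rows[t], ]
        xb[, , 1L, t] <- extract_patch(v1, a, r$s, r$i0, r$j0, p)
        xb[, , 2L, t] <- extract_patch(v2, a, r$s, r$i0, r$j0, p)
      }
      z <- net_forward(model, xb, training = FALSE)$out
      for (t in seq_along(rows)) {
        r <- combos[rows[t], ]
        w <- patch_window(a, r$s, r$i0, r$j0, p)
        logit[w[[1]], w[[2]], w[[3]]] <-
          logit[w[[1]], w[[2]], w[[3]]] + as.vector(z[, , 1L, t])
      }
    }
  }
  list(logit_sum = scalar_volume(logit, t1$grid),
       raw_mask = binary_mask((logit > 0) * 1L, t1$grid))
}

#' Morphological mask cleanup
#'
#' Fills interior holes (background components not connected to the volume
#' border, 6-connectivity) and removes disconnected spurious clusters:
#' 26-connected foreground components smaller than `min_component_fraction`
#' of the largest component are discarded. A postmortem sample is two
#' substantial objects — the hemisphere and the cerebellum floating a few
#' millimetres away in the fixation fluid — so cleanup must keep every
#' sizeable component, not just the largest one. Idempotent.
#'
#' @param raw a [binary_mask()].
#' @param min_component_fraction components at least this fraction of the
#'   largest component survive.
#' @return A cleaned `binary_mask`.
#' @export
clean_mask <- function(raw, min_component_fraction = 0.05) {
  m <- raw$values
  if (!any(m > 0L)) {
    warn("clean_mask: empty input mask")
    return(raw)
  }
  d <- dim(m)
  bg <- .cc_label(as.vector(m == 0L), d, 6L)
  dim(bg) <- d
  if (max(bg) > 0) {
    border_ids <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                           bg[, , 1], bg[, , d[3]]))
    hole <- bg > 0L & !(bg %in% setdiff(border_ids, 0L))
    m[hole] <- 1L
  }
  fg <- .cc_label(as.vector(m == 1L), d, 26L)
  sizes <- tabulate(fg)
  keep <- which(sizes >= min_component_fraction * max(sizes))
  dim(fg) <- d
  m[] <- 0L
  m[fg %in% keep] <- 1L
  binary_mask(m, raw$grid)
}

#' Segmentation metrics
#'
#' Confusion counts and the derived overlap metrics
#' Dice = 2TP / (2TP + FP + FN), TPR = TP / (TP + FN), TNR = TN / (TN + FP).
#'
#' @param pred,truth binary masks on one grid.
#' @return A one-row tibble with TP, TN, FP, FN, dice, tpr, tnr.
#' @export
evaluate_mask <- function(pred, truth) {
  stop_if_grid_mismatch(pred, truth, "masks")
  p <- pred$values > 0L
  t <- truth$values > 0L
  tp <- sum(p & t)
  tn <- sum(!p & !t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  tibble(TP = tp, TN = tn, FP = fp, FN = fn,
         dice = 2 * tp / (2 * tp + fp + fn),
         tpr = tp / (tp + fn),
         tnr = tn / (tn + fp))
}

#' Leave-one-out cross-validation of the brain extraction
#'
#' For each sample a fresh model triplet is trained on the patches of all
#' other samples and evaluated on the held-out pair after tiled inference and
#' morphological cleanup. Reports per-fold metrics, their arithmetic mean,
#' and pulled metrics recomputed from the confusion counts summed across all
#' held-out samples.
#'
#' @param samples list of samples, each a list with elements `t1`, `t2`,
#'   `mask` and optionally `id`.
#' @param config a [train_config()].
#' @param spec an [autoencoder_spec()].
#' @param stride inference tiling stride.
#' @return A tibble with one row per fold plus rows `"average"` and
#'   `"pulled"`; columns sample_id, TP, TN, FP, FN, dice, tpr, tnr.
#' @export
cross_validate <- function(samples, config = train_config(),
                           spec = autoencoder_spec(), stride = 5L) {
  if (length(samples) < 2) abort("cross-validation needs at least 2 samples")
  ids <- vapply(seq_along(samples), function(i) {
    samples[[i]]$id %||% sprintf("sample%02d", i)
  }, character(1))
  per_fold <- list()
  for (fold in seq_along(samples)) {
    train_idx <- setdiff(seq_along(samples), fold)
    patch_sets <- lapply(names(AXIS_INDEX), function(axis) {
      sets <- lapply(train_idx, function(i) {
        s <- samples[[i]]
        sample_training_patches(s$t1, s$t2, s$mask, axis,
                                config$patches_per_scan_per_axis,
                                seed = config$seed + 1000L * fold +
                                  10L * i + axis_index(axis))
      })
      bind_patch_sets(sets)
    })
    names(patch_sets) <- names(AXIS_INDEX)
    cfg <- config
    cfg$seed <- config$seed + fold
    triplet <- train_triplet(patch_sets, cfg, spec)
    held <- samples[[fold]]
    pred <- clean_mask(infer_mask(triplet, held$t1, held$t2, stride)$raw_mask)
    per_fold[[fold]] <- dplyr::mutate(evaluate_mask(pred, held$mask),
                                      sample_id = ids[fold], .before = 1)
  }
  folds <- dplyr::bind_rows(per_fold)
  avg <- tibble(sample_id = "average",
                TP = mean(folds$TP), TN = mean(folds$TN),
                FP = mean(folds$FP), FN = mean(folds$FN),
                dice = mean(folds$dice), tpr = mean(folds$tpr),
                tnr = mean(folds$tnr))
  tp <- sum(folds$TP); tn <- sum(folds$TN); fp <- sum(folds$FP); fn <- sum(folds$FN)
  pulled <- tibble(sample_id = "pulled", TP = tp, TN = tn, FP = fp, FN = fn,
                   dice = 2 * tp / (2 * tp + fp + fn),
                   tpr = tp / (tp + fn), tnr = tn / (tn + fp))
  dplyr::bind_rows(folds, avg, pulled)
}
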