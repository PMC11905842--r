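#' Restrict an atlas for postmortem hemisphere registration
#'
#' Derives a single-hemisphere atlas from a whole-brain parcellation:
#' ventricle/CSF labels are removed everywhere, labels of the discarded
#' hemisphere are removed everywhere, and for bilateral regions both the
#' label and the template intensity are zeroed on the discarded side of the
#' midline plane (the plane is a first-axis voxel index; in the MNI152
#' template space used to register the source atlases it sits at x = 90).
#'
#' @param parcellation a `label_volume`.
#' @param template the co-registered template `scalar_volume`.
#' @param table the [label_table()] covering every label.
#' @param midline_index 0-based first-axis index of the midline plane.
#' @param keep_side `"left"` or `"right"`; which hemisphere survives. Voxels
#'   with first-axis index strictly greater than `midline_index` belong to
#'   the `"right"` side under this convention.
#' @return An object of class `restricted_atlas`:
#'   `list(parcellation, template, table, midline_index, keep_side)`.
#' @export
restrict_atlas <- function(parcellation, template, table, midline_index = 90L,
                           keep_side = c("left", "right")) {
  keep_side <- match.arg(keep_side)
  stop_if_grid_mismatch(parcellation, template, "parcellation and template")
  check_labels_covered(parcellation, table)
  d <- parcellation$grid$dims
  if (midline_index < 0 || midline_index >= d[1]) {
    abort("`midline_index` lies outside the grid")
  }
  labs <- parcellation$values
  tmpl <- template$values
  drop_side <- setdiff(c("left", "right"), keep_side)
  drop_ids <- c(labels_of(table, tissue = "ventricle_CSF"),
                labels_of(table, hemisphere = drop_side))
  labs[labs %in% drop_ids] <- 0L
  # bilateral regions: cut at the midline plane (0-based index convention)
  x0 <- slice.index(labs, 1) - 1L
  discarded <- if (keep_side == "left") x0 > midline_index else x0 < midline_index
  bilateral <- labs %in% labels_of(table, hemisphere = "both")
  labs[discarded & bilateral] <- 0L
  tmpl[discarded] <- 0
  kept_table <- table[table$label %in% setdiff(unique(as.vector(labs)), 0L), ]
  out <- list(parcellation = label_volume(labs, parcellation$grid),
              template = scalar_volume(tmpl, template$grid),
              table = validate_label_table(kept_table),
              midline_index = as.integer(midline_index),
              keep_side = keep_side)
  structure(out, class = "restricted_atlas")
}

#' Erode cerebellar labels near cortex
#'
#' Removes all cerebellar labels (grey and white) within `distance_voxels`
#' Chebyshev distance of any cortical-labeled voxel, opening a thin gap that
#' deformable registration can inflate to reach a cerebellum floating away
#' from the forebrain in fixation fluid. Idempotent; an atlas without
#' cortical labels is returned unchanged.
#'
#' @param atlas a [restrict_atlas()] result.
#' @param distance_voxels erosion distance (>= 1).
#' @return The eroded `restricted_atlas`.
#' @export
erode_cerebellum <- function(atlas, distance_voxels = 2L) {
  if (distance_voxels < 1) abort("`distance_voxels` must be >= 1")
  labs <- atlas$parcellation$values
  cortical <- labels_of(atlas$table, cortical = TRUE)
  if (length(cortical) == 0 || !any(labs %in% cortical)) return(atlas)
  near_cortex <- box_count(array(labs %in% cortical, dim(labs)),
                           as.integer(distance_voxels)) > 0
  cerebellar <- labs %in% labels_of(atlas$table, cerebellum = TRUE)
  labs[cerebellar & near_cortex] <- 0L
  atlas$parcellation <- label_volume(labs, atlas$parcellation$grid)
  atlas
}
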