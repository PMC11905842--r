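#' Fusion configuration
#'
#' Tuning constants of the tissue-constrained multi-atlas label fusion:
#' neighborhood half-widths for the white-matter region growing (7x7x7) and
#' the cerebellar growing (3x3x3), the strict count threshold for cerebellar
#' grey-matter completion (more than 5 cerebellar-WM voxels in the 7x7x7
#' box), the grey-matter voting neighborhood (5x5x5) with Gaussian distance
#' weights of sigma sqrt(2) voxels, the strict fraction of cleaned
#' parcellations (1/4) above which a voxel is forced to cerebellar grey
#' matter, and the component connectivity used for label pruning.
#'
#' @param wm_growth_radius,cerebellum_growth_radius box half-widths, voxels.
#' @param cgm_wm_count_threshold strict voxel-count threshold.
#' @param gm_vote_radius box half-width of the grey-matter voting.
#' @param gm_vote_sigma Gaussian sigma, voxels (Euclidean distance).
#' @param cgm_vote_fraction strict fraction for the cerebellar override.
#' @param connectivity 6 or 26, for connected-component pruning.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(wm_growth_radius = 3L, cerebellum_growth_radius = 1L,
                          cgm_wm_count_threshold = 5L, gm_vote_radius = 2L,
                          gm_vote_sigma = sqrt(2), cgm_vote_fraction = 1 / 4,
                          connectivity = 26L) {
  if (gm_vote_sigma <= 0) abort("`gm_vote_sigma` must be positive")
  if (cgm_vote_fraction <= 0 || cgm_vote_fraction >= 1) {
    abort("`cgm_vote_fraction` must lie in (0, 1)")
  }
  structure(list(wm_growth_radius = as.integer(wm_growth_radius),
                 cerebellum_growth_radius = as.integer(cerebellum_growth_radius),
                 cgm_wm_count_threshold = as.integer(cgm_wm_count_threshold),
                 gm_vote_radius = as.integer(gm_vote_radius),
                 gm_vote_sigma = gm_vote_sigma,
                 cgm_vote_fraction = cgm_vote_fraction,
                 connectivity = as.integer(connectivity)),
            class = "fusion_config")
}

keep_largest_component <- function(sel, connectivity) {
  cc <- .cc_label(as.vector(sel), dim(sel), connectivity)
  sizes <- tabulate(cc)
  if (length(sizes) <= 1) return(sel)
  dim(cc) <- dim(sel)
  cc == which.max(sizes)
}

#' Clean a warped parcellation against the tissue map
#'
#' Makes one atlas parcellation consistent with the subject's tissue map:
#' (a) non-cerebellar white-matter labels are removed from grey-matter
#' voxels, grey-matter labels from white-matter voxels, ventricle/CSF labels
#' and any label on background or CSF tissue are removed; (b) cerebellar
#' labels are fixed by swapping the cerebellar grey/white label values to
#' match the tissue class; (c) each non-cerebellar label keeps only its
#' largest connected component; (d) cerebellar white matter grows
#' iteratively into unlabeled white-matter voxels adjacent (3x3x3) to a
#' cerebellar-WM voxel; (e) unlabeled grey-matter voxels with strictly more
#' than `cgm_wm_count_threshold` cerebellar-WM voxels in their 7x7x7 box
#' become cerebellar grey matter.
#'
#' @param warped a warped atlas `label_volume`.
#' @param tissue the subject `tissue_map`.
#' @param table the [label_table()].
#' @param config a [fusion_config()].
#' @return A tissue-consistent `label_volume`.
#' @export
clean_warped_parcellation <- function(warped, tissue, table,
                                      config = fusion_config()) {
  stop_if_grid_mismatch(warped, tissue, "parcellation and tissue map")
  check_labels_covered(warped, table)
  labs <- warped$values
  tis <- tissue$values
  cwm <- cerebellar_wm_label(table)
  cgm <- cerebellar_gm_label(table)
  wm_ids <- labels_of(table, tissue = "WM", cerebellum = FALSE)
  gm_ids <- labels_of(table, tissue = "GM", cerebellum = FALSE)
  vent_ids <- labels_of(table, tissue = "ventricle_CSF")

  labs[labs %in% vent_ids] <- 0L
  labs[labs %in% wm_ids & tis != TISSUE_WM] <- 0L
  labs[labs %in% gm_ids & tis != TISSUE_GM] <- 0L
  if (!is.na(cwm)) {
    cereb <- labs %in% c(cwm, cgm)
    labs[cereb & tis == TISSUE_WM] <- cwm
    labs[cereb & tis == TISSUE_GM] <- cgm
    labs[cereb & tis != TISSUE_WM & tis != TISSUE_GM] <- 0L
  }
  for (l in intersect(c(wm_ids, gm_ids), unique(as.vector(labs)))) {
    sel <- labs == l
    keep <- keep_largest_component(sel, config$connectivity)
    labs[sel & !keep] <- 0L
  }
  if (!is.na(cwm)) {
    repeat {
      grow <- labs == 0L & tis == TISSUE_WM &
        box_count(labs == cwm, config$cerebellum_growth_radius) > 0
      if (!any(grow)) break
      labs[grow] <- cwm
    }
    fill <- labs == 0L & tis == TISSUE_GM &
      box_count(labs == cwm, config$wm_growth_radius) >
        config$cgm_wm_count_threshold
    labs[fill] <- cgm
  }
  label_volume(labs, warped$grid)
}

# per-voxel counts of label l across a list of parcellations
label_count_stack <- function(cleaned, l) {
  Reduce(`+`, lapply(cleaned, function(p) (p$values == l) * 1L))
}

# argmax over a list of per-label score arrays; ties break to the smallest
# label id (the list must be ordered by increasing id); returns 0 where no
# score is positive
argmax_label <- function(scores, ids) {
  best <- array(0, dim(scores[[1]]))
  winner <- array(0L, dim(scores[[1]]))
  for (k in seq_along(ids)) {
    better <- scores[[k]] > best
    winner[better] <- ids[k]
    best[better] <- scores[[k]][better]
  }
  winner
}

#' Fuse cleaned parcellations by tissue-constrained majority voting
#'
#' White-matter stage: each white-matter voxel takes the most frequent
#' white-matter label across the cleaned parcellations; per-label
#' disconnected components are removed; remaining unlabeled white-matter
#' voxels are filled by synchronous region growing (most frequent
#' already-selected label in the 7x7x7 box); white-matter clusters the
#' growing cannot reach are treated as tissue-segmentation failures and
#' handed to the grey-matter stage. Grey-matter stage: votes are all
#' grey-matter labels of all parcellations in the 5x5x5 neighborhood,
#' weighted by a Gaussian of the Euclidean distance to the center
#' (sigma sqrt(2)); the heaviest label wins. Any grey-matter voxel marked
#' cerebellar grey in strictly more than a quarter of the cleaned
#' parcellations is set to cerebellar grey directly. Background and CSF stay
#' unlabeled. All ties break to the smallest label id; identical
#' tissue-consistent inputs are a fixed point.
#'
#' @param cleaned list of [clean_warped_parcellation()] results on one grid.
#' @param tissue the subject `tissue_map`.
#' @param table the [label_table()].
#' @param config a [fusion_config()].
#' @return A `label_volume`; attributes `wm_failures` and `gm_unvoted` count
#'   the reassigned white-matter voxels and the grey-matter voxels no vote
#'   reached.
#' @export
fuse_parcellations <- function(cleaned, tissue, table,
                               config = fusion_config()) {
  if (length(cleaned) == 0) abort("`cleaned` must contain at least one parcellation")
  for (p in cleaned) stop_if_grid_mismatch(p, tissue, "parcellations and tissue map")
  tis <- tissue$values
  d <- dim(tis)
  n <- length(cleaned)
  cgm <- cerebellar_gm_label(table)
  wm_ids <- sort(labels_of(table, tissue = "WM"))
  gm_ids <- sort(labels_of(table, tissue = "GM"))

  # white matter: plain majority where any vote exists
  wm_counts <- lapply(wm_ids, function(l) label_count_stack(cleaned, l))
  wm_sel <- argmax_label(wm_counts, wm_ids)
  wm_sel[tis != TISSUE_WM] <- 0L
  for (l in intersect(wm_ids, unique(as.vector(wm_sel)))) {
    sel <- wm_sel == l
    keep <- keep_largest_component(sel, config$connectivity)
    wm_sel[sel & !keep] <- 0L
  }
  # synchronous region growing on the unlabeled white matter
  repeat {
    unl <- wm_sel == 0L & tis == TISSUE_WM
    if (!any(unl)) break
    counts <- lapply(wm_ids, function(l) {
      box_count(wm_sel == l, config$wm_growth_radius)
    })
    grown <- argmax_label(counts, wm_ids)
    adopt <- unl & grown > 0L
    if (!any(adopt)) break
    wm_sel[adopt] <- grown[adopt]
  }
  wm_failures <- wm_sel == 0L & tis == TISSUE_WM

  # grey matter: Gaussian-weighted neighborhood voting
  gm_zone <- tis == TISSUE_GM | wm_failures
  gm_weights <- lapply(gm_ids, function(l) {
    gauss_vote_filter(label_count_stack(cleaned, l), config$gm_vote_radius,
                      config$gm_vote_sigma)
  })
  gm_sel <- argmax_label(gm_weights, gm_ids)
  gm_sel[!gm_zone] <- 0L
  gm_unvoted <- sum(gm_zone & gm_sel == 0L)
  if (!is.na(cgm)) {
    override <- gm_zone &
      label_count_stack(cleaned, cgm) > config$cgm_vote_fraction * n
    gm_sel[override] <- cgm
  }

  fused <- wm_sel
  fused[gm_zone] <- gm_sel[gm_zone]
  out <- label_volume(fused, tissue$grid)
  attr(out, "wm_failures") <- sum(wm_failures)
  attr(out, "gm_unvoted") <- gm_unvoted
  out
}

#' L1 Voronoi tessellation of the cerebrum white matter
#'
#' Splits the single cerebrum white-matter region into sub-regions by
#' assigning every cerebrum-WM voxel the (non-cerebellar) grey-matter region
#' nearest in Manhattan (L1) distance, computed exactly by a multi-source
#' 6-connected breadth-first search over the grid. Ties at equal distance
#' resolve to the smallest grey-matter label id. Sub-region ids are
#' `offset + grey-matter label id`, which keeps the pairing with the parent
#' region invertible for the hyperintensity volume swap.
#'
#' @param parcellation a fused `label_volume`.
#' @param table the [label_table()].
#' @param offset id offset for the sub-regions.
#' @return A list with `parcellation` (relabeled `label_volume`) and `table`
#'   (the input table extended with the sub-regions actually reached and a
#'   `voronoi_partner` column on grey-matter rows).
#' @export
voronoi_tessellate_wm <- function(parcellation, table, offset = 3000L) {
  gm_ids <- labels_of(table, tissue = "GM", cerebellum = FALSE)
  labs <- parcellation$values
  if (!any(labs %in% gm_ids)) abort("no grey-matter labels present")
  wm_ids <- labels_of(table, tissue = "WM", cerebellum = FALSE)
  target <- labs %in% wm_ids
  dim(target) <- dim(labs)
  if (!any(target)) abort("no cerebrum white-matter voxels present")
  seeds <- array(0L, dim(labs))
  gm_sel <- labs %in% gm_ids
  seeds[gm_sel] <- labs[gm_sel]
  nearest <- .l1_nearest_region(seeds, dim(labs))
  labs[target] <- offset + nearest[target]
  reached <- sort(unique(nearest[target]))
  sub <- table[match(reached, table$label), ]
  sub$label <- offset + reached
  sub$name <- sprintf("wm_near_%s", sub$name)
  sub$tissue_class <- "WM"
  sub$is_cortical <- FALSE
  ext <- dplyr::bind_rows(as_tibble(table), as_tibble(sub))
  ext$voronoi_partner <- ifelse(
    ext$tissue_class == "GM" & !ext$is_cerebellum &
      (ext$label + offset) %in% sub$label,
    ext$label + offset, NA_integer_)
  list(parcellation = label_volume(labs, parcellation$grid),
       table = validate_label_table(ext))
}
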