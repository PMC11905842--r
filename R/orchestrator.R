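#' Postmortem pipeline configuration
#'
#' Wires the package stages into the postmortem processing chain. Stages run
#' in order: brain extraction (a trained [train_triplet()] applied to the
#' reoriented T1/T2 pair, or a precomputed mask supplied in its slot),
#' intensity correction of the masked T2, tissue-constrained fusion of the
#' externally warped atlases, Voronoi tessellation, volume aggregation, and
#' hyperintensity accounting when a mask is available. Inputs normally
#' produced by external tools (registered T2-in-T1, tissue map, warped
#' atlases, hyperintensity mask) are declared slots.
#'
#' @param t1,t2 co-registered `scalar_volume`s.
#' @param triplet optional trained `model_triplet`; either `triplet` or
#'   `mask` must be given.
#' @param mask optional precomputed brain [binary_mask()].
#' @param tissue subject `tissue_map` (external tissue segmentation).
#' @param atlases list of warped atlas `label_volume`s (external
#'   registration), or `NULL` to stop after intensity correction.
#' @param table the [label_table()] for the atlases.
#' @param wmh_mask optional hyperintensity [binary_mask()].
#' @param fusion a [fusion_config()].
#' @param sigma_mm intensity-correction kernel, mm.
#' @param seed integer seed recorded in the manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(t1, t2, triplet = NULL, mask = NULL, tissue = NULL,
                            atlases = NULL, table = NULL, wmh_mask = NULL,
                            fusion = fusion_config(), sigma_mm = 2, seed = 1L) {
  if (is.null(triplet) && is.null(mask)) {
    abort("provide a trained `triplet` or a precomputed `mask`")
  }
  if (!is.null(atlases) && (is.null(tissue) || is.null(table))) {
    abort("fusing atlases requires `tissue` and `table`")
  }
  structure(list(t1 = t1, t2 = t2, triplet = triplet, mask = mask,
                 tissue = tissue, atlases = atlases, table = table,
                 wmh_mask = wmh_mask, fusion = fusion, sigma_mm = sigma_mm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

manifest_entry <- function(manifest, name, object) {
  manifest[[name]] <- rlang::hash(object)
  manifest
}

#' Run the postmortem pipeline
#'
#' Executes the internal stages of the postmortem chain on one sample and
#' returns every intermediate along with a manifest of content hashes, so a
#' re-run with the same configuration can be verified to reproduce the same
#' artifacts.
#'
#' @param config a [pipeline_config()].
#' @return A list with `mask`, `t2_corrected`, `parcellation`, `table`,
#'   `regions`, `aggregates`, `region_table` (when a hyperintensity mask was
#'   supplied, post-swap), `manifest` and `log` (stage messages).
#' @export
run_postmortem <- function(config) {
  log <- character()
  manifest <- list()
  say <- function(...) log <<- c(log, sprintf(...))

  if (is.null(config$mask)) {
    say("brainseg: tiled inference + cleanup")
    inf <- infer_mask(config$triplet, config$t1, config$t2)
    mask <- clean_mask(inf$raw_mask)
  } else {
    say("brainseg: using the supplied mask")
    mask <- config$mask
  }
  manifest <- manifest_entry(manifest, "mask", mask$values)

  say("intensity: normalized-convolution correction of the masked T2")
  t2m <- config$t2
  t2m$values <- t2m$values * (mask$values > 0L)
  t2c <- correct_intensity(t2m, mask, sigma_mm = config$sigma_mm)
  manifest <- manifest_entry(manifest, "t2_corrected", t2c$values)

  if (is.null(config$atlases)) {
    say("fusion: no warped atlases declared; stopping after intensity correction")
    return(list(mask = mask, t2_corrected = t2c, parcellation = NULL,
                manifest = manifest, log = log))
  }

  say("fusion: cleaning %d warped parcellations", length(config$atlases))
  cleaned <- lapply(config$atlases, clean_warped_parcellation,
                    tissue = config$tissue, table = config$table,
                    config = config$fusion)
  say("fusion: tissue-constrained majority voting")
  fused <- fuse_parcellations(cleaned, config$tissue, config$table,
                              config$fusion)
  say("fusion: %d WM failures reassigned, %d GM voxels unvoted",
      attr(fused, "wm_failures"), attr(fused, "gm_unvoted"))
  say("voronoi: L1 tessellation of the cerebrum white matter")
  vor <- voronoi_tessellate_wm(fused, config$table)
  manifest <- manifest_entry(manifest, "parcellation", vor$parcellation$values)

  say("morphometry: volume aggregation")
  agg <- aggregate_volumes(vor$parcellation, vor$table)

  region_table <- NULL
  if (!is.null(config$wmh_mask)) {
    say("wmh: regional fractions + corrective swap")
    fractions <- regional_wmh_fractions(config$wmh_mask, vor$parcellation,
                                        vor$table)
    region_table <- corrective_swap(fractions)
    manifest <- manifest_entry(manifest, "region_table", region_table)
  }
  manifest <- manifest_entry(manifest, "aggregates", agg$aggregates)

  list(mask = mask, t2_corrected = t2c, parcellation = vor$parcellation,
       table = vor$table, regions = agg$regions, aggregates = agg$aggregates,
       region_table = region_table, manifest = manifest, log = log)
}

#' Run the in vivo pipeline
#'
#' Combines the co-registered synthesized scans of one clinical session
#' (intensity matching to the first scan, then voxel-wise averaging), fuses
#' the supplied warped whole-brain atlases under the same tissue-constrained
#' voting, and aggregates regional volumes.
#'
#' @param session list of co-registered `scalar_volume`s (>= 1; the first is
#'   the intensity reference).
#' @param tissue subject `tissue_map`.
#' @param atlases list of warped atlas `label_volume`s.
#' @param table the [label_table()].
#' @param fusion a [fusion_config()].
#' @param seed integer seed for the intensity-matching subsample.
#' @return A list with `combined`, `parcellation`, `table`, `regions`,
#'   `aggregates` and `manifest`.
#' @export
run_invivo <- function(session, tissue, atlases, table,
                       fusion = fusion_config(), seed = 1L) {
  if (length(session) == 0) abort("`session` must contain at least one scan")
  combined <- combine_session(session, seed = seed)
  cleaned <- lapply(atlases, clean_warped_parcellation, tissue = tissue,
                    table = table, config = fusion)
  fused <- fuse_parcellations(cleaned, tissue, table, fusion)
  vor <- voronoi_tessellate_wm(fused, table)
  agg <- aggregate_volumes(vor$parcellation, vor$table)
  manifest <- list()
  manifest <- manifest_entry(manifest, "combined", combined$values)
  manifest <- manifest_entry(manifest, "parcellation", vor$parcellation$values)
  list(combined = combined, parcellation = vor$parcellation, table = vor$table,
       regions = agg$regions, aggregates = agg$aggregates, manifest = manifest)
}
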