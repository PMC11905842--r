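# Small deterministic fixtures shared across test files.

tiny_phantom <- local({
  cache <- new.env()
  function(seed = 1) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- make_phantom(phantom_spec(seed = seed))
    }
    cache[[key]]
  }
})

random_volume <- function(dims = c(8, 8, 8), spacing = 0.5, seed = 1) {
  set.seed(seed)
  scalar_volume(array(runif(prod(dims)), dims), spacing = spacing)
}

random_mask <- function(dims = c(8, 8, 8), p = 0.5, seed = 1, spacing = 1) {
  set.seed(seed)
  binary_mask(array(rbinom(prod(dims), 1, p), dims), spacing = spacing)
}

# a minimal whole-brain style label table with both hemispheres, a bilateral
# region, a ventricle and a cerebellum
mini_table <- function() {
  label_table(
    label = c(2L, 4L, 7L, 8L, 41L, 45L, 46L, 47L, 1002L, 2002L, 10L),
    name = c("left_wm", "left_ventricle", "cb_wm", "cb_gm", "right_wm",
             "right_ventricle", "right_cb_wm", "right_cb_gm",
             "left_cortex", "right_cortex", "brainstem"),
    tissue_class = c("WM", "ventricle_CSF", "WM", "GM", "WM", "ventricle_CSF",
                     "WM", "GM", "GM", "GM", "WM"),
    hemisphere = c("left", "left", "left", "left", "right", "right", "right",
                   "right", "left", "right", "both"),
    is_cerebellum = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                      FALSE, FALSE, FALSE),
    is_cortical = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    TRUE, TRUE, FALSE)
  )
}

# brute-force L1 nearest-GM oracle used to validate the BFS tessellation
brute_force_voronoi <- function(labs, gm_ids, wm_ids) {
  d <- dim(labs)
  gm_idx <- which(labs %in% gm_ids)
  gm_pos <- arrayInd(gm_idx, d)
  gm_lab <- labs[gm_idx]
  out <- labs
  for (v in which(labs %in% wm_ids)) {
    pos <- arrayInd(v, d)
    dist <- abs(gm_pos[, 1] - pos[1]) + abs(gm_pos[, 2] - pos[2]) +
      abs(gm_pos[, 3] - pos[3])
    best <- min(dist)
    out[v] <- min(gm_lab[dist == best])
  }
  out
}
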