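fusion_table <- function() {
  label_table(
    label = c(2L, 7L, 8L, 10L, 1002L, 1003L, 4L),
    name = c("wm", "cb_wm", "cb_gm", "thalamus", "cortex_a", "cortex_b",
             "ventricle"),
    tissue_class = c("WM", "WM", "GM", "GM", "GM", "GM", "ventricle_CSF"),
    hemisphere = "left",
    is_cerebellum = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    is_cortical = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)
  )
}

test_that("cleaning removes tissue-inconsistent labels and swaps cerebellar ones", {
  d <- c(16, 16, 16)
  tis <- array(0L, d)
  tis[2:15, 2:15, 2:15] <- 3L                 # WM block
  tis[2:15, 2:15, 12:15] <- 2L                # GM slab on top
  labs <- array(0L, d)
  labs[3:14, 3:14, 3:10] <- 2L                # WM label on WM tissue: kept
  labs[5, 5, 13] <- 2L                        # WM label on GM tissue: removed
  labs[6, 6, 5] <- 1002L                      # GM label on WM tissue: removed
  labs[7, 7, 13] <- 1002L                     # GM label on GM tissue: kept
  labs[8, 8, 13] <- 4L                        # ventricle label: removed
  tissue <- tissue_map(tis, spacing = 1)
  out <- clean_warped_parcellation(label_volume(labs, spacing = 1), tissue,
                                   fusion_table())
  expect_identical(out$values[5, 5, 13], 0L)
  expect_identical(out$values[6, 6, 5], 0L)
  expect_identical(out$values[7, 7, 13], 1002L)
  expect_identical(out$values[8, 8, 13], 0L)
  expect_identical(out$values[4, 4, 4], 2L)
})

test_that("cerebellar labels swap to match the tissue class", {
  d <- c(12, 12, 12)
  tis <- array(0L, d)
  tis[3:10, 3:10, 3:6] <- 3L   # cerebellar WM tissue
  tis[3:10, 3:10, 7:10] <- 2L  # cerebellar GM tissue
  labs <- array(0L, d)
  labs[4:9, 4:9, 3:6] <- 8L    # GM label on WM tissue -> becomes 7
  labs[4:9, 4:9, 7:10] <- 7L   # WM label on GM tissue -> becomes 8
  out <- clean_warped_parcellation(label_volume(labs, spacing = 1),
                                   tissue_map(tis, spacing = 1),
                                   fusion_table())
  expect_true(all(out$values[4:9, 4:9, 3:6] == 7L))
  expect_true(all(out$values[4:9, 4:9, 7:10] == 8L))
})

test_that("cerebellar growing follows the strict 7x7x7 count rule", {
  d <- c(15, 15, 15)
  tis <- array(0L, d)
  tis[2:14, 2:14, 2:14] <- 2L  # GM everywhere inside
  labs <- array(0L, d)
  # a 2x3 block of cerebellar WM on WM tissue
  tis[4:5, 4:6, 4] <- 3L
  labs[4:5, 4:6, 4] <- 7L
  # voxel with exactly 6 cerebellar WM voxels within its 7x7x7 box -> cb GM
  # voxel with exactly 5 -> untouched
  out <- clean_warped_parcellation(label_volume(labs, spacing = 1),
                                   tissue_map(tis, spacing = 1),
                                   fusion_table())
  counts <- exvivomorph:::box_count(out$values == 7L, 3L)
  gm_unlabeled_before <- tis == 2L & labs == 0L
  expect_true(all(out$values[gm_unlabeled_before & counts > 5] == 8L))
  expect_true(all(out$values[gm_unlabeled_before & counts <= 5] == 0L))
  expect_gt(sum(out$values == 8L), 0)
})

test_that("cerebellar WM region growing reaches connected white matter", {
  d <- c(15, 15, 15)
  tis <- array(0L, d)
  tis[3:12, 7, 7] <- 3L  # a thin WM branch
  labs <- array(0L, d)
  labs[3, 7, 7] <- 7L    # seeded at one end
  out <- clean_warped_parcellation(label_volume(labs, spacing = 1),
                                   tissue_map(tis, spacing = 1),
                                   fusion_table())
  expect_true(all(out$values[3:12, 7, 7] == 7L))
})

test_that("fusion of identical tissue-consistent parcellations is a fixed point", {
  ph <- tiny_phantom(1)
  truth <- ph$truth_parcellation
  tis <- ph$truth_tissue
  for (n in c(1L, 3L)) {
    fused <- fuse_parcellations(rep(list(truth), n), tis, ph$label_table)
    expect_identical(fused$values, truth$values)
  }
})

test_that("white-matter voting is a plain majority with min-id tie-break", {
  d <- c(18, 18, 18)
  tis <- array(0L, d)
  tis[2:17, 2:17, 2:17] <- 3L
  mk <- function(l) {
    a <- array(0L, d)
    a[2:17, 2:17, 2:17] <- l
    label_volume(a, spacing = 1)
  }
  tbl <- label_table(c(2L, 10L, 16L), c("wm_a", "thal", "wm_b"),
                     c("WM", "GM", "WM"))
  tissue <- tissue_map(tis, spacing = 1)
  votes <- c(rep(list(mk(2L)), 11), rep(list(mk(16L)), 9))
  fused <- fuse_parcellations(votes, tissue, tbl)
  expect_true(all(fused$values[tis == 3L] == 2L))
  # 10 vs 10: tie broken to the smallest label id
  votes2 <- c(rep(list(mk(16L)), 10), rep(list(mk(2L)), 10))
  fused2 <- fuse_parcellations(votes2, tissue, tbl)
  expect_true(all(fused2$values[tis == 3L] == 2L))
  expect_error(fuse_parcellations(list(), tissue, tbl), "at least one")
})

test_that("the cerebellar override uses a strict quarter fraction", {
  d <- c(12, 12, 12)
  tis <- array(0L, d)
  tis[2:11, 2:11, 2:11] <- 2L
  tissue <- tissue_map(tis, spacing = 1)
  mk <- function(l) {
    a <- array(0L, d)
    a[tis == 2L] <- l
    label_volume(a, spacing = 1)
  }
  tbl <- fusion_table()
  # 6 of 20 parcellations say cerebellar GM (6 > 5 = 20/4) -> override
  set1 <- c(rep(list(mk(8L)), 6), rep(list(mk(1002L)), 14))
  fused1 <- fuse_parcellations(set1, tissue, tbl)
  expect_true(all(fused1$values[tis == 2L] == 8L))
  # 5 of 20 (not > 20/4) -> no override, cortical majority wins
  set2 <- c(rep(list(mk(8L)), 5), rep(list(mk(1002L)), 15))
  fused2 <- fuse_parcellations(set2, tissue, tbl)
  expect_true(all(fused2$values[tis == 2L] == 1002L))
})

test_that("fused output is tissue-consistent and beats individual atlases", {
  ph <- tiny_phantom(1)
  atlases <- make_atlas_set(ph, 20, deformation_amplitude = 1, seed = 7)
  tis <- ph$truth_tissue
  tbl <- ph$label_table
  cleaned <- lapply(atlases, function(a) {
    clean_warped_parcellation(a$labels, tis, tbl)
  })
  fused <- fuse_parcellations(cleaned, tis, tbl)
  wm_ids <- labels_of(tbl, tissue = "WM")
  gm_ids <- labels_of(tbl, tissue = "GM")
  expect_true(all(tis$values[fused$values %in% wm_ids] == 3L))
  expect_true(all(tis$values[fused$values %in% gm_ids] == 2L))
  expect_true(all(fused$values[tis$values == 0L] == 0L))

  dice_of <- function(vals) {
    labs <- setdiff(unique(as.vector(ph$truth_parcellation$values)), 0L)
    mean(vapply(labs, function(l) {
      pa <- vals == l
      pt <- ph$truth_parcellation$values == l
      2 * sum(pa & pt) / (sum(pa) + sum(pt))
    }, numeric(1)))
  }
  fused_dice <- dice_of(fused$values)
  atlas_dice <- mean(vapply(atlases, function(a) dice_of(a$labels$values),
                            numeric(1)))
  expect_gt(fused_dice, atlas_dice)
})

test_that("the L1 Voronoi tessellation matches the brute-force oracle", {
  set.seed(41)
  tbl <- fusion_table()
  for (i in 1:20) {
    d <- c(12, 12, 12)
    labs <- array(0L, d)
    n_gm <- sample(3:8, 1)
    gm_pos <- sample(prod(d), n_gm)
    labs[gm_pos] <- sample(c(10L, 1002L, 1003L), n_gm, replace = TRUE)
    wm_pos <- sample(setdiff(seq_len(prod(d)), gm_pos), 200)
    labs[wm_pos] <- 2L
    lv <- label_volume(labs, spacing = 1)
    vor <- voronoi_tessellate_wm(lv, tbl)
    oracle <- brute_force_voronoi(labs, c(10L, 1002L, 1003L), 2L)
    got <- vor$parcellation$values
    expect_identical(got[labs == 2L] - 3000L, oracle[labs == 2L])
    # non-WM voxels untouched
    expect_identical(got[labs != 2L], labs[labs != 2L])
  }
})

test_that("voronoi handles the degenerate single-region case and errors", {
  d <- c(8, 8, 8)
  labs <- array(0L, d)
  labs[2, 2, 2] <- 10L
  labs[4:6, 4:6, 4:6] <- 2L
  vor <- voronoi_tessellate_wm(label_volume(labs, spacing = 1), fusion_table())
  expect_true(all(vor$parcellation$values[labs == 2L] == 3010L))
  partner <- vor$table$voronoi_partner[vor$table$label == 10L]
  expect_identical(partner, 3010L)
  labs2 <- array(0L, d)
  labs2[3, 3, 3] <- 2L
  expect_error(voronoi_tessellate_wm(label_volume(labs2, spacing = 1),
                                     fusion_table()),
               "grey-matter")
})
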