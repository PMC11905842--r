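test_that("phantom compartments have the formalin contrast of fixed tissue", {
  ph <- tiny_phantom(1)
  brain <- ph$truth_mask$values == 1L
  formalin <- !brain & ph$t2$values > 0.3  # fluid, not air
  expect_gt(mean(ph$t2$values[formalin]), mean(ph$t2$values[brain]))
  wm <- ph$truth_parcellation$values %in% c(2L, 7L)
  expect_lt(mean(ph$t1$values[formalin]), mean(ph$t1$values[wm]))
})

test_that("the cerebellum floats detached from the forebrain", {
  ph <- tiny_phantom(1)
  cc <- exvivomorph:::.cc_label(as.vector(ph$truth_mask$values == 1L),
                                ph$truth_mask$grid$dims, 26L)
  expect_identical(max(cc), 2L)
  # at least `gap` voxels of non-brain between the two components
  dim(cc) <- ph$truth_mask$grid$dims
  cereb <- ph$truth_parcellation$values %in% c(7L, 8L)
  fore <- ph$truth_mask$values == 1L & !cereb
  near <- exvivomorph:::box_count(fore, ph$spec$cerebellum_gap) > 0
  expect_false(any(near & cereb))
})

test_that("ground truth is internally consistent", {
  ph <- tiny_phantom(1)
  tis <- ph$truth_tissue$values
  parc <- ph$truth_parcellation$values
  expect_identical((tis > 0L) * 1L, unclass(ph$truth_mask$values) * 1L)
  wm_ids <- labels_of(ph$label_table, tissue = "WM")
  gm_ids <- labels_of(ph$label_table, tissue = "GM")
  expect_true(all(tis[parc %in% wm_ids] == 3L))
  expect_true(all(tis[parc %in% gm_ids] == 2L))
  expect_true(all(tis[ph$wmh_mask$values == 1L] == 3L))
  expect_true(all(parc[ph$wmh_mask$values == 1L] == 2L))
})

test_that("ellipsoid voxelisation matches the analytic volume within 5%", {
  r <- 11
  spec <- phantom_spec(dims = c(48, 48, 48), wmh_count = 0L,
                       forebrain_semi = c(r, r, r),
                       cerebellum_semi = c(5, 5, 5),
                       cerebellum_gap = 3L,
                       hemisphere_cut = FALSE, seed = 2)
  ph <- make_phantom(spec)
  fore <- sum(ph$truth_parcellation$values %in%
                c(2L, exvivomorph:::DEEP_NUCLEI$label,
                  exvivomorph:::CORTICAL_LABELS))
  expect_lt(abs(fore - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.05)
  cereb <- sum(ph$truth_parcellation$values %in% c(7L, 8L))
  expect_lt(abs(cereb - 4 / 3 * pi * 5^3) / (4 / 3 * pi * 5^3), 0.05)
})

test_that("phantoms are pure functions of the spec seed", {
  a <- make_phantom(phantom_spec(seed = 9))
  b <- make_phantom(phantom_spec(seed = 9))
  expect_identical(a$t1$values, b$t1$values)
  expect_identical(a$t2$values, b$t2$values)
  expect_identical(a$truth_parcellation$values, b$truth_parcellation$values)
  expect_identical(a$wmh_mask$values, b$wmh_mask$values)
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(t2_means = c(air = 0, formalin = 0.4, gm = 0.55,
                                         wm = 0.35, cgm = 0.55, cwm = 0.35,
                                         wmh = 0.55)),
               "formalin")
  expect_error(phantom_spec(artifact_scale = 5), ">= 10")
  expect_error(make_phantom(phantom_spec(cerebellum_gap = 30L)), "gap")
})

test_that("pseudo-atlases reproduce the truth at amplitude zero", {
  ph <- tiny_phantom(1)
  atl <- make_atlas_set(ph, 3, deformation_amplitude = 0, seed = 4)
  for (a in atl) {
    expect_identical(a$labels$values, ph$truth_parcellation$values)
  }
})

test_that("pseudo-atlas deformation degrades boundary labels but not to zero", {
  ph <- tiny_phantom(1)
  atl <- make_atlas_set(ph, 3, deformation_amplitude = 1, seed = 4)
  truth <- ph$truth_parcellation$values
  cortical_present <- intersect(exvivomorph:::CORTICAL_LABELS,
                                unique(as.vector(truth)))[1:3]
  for (a in atl) {
    for (l in cortical_present) {
      pa <- a$labels$values == l
      pt <- truth == l
      d <- 2 * sum(pa & pt) / (sum(pa) + sum(pt))
      expect_gt(d, 0)
      expect_lt(d, 1)
    }
  }
  again <- make_atlas_set(ph, 3, deformation_amplitude = 1, seed = 4)
  expect_identical(lapply(atl, function(a) a$labels$values),
                   lapply(again, function(a) a$labels$values))
})

test_that("cohorts are deterministic and recover coefficients exactly without noise", {
  vm <- default_volume_models()
  for (nm in names(vm)) vm[[nm]]$sd <- 0
  spec <- cohort_spec(n_donors = 50, volume_models = vm,
                      age_model = list(alpha = 62, beta = 4, gamma = -0.22, sd = 0),
                      seed = 11)
  co <- make_cohort(spec)
  co2 <- make_cohort(spec)
  expect_identical(co$donors, co2$donors)
  expect_identical(co$volumes, co2$volumes)
  d <- dplyr::left_join(dplyr::filter(co$volumes, region == "hippocampus"),
                        co$donors, by = "donor")
  d$sexF <- as.integer(d$sex == "F")
  fit <- stats::lm(volume ~ age_scan + sexF + invivo + AD + FTD + OD + VD + M,
                   data = d)
  m <- vm$hippocampus
  expect_equal(unname(coef(fit)[c("(Intercept)", "age_scan", "sexF", "invivo",
                                  "AD", "FTD")]),
               c(m$intercept, m$age, m$sex, m$invivo, m$eta[["AD"]],
                 m$eta[["FTD"]]),
               tolerance = 1e-8)
  # age follows the quadratic exactly at zero noise
  expect_equal(co$donors$age_death,
               62 + 4 * co$donors$sum_scores - 0.22 * co$donors$sum_scores^2,
               tolerance = 1e-10)
})
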