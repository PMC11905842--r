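# label-table-shaped metadata for the voxel-level fraction measurements
fractions_table <- function() {
  tibble::tibble(
    label = c(10L, 3010L, 2L, 1002L, 4002L),
    name = c("g", "wm_near_g", "wm", "cortex", "wm_near_cortex"),
    tissue_class = c("GM", "WM", "WM", "GM", "WM"),
    voronoi_partner = c(3010L, NA, NA, 4002L, NA)
  )
}

swap_fixture <- function() {
  tibble::tibble(
    region = c(10L, 3010L, 2L, 1002L, 4002L),
    name = c("g", "wm_near_g", "wm", "cortex", "wm_near_cortex"),
    tissue_class = c("GM", "WM", "WM", "GM", "WM"),
    volume_mm3 = c(100, 50, 400, 80, 60),
    wmh_mm3 = c(10, 5, 20, 0, 3),
    fraction = c(0.1, 0.1, 0.05, 0, 0.05),
    voronoi_partner = c(3010L, NA, NA, 4002L, NA)
  )
}

test_that("regional fractions follow count-times-voxel-volume arithmetic", {
  d <- c(12, 12, 12)
  labs <- array(0L, d)
  labs[1:6, , 1] <- 10L        # 72 voxels
  labs[7:12, , 1] <- 3010L
  wmh <- array(0L, d)
  wmh[1:3, , 1] <- 1L          # covers half of region 10
  grid <- vox_grid(d, 0.5)
  rt <- regional_wmh_fractions(binary_mask(wmh, grid),
                               label_volume(labs, grid), fractions_table())
  r10 <- rt[rt$region == 10L, ]
  expect_equal(r10$volume_mm3, 72 * 0.125)
  expect_equal(r10$fraction, 0.5)
  expect_equal(rt$wmh_mm3[rt$region == 3010L], 0)

  # a 100-voxel blob at 0.5 mm spacing measures 12.5 mm^3
  labs[7:12, , 1:3] <- 3010L
  wmh2 <- array(0L, d)
  wmh2[which(labs == 3010L)[1:100]] <- 1L
  rt2 <- regional_wmh_fractions(binary_mask(wmh2, grid),
                                label_volume(labs, grid), fractions_table())
  expect_equal(rt2$wmh_mm3[rt2$region == 3010L], 12.5)

  empty <- regional_wmh_fractions(binary_mask(array(0L, d), grid),
                                  label_volume(labs, grid), fractions_table())
  expect_true(all(empty$fraction == 0))
})

test_that("the corrective swap moves GM hyperintensity volume to the partner", {
  out <- corrective_swap(swap_fixture())
  expect_equal(out$volume_mm3[out$region == 10L], 90)
  expect_equal(out$wmh_mm3[out$region == 10L], 0)
  expect_equal(out$volume_mm3[out$region == 3010L], 60)
  expect_equal(out$wmh_mm3[out$region == 3010L], 15)
  # untouched rows
  expect_equal(out$volume_mm3[out$region == 2L], 400)
  expect_equal(out$volume_mm3[out$region == 1002L], 80)
  delta <- attr(out, "delta")
  expect_equal(sum(delta$delta_mm3), 0)
})

test_that("swap conserves totals and is idempotent on random tables", {
  set.seed(51)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    gm <- sample(c(TRUE, FALSE), n, replace = TRUE)
    gm[1] <- TRUE
    tbl <- tibble::tibble(
      region = seq_len(n),
      name = sprintf("r%d", seq_len(n)),
      tissue_class = ifelse(gm, "GM", "WM"),
      volume_mm3 = runif(n, 50, 500),
      wmh_mm3 = NA_real_,
      fraction = 0,
      voronoi_partner = NA_integer_
    )
    tbl$wmh_mm3 <- runif(n) * tbl$volume_mm3 * 0.3
    wm_idx <- which(!gm)
    tbl$voronoi_partner[gm] <- if (length(wm_idx) > 0) {
      tbl$region[wm_idx][sample.int(length(wm_idx), sum(gm), replace = TRUE)]
    } else {
      NA_integer_
    }
    suppress <- function(x) suppressWarnings(x)
    once <- suppress(corrective_swap(tbl))
    expect_equal(sum(once$volume_mm3), sum(tbl$volume_mm3), tolerance = 1e-9)
    expect_equal(sum(once$wmh_mm3), sum(tbl$wmh_mm3), tolerance = 1e-9)
    twice <- suppress(corrective_swap(once))
    expect_equal(twice$volume_mm3, once$volume_mm3, tolerance = 1e-12)
    expect_true(all(once$volume_mm3 >= -1e-9))
  }
})

test_that("zero hyperintensities make the swap an identity", {
  tbl <- swap_fixture()
  tbl$wmh_mm3 <- 0
  out <- corrective_swap(tbl)
  expect_equal(out$volume_mm3, tbl$volume_mm3)
})

test_that("a GM region without partner is flagged and left unchanged", {
  tbl <- swap_fixture()
  tbl$voronoi_partner[tbl$region == 10L] <- NA_integer_
  expect_warning(out <- corrective_swap(tbl), "no Voronoi partner")
  expect_equal(out$volume_mm3[out$region == 10L], 100)
})

test_that("the imputed swap averages same-sex reference amounts", {
  ref <- function(w, sex) {
    t <- swap_fixture()
    t$wmh_mm3[t$region == 10L] <- w
    list(table = t, sex = sex)
  }
  target <- list(table = swap_fixture(), sex = "F")
  target$table$wmh_mm3 <- 0
  out <- imputed_swap(list(ref(4, "F"), ref(8, "F"), ref(100, "M")), target)
  expect_equal(out$volume_mm3[out$region == 10L], 94)  # mean(4, 8) = 6 moved
  expect_equal(out$volume_mm3[out$region == 3010L], 56)

  same <- imputed_swap(list(ref(10, "F")), target)
  expect_equal(same$volume_mm3[same$region == 10L], 90)

  zero_refs <- list(ref(0, "F"))
  z <- imputed_swap(zero_refs, target)
  expect_equal(z$volume_mm3, target$table$volume_mm3)
  expect_error(imputed_swap(list(ref(1, "M")), target), "no reference")
})

test_that("imputed amounts are clipped at the available volume", {
  big <- list(table = swap_fixture(), sex = "F")
  big$table$wmh_mm3[big$table$region == 10L] <- 500
  target <- list(table = swap_fixture(), sex = "F")
  expect_warning(out <- imputed_swap(list(big), target), "clipped")
  expect_equal(out$volume_mm3[out$region == 10L], 0)
  expect_equal(sum(out$volume_mm3), sum(target$table$volume_mm3),
               tolerance = 1e-9)
})

test_that("postmortem deltas replicate onto in vivo tables conservatively", {
  pm <- corrective_swap(swap_fixture())
  delta <- attr(pm, "delta")
  iv <- swap_fixture()
  iv$volume_mm3 <- iv$volume_mm3 * 1.2
  out <- replicate_to_invivo(delta, iv)
  expect_equal(sum(out$volume_mm3), sum(iv$volume_mm3), tolerance = 1e-9)
  expect_equal(out$volume_mm3[out$region == 10L],
               iv$volume_mm3[iv$region == 10L] - 10)
  zero <- replicate_to_invivo(tibble::tibble(region = iv$region,
                                             delta_mm3 = 0), iv)
  expect_equal(zero$volume_mm3, iv$volume_mm3)
  bad <- tibble::tibble(region = 999L, delta_mm3 = 5)
  expect_warning(replicate_to_invivo(bad, iv), "absent")
})

test_that("hyperintensity cohort tests run the declared battery", {
  set.seed(52)
  donors <- expand.grid(donor = sprintf("D%02d", 1:20), region = c(3010L, 4002L))
  donors$sex <- rep(c("F", "M"), each = 10)
  donors$age <- runif(40, 60, 95)
  donors$wmh_mm3 <- runif(40, 0, 500) + (donors$sex == "M") * 300
  res <- wmh_cohort_tests(donors, n_tests = 46)
  expect_identical(nrow(res$sex_tests), 2L)
  expect_true(all(res$sex_tests$p_bonferroni >= res$sex_tests$p_value))
  expect_true(all(res$age_correlations$rho >= -1 & res$age_correlations$rho <= 1))
})
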