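#' Regional white-matter-hyperintensity fractions
#'
#' Measures, for every region of a parcellation, the region volume, the
#' volume of white-matter hyperintensities inside it, and their ratio.
#'
#' @param wmh_mask a [binary_mask()] of hyperintense voxels.
#' @param parcellation a `label_volume` (typically after the Voronoi
#'   tessellation).
#' @param table the extended [label_table()] carrying `voronoi_partner`.
#' @return A `region_table` tibble: region, name, tissue_class, volume_mm3,
#'   wmh_mm3, fraction, voronoi_partner.
#' @export
regional_wmh_fractions <- function(wmh_mask, parcellation, table) {
  stop_if_grid_mismatch(wmh_mask, parcellation, "mask and parcellation")
  labs <- as.vector(parcellation$values)
  if (!any(labs > 0L)) abort("`parcellation` is empty")
  vv <- voxel_volume(parcellation$grid)
  ids <- sort(unique(labs[labs > 0L]))
  count_all <- tabulate(labs, nbins = max(ids))[ids]
  inwmh <- labs[wmh_mask$values > 0L]
  count_wmh <- tabulate(inwmh, nbins = max(ids))[ids]
  tbl <- tibble(
    region = ids,
    name = table$name[match(ids, table$label)],
    tissue_class = table$tissue_class[match(ids, table$label)],
    volume_mm3 = count_all * vv,
    wmh_mm3 = count_wmh * vv,
    fraction = count_wmh / count_all,
    voronoi_partner = if ("voronoi_partner" %in% names(table)) {
      table$voronoi_partner[match(ids, table$label)]
    } else {
      NA_integer_
    }
  )
  class(tbl) <- unique(c("region_table", class(tbl)))
  tbl
}

#' Corrective hyperintensity volume swap
#'
#' Hyperintense white matter resembles grey matter in T2-weighted scans, so
#' tissue-driven parcellations misassign it to adjacent grey-matter regions.
#' The corrective swap moves, for each grey-matter region `g` with
#' hyperintensity volume `w`, that volume (and its hyperintensity
#' bookkeeping) from `g` to the nearest white-matter Voronoi sub-region
#' `V(g)`: `volume[g] -= w`, `volume[V(g)] += w`, `wmh[g] = 0`,
#' `wmh[V(g)] += w`. White-matter regions and grey-matter regions without
#' hyperintensities are untouched; total volume and total hyperintensity
#' volume are conserved, and the swap is idempotent.
#'
#' @param table a `region_table` (see [regional_wmh_fractions()]).
#' @return The swapped `region_table`; attribute `"delta"` holds the
#'   per-region volume changes (used to replicate the correction on in vivo
#'   tables).
#' @export
corrective_swap <- function(table) {
  out <- table
  delta <- setNames(numeric(nrow(out)), out$region)
  gm <- which(out$tissue_class == "GM" & out$wmh_mm3 > 0)
  for (i in gm) {
    partner <- out$voronoi_partner[i]
    if (is.na(partner) || !partner %in% out$region) {
      warn(sprintf("grey-matter region %d has hyperintensities but no Voronoi partner; left unchanged",
                   out$region[i]))
      next
    }
    j <- match(partner, out$region)
    w <- out$wmh_mm3[i]
    out$volume_mm3[i] <- out$volume_mm3[i] - w
    out$volume_mm3[j] <- out$volume_mm3[j] + w
    out$wmh_mm3[i] <- 0
    out$wmh_mm3[j] <- out$wmh_mm3[j] + w
    delta[i] <- delta[i] - w
    delta[as.character(partner)] <- delta[as.character(partner)] + w
  }
  out$fraction <- ifelse(out$volume_mm3 > 0, out$wmh_mm3 / out$volume_mm3, 0)
  attr(out, "delta") <- tibble(region = out$region, delta_mm3 = unname(delta))
  out
}

#' Sex-averaged imputed swap for donors without hyperintensity masks
#'
#' For a donor without a delineated hyperintensity mask, the volume moved
#' from each grey-matter region to its Voronoi partner is the mean of the
#' volumes swapped by [corrective_swap()] for the reference donors of the
#' same sex. Amounts are clipped at the target region's available volume
#' (clipping is reported with a warning).
#'
#' @param references list of `list(table = region_table, sex = "F"/"M")`,
#'   tables as measured (pre-swap) for donors with masks.
#' @param target `list(table = region_table, sex = ...)` for the donor
#'   without a mask.
#' @return The adjusted `region_table` with a `"delta"` attribute.
#' @export
imputed_swap <- function(references, target) {
  same <- Filter(function(r) r$sex == target$sex, references)
  if (length(same) == 0) abort("no reference donors of the target's sex")
  out <- target$table
  gm <- which(out$tissue_class == "GM" & !is.na(out$voronoi_partner))
  delta <- setNames(numeric(nrow(out)), out$region)
  for (i in gm) {
    region <- out$region[i]
    amounts <- vapply(same, function(r) {
      k <- match(region, r$table$region)
      if (is.na(k) || r$table$tissue_class[k] != "GM") return(NA_real_)
      r$table$wmh_mm3[k]
    }, numeric(1))
    a <- mean(amounts, na.rm = TRUE)
    if (!is.finite(a) || a <= 0) next
    if (a > out$volume_mm3[i]) {
      warn(sprintf("imputed swap for region %d clipped at the available volume", region))
      a <- out$volume_mm3[i]
    }
    j <- match(out$voronoi_partner[i], out$region)
    if (is.na(j)) next
    out$volume_mm3[i] <- out$volume_mm3[i] - a
    out$volume_mm3[j] <- out$volume_mm3[j] + a
    delta[i] <- delta[i] - a
    delta[j] <- delta[j] + a
  }
  out$fraction <- ifelse(out$volume_mm3 > 0, out$wmh_mm3 / out$volume_mm3, 0)
  attr(out, "delta") <- tibble(region = out$region, delta_mm3 = unname(delta))
  out
}

#' Replicate postmortem volume corrections on an in vivo table
#'
#' Applies the same additive per-region volume changes performed on a
#' donor's postmortem regions to the donor's in vivo region table.
#'
#' @param delta tibble with columns `region` and `delta_mm3` (the `"delta"`
#'   attribute of a swap).
#' @param invivo_table the donor's in vivo `region_table`.
#' @return The shifted `region_table`.
#' @export
replicate_to_invivo <- function(delta, invivo_table) {
  out <- invivo_table
  idx <- match(delta$region, out$region)
  missing <- delta$region[is.na(idx) & delta$delta_mm3 != 0]
  if (length(missing) > 0) {
    warn(sprintf("regions absent from the in vivo table: %s",
                 paste(missing, collapse = ", ")))
  }
  ok <- !is.na(idx)
  out$volume_mm3[idx[ok]] <- out$volume_mm3[idx[ok]] + delta$delta_mm3[ok]
  out$fraction <- ifelse(out$volume_mm3 > 0, out$wmh_mm3 / out$volume_mm3, 0)
  out
}

#' Hyperintensity cohort tests
#'
#' Thin wrappers over the standard tests used to screen the hyperintensity
#' burden: a Wilcoxon rank-sum test of men versus women per white-matter
#' Voronoi region with Bonferroni correction over the declared family size,
#' and Spearman rank correlations of hyperintensity volume with age at
#' death.
#'
#' @param wmh_long tibble with columns donor, region, wmh_mm3, sex, age.
#' @param n_tests Bonferroni family size; defaults to the number of regions.
#' @return A list with `sex_tests` and `age_correlations` tibbles.
#' @export
wmh_cohort_tests <- function(wmh_long, n_tests = NULL) {
  regions <- sort(unique(wmh_long$region))
  n_tests <- n_tests %||% length(regions)
  sex_tests <- purrr::map_dfr(regions, function(r) {
    d <- wmh_long[wmh_long$region == r, ]
    p <- tryCatch(
      wilcox.test(wmh_mm3 ~ sex, data = d, exact = FALSE)$p.value,
      error = function(e) NA_real_)
    tibble(region = r, p_value = p,
           p_bonferroni = pmin(1, p * n_tests))
  })
  age_cor <- purrr::map_dfr(regions, function(r) {
    d <- wmh_long[wmh_long$region == r, ]
    ct <- tryCatch(cor.test(d$wmh_mm3, d$age, method = "spearman",
                            exact = FALSE),
                   error = function(e) NULL)
    tibble(region = r,
           rho = if (is.null(ct)) NA_real_ else unname(ct$estimate),
           p_value = if (is.null(ct)) NA_real_ else ct$p.value,
           p_bonferroni = if (is.null(ct)) NA_real_ else pmin(1, ct$p.value * n_tests))
  })
  list(sex_tests = sex_tests, age_correlations = age_cor)
}
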