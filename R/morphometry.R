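DEEP_GM_LABELS <- c(10L, 11L, 12L, 13L, 17L, 18L, 26L)
HIPPOCAMPUS_LABEL <- 17L
CEREBELLUM_LABELS <- c(7L, 8L)

#' Aggregate regional volumes
#'
#' Converts a parcellation into per-label volumes (voxel count times voxel
#' volume) and the five aggregates used by the morphometry models: total
#' brain (all labeled voxels), cerebrum white matter, deep grey matter (sum
#' of thalamus, caudate, putamen, pallidum, hippocampus, amygdala and
#' accumbens, protocol labels 10, 11, 12, 13, 17, 18, 26), hippocampus
#' (label 17) and cerebellum (labels 7 and 8). An aggregate whose required
#' labels are absent is reported as `NA`, never as zero.
#'
#' @param parcellation a `label_volume`.
#' @param table the [label_table()].
#' @return A list with `regions` (tibble: region, name, volume_mm3) and
#'   `aggregates` (named numeric: brain, cerebrum_wm, deep_gm, hippocampus,
#'   cerebellum).
#' @export
aggregate_volumes <- function(parcellation, table) {
  labs <- as.vector(parcellation$values)
  vv <- voxel_volume(parcellation$grid)
  ids <- sort(unique(labs[labs > 0L]))
  counts <- tabulate(labs, nbins = max(c(ids, 1L)))[ids]
  regions <- tibble(region = ids,
                    name = table$name[match(ids, table$label)],
                    volume_mm3 = counts * vv)
  vol_of <- function(wanted) {
    if (!all(wanted %in% ids)) return(NA_real_)
    sum(regions$volume_mm3[regions$region %in% wanted])
  }
  wm_ids <- intersect(labels_of(table, tissue = "WM", cerebellum = FALSE), ids)
  aggregates <- c(
    brain = sum(regions$volume_mm3),
    cerebrum_wm = if (length(wm_ids) > 0) {
      sum(regions$volume_mm3[regions$region %in% wm_ids])
    } else {
      NA_real_
    },
    deep_gm = vol_of(DEEP_GM_LABELS),
    hippocampus = vol_of(HIPPOCAMPUS_LABEL),
    cerebellum = vol_of(CEREBELLUM_LABELS)
  )
  list(regions = regions, aggregates = aggregates)
}

#' Average the aggregates of repeated scans
#'
#' When a donor was scanned twice in one session the final regional values
#' are the arithmetic mean of the per-scan aggregates.
#'
#' @param ... named aggregate vectors as returned by [aggregate_volumes()].
#' @return The element-wise mean vector.
#' @export
average_aggregates <- function(...) {
  mats <- do.call(rbind, list(...))
  colMeans(mats)
}

#' Robust linear morphometry fit
#'
#' Fits `response ~ predictors` by iteratively reweighted least squares
#' under Huber's loss (tuning constant 1.345, the standard 95%-efficiency
#' choice), as used for all the volume and age models:
#' `vol = a + b age + c sex + d invivo + eta . diagnosis`,
#' `age = a + b sex + c volume`, and the quadratic neuropathology models.
#' Standard errors come from the robust fit; p-values are two-sided
#' asymptotic normal.
#'
#' @param data data frame of observations.
#' @param formula model formula.
#' @param k Huber tuning constant.
#' @param maxit IRLS iteration cap.
#' @return An object of class `robust_fit`; see [tidy.robust_fit()].
#' @export
fit_robust_linear <- function(data, formula, k = 1.345, maxit = 100) {
  mf <- stats::model.frame(formula, data)
  if (nrow(mf) <= ncol(stats::model.matrix(formula, mf))) {
    abort("not enough observations for the number of predictors")
  }
  if (qr(stats::model.matrix(formula, mf))$rank < ncol(stats::model.matrix(formula, mf))) {
    abort("singular design matrix")
  }
  fit <- MASS::rlm(formula, data = data, psi = MASS::psi.huber, k = k,
                   maxit = maxit)
  s <- summary(fit)
  co <- s$coefficients
  structure(list(fit = fit, formula = formula, n = nrow(mf),
                 coefficients = tibble(
                   term = rownames(co),
                   estimate = unname(co[, "Value"]),
                   std_error = unname(co[, "Std. Error"]),
                   statistic = unname(co[, "t value"]),
                   p_value = unname(2 * pnorm(-abs(co[, "t value"]))))),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("<robust_fit> %s, n = %d (Huber IRLS)\n",
              deparse(x$formula), x$n))
  print(x$coefficients)
  invisible(x)
}

#' Quadratic age-versus-neuropathology model with error band
#'
#' Two-step robust quadratic trend of the age at death against the sum of
#' neuropathology scores `s`: first `age = a + b s + c s^2` is fitted
#' robustly; then the absolute prediction error `|age - predicted|` is
#' fitted by the same quadratic form; the predicted error, floored at zero,
#' is added to and subtracted from the age prediction to draw a spread band.
#'
#' @param records data frame with columns `age` and `s` (>= 4 rows).
#' @param k Huber tuning constant.
#' @return An object of class `age_score_fit` with the two coefficient sets
#'   and a `predict_band(s)` evaluation grid; see [autoplot.age_score_fit()].
#' @export
fit_age_score_band <- function(records, k = 1.345) {
  if (nrow(records) < 4) abort("at least 4 donors are needed")
  if (length(unique(records$s)) < 3) abort("scores are degenerate (all equal)")
  records$s2 <- records$s^2
  step1 <- fit_robust_linear(records, age ~ s + s2, k = k)
  records$abs_err <- abs(records$age - predict(step1$fit, records))
  step2 <- fit_robust_linear(records, abs_err ~ s + s2, k = k)
  cf1 <- step1$coefficients$estimate
  cf2 <- step2$coefficients$estimate
  neg_err <- 0L
  band_fun <- function(s) {
    pred <- cf1[1] + cf1[2] * s + cf1[3] * s^2
    err <- cf2[1] + cf2[2] * s + cf2[3] * s^2
    err_floored <- pmax(err, 0)
    tibble(s = s, predicted = pred,
           lower = pred - err_floored, upper = pred + err_floored)
  }
  grid <- band_fun(seq(min(records$s), max(records$s), length.out = 101))
  neg_err <- sum(cf2[1] + cf2[2] * grid$s + cf2[3] * grid$s^2 < 0)
  structure(list(age_fit = step1, error_fit = step2,
                 alpha = cf1[1], beta = cf1[2], gamma = cf1[3],
                 delta = cf2[1], eta = cf2[2], lambda = cf2[3],
                 band = grid, band_fun = band_fun, n = step1$n,
                 negative_error_points = neg_err),
            class = "age_score_fit")
}

#' @export
print.age_score_fit <- function(x, ...) {
  cat(sprintf("<age_score_fit> age = %.2f %+.3f s %+.4f s^2 (n = %d)\n",
              x$alpha, x$beta, x$gamma, x$n))
  cat(sprintf("  |error| = %.2f %+.3f s %+.4f s^2; band floored at 0 on %d grid points\n",
              x$delta, x$eta, x$lambda, x$negative_error_points))
  invisible(x)
}

#' Cohort descriptive tests
#'
#' The standard descriptive battery: Welch two-sample t-tests of men versus
#' women for the continuous covariates, Fisher exact tests comparing a
#' subgroup's sex split against the whole cohort, and Spearman rank
#' correlations between score/volume pairs. Bonferroni thresholds use the
#' declared family size.
#'
#' @param donors tibble with at least `sex` plus the tested columns.
#' @param welch_vars columns compared between sexes.
#' @param subgroups named list of logical vectors marking subgroup
#'   membership for the Fisher tests.
#' @param spearman_pairs named list of character pairs to correlate.
#' @param n_tests Bonferroni family size (defaults to the number of tests).
#' @return A tibble with test, variable, statistic, estimate, p_value,
#'   p_bonferroni.
#' @export
cohort_tests <- function(donors, welch_vars = character(),
                         subgroups = list(), spearman_pairs = list(),
                         n_tests = NULL) {
  rows <- list()
  for (v in welch_vars) {
    men <- donors[[v]][donors$sex == "M"]
    women <- donors[[v]][donors$sex == "F"]
    if (length(men) < 2 || length(women) < 2) {
      warn(sprintf("degenerate groups for Welch test of %s", v))
      next
    }
    tt <- t.test(men, women)
    rows[[length(rows) + 1]] <- tibble(test = "welch", variable = v,
                                       statistic = unname(tt$statistic),
                                       estimate = unname(diff(rev(tt$estimate))),
                                       p_value = tt$p.value)
  }
  for (nm in names(subgroups)) {
    sel <- subgroups[[nm]]
    tab <- rbind(table(factor(donors$sex[sel], levels = c("F", "M"))),
                 table(factor(donors$sex, levels = c("F", "M"))))
    ft <- fisher.test(tab)
    rows[[length(rows) + 1]] <- tibble(test = "fisher", variable = nm,
                                       statistic = NA_real_,
                                       estimate = unname(ft$estimate),
                                       p_value = ft$p.value)
  }
  for (nm in names(spearman_pairs)) {
    pr <- spearman_pairs[[nm]]
    ct <- cor.test(donors[[pr[1]]], donors[[pr[2]]], method = "spearman",
                   exact = FALSE)
    rows[[length(rows) + 1]] <- tibble(test = "spearman", variable = nm,
                                       statistic = NA_real_,
                                       estimate = unname(ct$estimate),
                                       p_value = ct$p.value)
  }
  out <- dplyr::bind_rows(rows)
  m <- n_tests %||% nrow(out)
  out$p_bonferroni <- pmin(1, out$p_value * m)
  out
}
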