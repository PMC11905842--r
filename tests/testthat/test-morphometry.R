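test_that("volume aggregation sums the declared label sets", {
  d <- c(10, 10, 10)
  labs <- array(0L, d)
  labs[1, 1, 1] <- 7L
  labs[2, 1, 1] <- 8L
  labs[3:4, 1, 1] <- 2L
  labs[cbind(3:9, 2, 1)] <- exvivomorph:::DEEP_GM_LABELS
  grid <- vox_grid(d, 0.5)
  ph <- tiny_phantom(1)
  agg <- aggregate_volumes(label_volume(labs, grid), ph$label_table)
  expect_equal(unname(agg$aggregates["cerebellum"]), 2 * 0.125)
  expect_equal(unname(agg$aggregates["deep_gm"]), 7 * 0.125)
  expect_equal(unname(agg$aggregates["hippocampus"]), 0.125)
  expect_equal(unname(agg$aggregates["cerebrum_wm"]), 2 * 0.125)
  expect_equal(unname(agg$aggregates["brain"]), 11 * 0.125)
  # deep GM aggregate is exactly the sum of its member labels
  members <- agg$regions$volume_mm3[agg$regions$region %in%
                                      exvivomorph:::DEEP_GM_LABELS]
  expect_identical(unname(agg$aggregates["deep_gm"]), sum(members))
})

test_that("missing required labels yield NA aggregates, not zero", {
  d <- c(6, 6, 6)
  labs <- array(0L, d)
  labs[1:2, 1, 1] <- 2L
  labs[3, 1, 1] <- 10L  # only one of the seven deep labels
  agg <- aggregate_volumes(label_volume(labs, vox_grid(d, 0.5)),
                           tiny_phantom(1)$label_table)
  expect_true(is.na(agg$aggregates["hippocampus"]))
  expect_true(is.na(agg$aggregates["deep_gm"]))
  expect_true(is.na(agg$aggregates["cerebellum"]))
  expect_false(is.na(agg$aggregates["brain"]))
})

test_that("two-scan donors average their aggregates", {
  a <- c(brain = 1000, deep_gm = 100)
  b <- c(brain = 2000, deep_gm = 200)
  expect_equal(average_aggregates(a, b), c(brain = 1500, deep_gm = 150))
})

test_that("robust fits recover noiseless linear models to high precision", {
  set.seed(61)
  n <- 60
  d <- tibble::tibble(age = runif(n, 60, 95),
                      sexF = rbinom(n, 1, 0.5),
                      invivo = rbinom(n, 1, 0.3))
  d$volume <- 5e5 - 1e3 * d$age - 7e4 * d$sexF + 6e4 * d$invivo
  fit <- suppressWarnings(fit_robust_linear(d, volume ~ age + sexF + invivo))
  est <- tidy(fit)$estimate
  expect_equal(est, c(5e5, -1e3, -7e4, 6e4), tolerance = 1e-8)
  expect_true(all(tidy(fit)$p_value >= 0 & tidy(fit)$p_value <= 1))
  expect_error(fit_robust_linear(d[1:3, ], volume ~ age + sexF + invivo),
               "observations")
  d$dup <- d$age
  expect_error(fit_robust_linear(d, volume ~ age + dup), "singular")
})

test_that("Huber fits beat least squares under gross outliers", {
  set.seed(62)
  wins <- 0L
  for (rep in 1:100) {
    n <- 80
    x <- runif(n, -2, 2)
    y <- 1 + 2 * x + rnorm(n, sd = 0.5)
    out_idx <- sample(n, 8)
    y[out_idx] <- y[out_idx] + sample(c(-1, 1), 8, TRUE) * runif(8, 10, 30)
    dd <- tibble::tibble(x = x, y = y)
    rob <- tidy(fit_robust_linear(dd, y ~ x))$estimate
    ols <- coef(stats::lm(y ~ x, dd))
    err_rob <- sum(abs(rob - c(1, 2)))
    err_ols <- sum(abs(ols - c(1, 2)))
    wins <- wins + (err_rob < err_ols)
  }
  expect_gt(wins, 80)
})

test_that("cohort-scale parameter recovery stays within 2 standard errors", {
  co <- make_cohort(cohort_spec(n_donors = 200, seed = 63))
  d <- dplyr::left_join(dplyr::filter(co$volumes, region == "brain"),
                        co$donors, by = "donor")
  d$sexF <- as.integer(d$sex == "F")
  fit <- tidy(fit_robust_linear(
    d, volume ~ age_scan + sexF + invivo + AD + FTD + OD + VD + M))
  truth <- c("(Intercept)" = 5.85e5, age_scan = 0, sexF = -7.52e4,
             invivo = 6.96e4, AD = 0, FTD = 0, OD = 0, VD = 0, M = 0)
  z <- abs(fit$estimate - truth[fit$term]) / fit$std_error
  expect_true(all(z[fit$term %in% c("sexF", "invivo")] < 2))
  expect_gt(mean(z < 2), 0.85)
})

test_that("the quadratic age-score band reproduces exact and noisy settings", {
  # exact quadratic: step-1 coefficients exact, error fit near zero
  s <- rep(0:14, 4)
  rec <- tibble::tibble(s = s, age = 60 + 3 * s - 0.15 * s^2)
  fit <- suppressWarnings(fit_age_score_band(rec))  # IRLS dithers at machine precision on exact data
  expect_equal(unname(c(fit$alpha, fit$beta, fit$gamma)), c(60, 3, -0.15),
               tolerance = 1e-6)
  expect_lt(max(abs(c(fit$delta, fit$eta, fit$lambda))), 1e-6)
  expect_true(all(fit$band$upper >= fit$band$lower))
  expect_true(all(fit$band$upper >= fit$band$predicted))

  # symmetric constant-SD noise: the error fit is near-constant in s
  set.seed(64)
  rec2 <- tibble::tibble(s = rep(0:14, 14))
  rec2$age <- 60 + 3 * rec2$s - 0.15 * rec2$s^2 + rnorm(nrow(rec2), sd = 4)
  fit2 <- fit_age_score_band(rec2)
  err <- fit2$delta + fit2$eta * (0:14) + fit2$lambda * (0:14)^2
  expect_lt(diff(range(err)), 3)
  expect_gt(min(err), 0)

  # inverted-U generator: fitted curvature is negative
  set.seed(65)
  rec3 <- tibble::tibble(s = sample(0:14, 200, replace = TRUE))
  rec3$age <- 62 + 4 * rec3$s - 0.22 * rec3$s^2 + rnorm(200, sd = 5)
  fit3 <- fit_age_score_band(rec3)
  expect_lt(fit3$gamma, 0)

  expect_error(fit_age_score_band(tibble::tibble(s = c(1, 1, 1, 1),
                                                 age = c(70, 71, 72, 73))),
               "degenerate")
})

test_that("descriptive tests return canonical degenerate values", {
  donors <- tibble::tibble(
    sex = rep(c("M", "F"), each = 4),
    height = rep(c(1.6, 1.7, 1.8, 1.9), 2),
    score = 1:8,
    rank = (1:8)^2
  )
  res <- cohort_tests(donors, welch_vars = "height",
                      subgroups = list(balanced = rep(c(TRUE, FALSE), 4)),
                      spearman_pairs = list(sr = c("score", "rank")))
  welch <- res[res$test == "welch", ]
  expect_equal(welch$statistic, 0)
  expect_equal(welch$p_value, 1)
  # a perfectly balanced subgroup: odds ratio 1, p = 1
  fisher <- res[res$test == "fisher", ]
  expect_equal(fisher$estimate, 1, tolerance = 1e-6)
  expect_equal(fisher$p_value, 1)
  # strictly increasing pair: rho = 1
  spear <- res[res$test == "spearman", ]
  expect_equal(spear$estimate, 1)
  expect_true(all(res$p_bonferroni >= res$p_value))
})

test_that("tidiers expose broom-style views and plots build", {
  set.seed(66)
  d <- tibble::tibble(x = rnorm(30), y = rnorm(30) + 2)
  fit <- fit_robust_linear(d, y ~ x)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std_error", "statistic", "p_value"))
  expect_identical(glance(fit)$n, 30L)

  rec <- tibble::tibble(s = rep(0:10, 5))
  rec$age <- 60 + 2 * rec$s - 0.1 * rec$s^2 + rnorm(length(rec$s), sd = 2)
  asf <- fit_age_score_band(rec)
  expect_identical(nrow(tidy(asf)), 6L)
  p <- autoplot(asf)
  expect_s3_class(p, "ggplot")
})
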