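#' Cohort simulation settings
#'
#' Generator for a synthetic brain-donor cohort. Regional volumes follow the
#' linear morphometry model
#' `vol = alpha + beta * age + gamma * sex(F) + delta * invivo + eta . D + noise`,
#' where `D` collects the diagnosis indicators (AD, FTD, OD, VD and M for a
#' missing diagnosis), and the age at death follows the quadratic
#' neuropathology relation `age = a + b * s + c * s^2 + noise` on the sum of
#' scores `s = thal + braak + cerad`. The default volume coefficients are the
#' significant coefficients reported for the study cohort's five aggregate
#' regions (unreported coefficients are zero); the default quadratic rises to
#' a plateau near s = 9 and bends down for extreme neuropathology burdens
#' (negative curvature), with residual scatter of a few years.
#'
#' @param n_donors number of donors (>= 2).
#' @param volume_models named list per region aggregate, each a list with
#'   `intercept`, `age`, `sex`, `invivo`, `eta` (length-5 vector for AD, FTD,
#'   OD, VD, M) and `sd` (residual SD, mm^3).
#' @param age_model list with `alpha`, `beta`, `gamma` (years; `gamma` < 0
#'   gives the inverted-U) and `sd`.
#' @param sex_ratio probability a donor is female.
#' @param prevalence named probabilities for M (missing diagnosis, exclusive)
#'   and the AD/FTD/OD/VD indicators (independent given not-missing).
#' @param p_invivo probability a donor also has an in vivo observation.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_donors = 100L,
                        volume_models = default_volume_models(),
                        age_model = list(alpha = 62, beta = 4, gamma = -0.22,
                                         sd = 6),
                        sex_ratio = 0.5,
                        prevalence = c(M = 0.16, AD = 0.45, FTD = 0.08,
                                       OD = 0.15, VD = 0.12),
                        p_invivo = 0.33, seed = 1L) {
  if (n_donors < 2) abort("`n_donors` must be >= 2")
  sds <- c(vapply(volume_models, function(m) m$sd, numeric(1)), age_model$sd)
  if (any(sds < 0)) abort("residual noise SDs must be >= 0")
  if (any(prevalence < 0 | prevalence > 1) || sex_ratio < 0 || sex_ratio > 1) {
    abort("prevalences and sex_ratio must lie in [0, 1]")
  }
  structure(list(n_donors = as.integer(n_donors),
                 volume_models = volume_models, age_model = age_model,
                 sex_ratio = sex_ratio, prevalence = prevalence,
                 p_invivo = p_invivo, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_volume_models <- function() {
  list(
    brain = list(intercept = 5.85e5, age = 0, sex = -7.52e4, invivo = 6.96e4,
                 eta = c(AD = 0, FTD = 0, OD = 0, VD = 0, M = 0), sd = 3e4),
    cerebrum_wm = list(intercept = 2.53e5, age = 0, sex = -4.16e4, invivo = 0,
                       eta = c(AD = 0, FTD = 0, OD = 0, VD = 0, M = 0), sd = 1.5e4),
    deep_gm = list(intercept = 2.66e4, age = -1.05e2, sex = -1.90e3,
                   invivo = -2.12e3,
                   eta = c(AD = 0, FTD = -3.02e3, OD = 0, VD = 0, M = 0), sd = 2e3),
    hippocampus = list(intercept = 4.87e3, age = -1.65e1, sex = -3.88e2,
                       invivo = 1.39e3,
                       eta = c(AD = -4.25e2, FTD = -1.10e3, OD = 0, VD = 0, M = 0),
                       sd = 5e2),
    cerebellum = list(intercept = 7.07e4, age = -1.91e2, sex = -7.65e3,
                      invivo = -3.67e3,
                      eta = c(AD = 0, FTD = 0, OD = 0, VD = 0, M = 0), sd = 7e3)
  )
}

#' Simulate a donor cohort
#'
#' Draws neuropathology scores, demographics, diagnoses and per-observation
#' regional volumes from a [cohort_spec()]. Each donor contributes a
#' postmortem observation and, with probability `p_invivo`, an in vivo
#' observation that inherits the postmortem diagnosis. Deterministic given
#' the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `donors` (one row per donor: donor, sex, age_death,
#'   thal, braak, cerad, sum_scores, AD, FTD, OD, VD, M, has_invivo) and
#'   `volumes` (long tibble: donor, invivo, age_scan, region, volume).
#' @export
make_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  n <- spec$n_donors
  thal <- sample(0:5, n, replace = TRUE)
  braak <- sample(0:6, n, replace = TRUE)
  cerad <- sample(0:3, n, replace = TRUE)
  s <- thal + braak + cerad
  am <- spec$age_model
  age <- am$alpha + am$beta * s + am$gamma * s^2 + rnorm(n, sd = am$sd)
  sex <- ifelse(runif(n) < spec$sex_ratio, "F", "M")
  M <- rbinom(n, 1, spec$prevalence["M"])
  draw <- function(p) rbinom(n, 1, p) * (1 - M)
  AD <- draw(spec$prevalence["AD"])
  FTD <- draw(spec$prevalence["FTD"])
  OD <- draw(spec$prevalence["OD"])
  VD <- draw(spec$prevalence["VD"])
  has_invivo <- rbinom(n, 1, spec$p_invivo) == 1
  donors <- tibble(donor = sprintf("D%03d", seq_len(n)), sex = sex,
                   age_death = age, thal = thal, braak = braak, cerad = cerad,
                   sum_scores = s, AD = AD, FTD = FTD, OD = OD, VD = VD, M = M,
                   has_invivo = has_invivo)
  sexF <- as.integer(sex == "F")
  if (length(unique(sex)) == 1 &&
      any(vapply(spec$volume_models, function(m) m$sex != 0, logical(1)))) {
    warn("all donors share one sex: the sex effect is not identifiable")
  }
  obs <- dplyr::bind_rows(
    tibble(idx = seq_len(n), invivo = 0L, age_scan = age),
    tibble(idx = which(has_invivo), invivo = 1L,
           age_scan = age[has_invivo] - runif(sum(has_invivo), 0, 3))
  )
  vols <- purrr::map_dfr(names(spec$volume_models), function(region) {
    m <- spec$volume_models[[region]]
    mu <- m$intercept + m$age * obs$age_scan + m$sex * sexF[obs$idx] +
      m$invivo * obs$invivo +
      m$eta["AD"] * AD[obs$idx] + m$eta["FTD"] * FTD[obs$idx] +
      m$eta["OD"] * OD[obs$idx] + m$eta["VD"] * VD[obs$idx] +
      m$eta["M"] * M[obs$idx]
    tibble(donor = donors$donor[obs$idx], invivo = obs$invivo,
           age_scan = obs$age_scan, region = region,
           volume = mu + rnorm(nrow(obs), sd = m$sd))
  })
  list(donors = donors, volumes = vols)
}
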