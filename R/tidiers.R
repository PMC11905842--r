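#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a robust fit
#'
#' @param x a [fit_robust_linear()] result.
#' @param ... unused.
#' @return A tibble with term, estimate, std_error, statistic, p_value.
#' @export
tidy.robust_fit <- function(x, ...) x$coefficients

#' @rdname tidy.robust_fit
#' @export
glance.robust_fit <- function(x, ...) {
  tibble(n = x$n,
         sigma = x$fit$s,
         converged = x$fit$converged)
}

#' @rdname tidy.age_score_fit
#' @export
glance.age_score_fit <- function(x, ...) {
  tibble(n = x$n, alpha = x$alpha, beta = x$beta, gamma = x$gamma,
         delta = x$delta, eta = x$eta, lambda = x$lambda,
         negative_error_points = x$negative_error_points)
}

#' Tidy the quadratic age-score model
#'
#' @param x a [fit_age_score_band()] result.
#' @param ... unused.
#' @return Coefficients of both steps, labeled by `model` (`"age"` or
#'   `"abs_error"`).
#' @export
tidy.age_score_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$age_fit$coefficients, model = "age", .before = 1),
    dplyr::mutate(x$error_fit$coefficients, model = "abs_error", .before = 1)
  )
}

#' Plot the age-score fit with its error band
#'
#' @param object a [fit_age_score_band()] result.
#' @param ... unused.
#' @return A ggplot object: predicted age against the sum of scores with the
#'   plus/minus absolute-error band.
#' @export
autoplot.age_score_fit <- function(object, ...) {
  ggplot2::ggplot(object$band, ggplot2::aes(x = .data$s)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted)) +
    ggplot2::labs(x = "sum of neuropathology scores",
                  y = "age at death (years)",
                  title = "Robust quadratic age trend with absolute-error band")
}

#' Plot regional hyperintensity fractions
#'
#' @param object a `region_table` from [regional_wmh_fractions()].
#' @param top show the `top` regions with the largest fractions.
#' @param ... unused.
#' @return A ggplot bar chart of the per-region hyperintensity fraction.
#' @export
autoplot.region_table <- function(object, top = 20, ...) {
  d <- dplyr::slice_max(as_tibble(object), .data$fraction, n = top)
  d$name <- factor(d$name, levels = rev(d$name))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fraction, y = .data$name)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "hyperintensity fraction of region volume", y = NULL)
}

#' Plot cross-validation segmentation metrics
#'
#' @param object the tibble returned by [cross_validate()].
#' @param ... unused.
#' @return A ggplot dot chart of Dice/TPR/TNR per held-out sample.
#' @export
plot_cv_metrics <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::filter(object, !.data$sample_id %in% c("average", "pulled")),
    c("dice", "tpr", "tnr"), names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Leave-one-out brain-extraction metrics") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
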