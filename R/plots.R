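#' @method autoplot ba_fit
#' @export
autoplot.ba_fit <- function(object, level = 0.95, ...) {
  loa <- limits_of_agreement(object, level = level)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(intercept = object$intercept_a,
                         slope = object$slope_b, linewidth = 0.9) +
    ggplot2::geom_abline(intercept = loa$intercept, slope = loa$slope,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "Mean of platform log scores",
      y = "Difference (y - x)",
      title = "Difference vs mean with fitted line and limits of agreement"
    )
}

#' Plot Kaplan-Meier curves from a km_fit table
#'
#' @param km A tibble from [km_fit()].
#' @return A ggplot step-function plot, one curve per group.
#' @export
plot_km <- function(km) {
  start <- km %>%
    distinct(.data$group) %>%
    mutate(time = 0, survival = 1)
  ggplot2::ggplot(
    bind_rows(start, select(km, "group", "time", "survival")),
    ggplot2::aes(x = .data$time, y = .data$survival,
                 colour = .data$group)
  ) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Recurrence-free survival",
                  colour = "Group")
}

#' Plot an AUC(t) series
#'
#' @param series One or more AUC series from [auc_series()]; pass a named
#'   list to overlay platforms.
#' @return A ggplot of AUC against horizon.
#' @export
plot_auc_series <- function(series) {
  if (is.data.frame(series)) series <- list(marker = series)
  d <- bind_rows(series, .id = "platform")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$horizon_months, y = .data$auc,
                                  colour = .data$platform)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Horizon (months)", y = "AUC(t)",
                  colour = "Platform")
}
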