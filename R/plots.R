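#' Observed rates against the composite expectation band
#'
#' Plots the observed monthly rate per 1,000 as a line over the composite
#' expectation band ribbon, faceted by subgroup when the band table is
#' stratified. A dashed vertical line marks the reference month.
#'
#' @param band_tbl Output of [expectation_band()] including observed `rate`.
#' @param reference Reference month drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_expectation_band <- function(band_tbl, reference = as.Date("2020-03-01")) {
  by <- intersect(c("age_band", "sex", "ethnicity", "imd_quintile"), names(band_tbl))
  p <- ggplot2::ggplot(band_tbl, ggplot2::aes(x = .data$month)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected),
      colour = "steelblue", linetype = "dotted"
    ) +
    ggplot2::geom_vline(xintercept = reference, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = NULL, y = "Measurements per 1,000 per month",
      title = "Observed monthly rate vs. composite expectation band"
    ) +
    ggplot2::theme_minimal()
  if ("rate" %in% names(band_tbl)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$rate), colour = "black")
  }
  if (length(by) > 0) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", paste(by, collapse = "+"))))
  }
  p
}

#' Relative deviation trajectory
#'
#' Plots the monthly relative deviation (%) from the expectation band with
#' its interval ribbon and a horizontal reference at zero.
#'
#' @param band_tbl Output of [expectation_band()] including observed `rate`.
#' @param reference Reference month drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_deviation <- function(band_tbl, reference = as.Date("2020-03-01")) {
  by <- intersect(c("age_band", "sex", "ethnicity", "imd_quintile"), names(band_tbl))
  dev <- dplyr::bind_cols(
    dplyr::select(band_tbl, dplyr::all_of(c(by, "month"))),
    deviation(band_tbl$rate, band_tbl$lower, band_tbl$upper)[-(1:4)]
  )
  p <- ggplot2::ggplot(dev, ggplot2::aes(x = .data$month)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$d_rel_lower, ymax = .data$d_rel_upper),
      fill = "firebrick", alpha = 0.2
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$d_rel), colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = reference, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = NULL, y = "Deviation from expected (%)",
      title = "Relative deviation from the expectation band"
    ) +
    ggplot2::theme_minimal()
  if (length(by) > 0) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", paste(by, collapse = "+"))))
  }
  p
}

#' Fitted seasonal curve
#'
#' Displays the fitted cyclic seasonal effect of a `trend_fit` over the
#' month-of-year, on the linear-predictor (log-rate) scale, centered per the
#' fit's sum-to-zero constraint.
#'
#' @param object A `trend_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, ...) {
  grid <- seq(0, 12, by = 0.05)
  B <- cyclic_basis(grid, object$meta$basis) %*% object$meta$Z
  sc <- object$coefficients[grep("^season", names(object$coefficients))]
  curve <- tibble::tibble(m = grid, effect = drop(B %*% sc))
  ggplot2::ggplot(curve, ggplot2::aes(.data$m, .data$effect)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_x_continuous(breaks = 0:12) +
    ggplot2::labs(
      x = "Month-of-year position", y = "Seasonal effect (log rate)",
      title = "Fitted cyclic seasonal curve"
    ) +
    ggplot2::theme_minimal()
}
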