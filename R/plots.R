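# ggplot2 figure methods for the main result types. Each mirrors the
# conventional presentation: grouped bars of mean +/- SE per priming
# within challenge.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

treatment_bar <- function(data, y, se, ylab) {
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$challenge, y = {{ y }}, fill = .data$priming
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7, colour = "black") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = {{ y }} - {{ se }}, ymax = {{ y }} + {{ se }}),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::scale_fill_grey(start = 1, end = 0.3) +
    ggplot2::labs(x = "challenge", y = ylab, fill = "priming") +
    ggplot2::theme_classic()
}

#' Plot relative expression per treatment cell
#'
#' Grouped bars of mean 2^-ddCt relative expression (+/- SE) per priming
#' within each challenge, faceted by gene when several are present.
#'
#' @param object A `sod_rq` tibble from [relative_expression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sod_rq <- function(object, ...) {
  p <- treatment_bar(object, .data$rq_mean, .data$rq_se,
                     "relative expression (2^-ddCt)")
  if (length(unique(object$gene)) > 1L) {
    p <- p + ggplot2::facet_wrap(~gene, scales = "free_y")
  }
  p
}

#' Plot survival proportions per treatment cell
#'
#' @param object A `sod_survival` tibble from [survival_proportions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sod_survival <- function(object, ...) {
  treatment_bar(object, .data$mean, .data$se, "proportion surviving") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}

#' Plot specific SOD activity per treatment cell
#'
#' Summarises per-sample specific activities as mean +/- SE across
#' experiments before plotting.
#'
#' @param object A `sod_activity` tibble from [sod_activity()] carrying
#'   `priming`/`challenge` columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sod_activity <- function(object, ...) {
  stopifnot(all(c("priming", "challenge") %in% names(object)))
  d <- object |>
    dplyr::group_by(.data$priming, .data$challenge) |>
    dplyr::summarise(
      mean = mean(.data$specific_activity_u_per_mg),
      se = stats::sd(.data$specific_activity_u_per_mg) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  treatment_bar(d, .data$mean, .data$se, "SOD specific activity (U/mg)")
}

#' Plot a qPCR standard curve
#'
#' Dilution points with the fitted OLS line; the subtitle reports slope
#' and amplification efficiency.
#'
#' @param object A `sod_std_curve` from [standard_curve_efficiency()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sod_std_curve <- function(object, ...) {
  d <- object$fit$model
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log10_quantity, y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::labs(
      x = "log10 template quantity", y = "Ct",
      subtitle = sprintf("slope %.3f, efficiency %.3f", object$slope,
                         object$efficiency)
    ) +
    ggplot2::theme_classic()
}
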