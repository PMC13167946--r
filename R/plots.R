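#' Heatmap of a functional connectivity matrix
#'
#' @param object An `nirs_fc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nirs_fc
#' @export
autoplot.nirs_fc <- function(object, ...) {
  df <- expand.grid(channel_a = object$channels,
                    channel_b = object$channels)
  df$r <- as.vector(object$r)
  ggplot2::ggplot(df, ggplot2::aes(.data$channel_a, .data$channel_b,
                                   fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Task-state FC: %s (%s, %s)", object$subject,
                      object$group, object$timepoint),
      x = "channel", y = "channel", fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Channel activation statistic map
#'
#' Per-channel t-statistics grouped by ROI, significant channels
#' (BH-FDR q < 0.05) filled.
#'
#' @param tests Output of [channel_activation_tests()].
#' @return A ggplot.
#' @export
plot_channel_activation <- function(tests) {
  facet <- if ("timepoint" %in% names(tests))
    ggplot2::facet_grid(ggplot2::vars(.data$group),
                        ggplot2::vars(.data$timepoint))
  else ggplot2::facet_wrap(ggplot2::vars(.data$group))
  ggplot2::ggplot(tests, ggplot2::aes(
    factor(.data$channel), .data$statistic, fill = .data$roi,
    alpha = .data$sig)) +
    ggplot2::geom_col() +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 1),
                                guide = "none") +
    facet +
    ggplot2::labs(x = "channel", y = "t statistic", fill = "ROI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, size = 6))
}

#' Brain-behaviour correlation scatter
#'
#' @param data One row per subject.
#' @param fc,scale Columns (tidy-eval) with the connectivity and scale
#'   changes.
#' @return A ggplot with the least-squares line.
#' @export
plot_fc_outcome <- function(data, fc, scale) {
  ggplot2::ggplot(data, ggplot2::aes({{ fc }}, {{ scale }})) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "#B2182B") +
    ggplot2::labs(x = "change in mean FC", y = "scale change") +
    ggplot2::theme_minimal()
}

#' Overview plot of a pipeline run
#'
#' Mean-FC change per subject by group.
#'
#' @param object A `vft_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vft_run
#' @export
autoplot.vft_run <- function(object, ...) {
  d <- object$fc$summary |>
    dplyr::select("subject", "group", "timepoint", "mean_fc") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "mean_fc") |>
    dplyr::mutate(delta = .data$post - .data$pre)
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$delta,
                                  colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = "change in mean FC (r)") +
    ggplot2::theme_minimal()
}
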