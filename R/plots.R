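#' Plot distance-binned asymmetry by pathology group
#'
#' Group means with standard-error bars per distance segment, faceted by
#' metric: the standard layout for peritumoral gradient results.
#'
#' @param distance_tbl Cohort distance-asymmetry tibble (from
#'   [cohort_asymmetry()] or [analyze_cohort()]), with `segment`,
#'   `metric`, `asymmetry`, `pathology`.
#' @return A ggplot object.
#' @export
plot_distance_asymmetry <- function(distance_tbl) {
  seg_levels <- unique(asym_distance_bins()$segment)
  d <- distance_tbl |>
    dplyr::filter(!is.na(.data$asymmetry)) |>
    dplyr::mutate(segment = factor(.data$segment,
                                   levels = union(seg_levels,
                                                  unique(.data$segment)))) |>
    dplyr::group_by(.data$metric, .data$segment, .data$pathology) |>
    dplyr::summarise(mean = mean(.data$asymmetry),
                     sem = sd(.data$asymmetry) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$segment, y = .data$mean,
                                  fill = .data$pathology)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           position = ggplot2::position_dodge(0.8),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Distance from tumor margin (nodes)",
                  y = "Asymmetry (%)", fill = "Pathology") +
    ggplot2::theme_minimal()
}

#' Plot tract profiles by hemisphere
#'
#' Mean node profile per hemisphere for one metric, faceted by tract.
#'
#' @param profiles Profile tibble.
#' @param metric Metric column name.
#' @return A ggplot object.
#' @export
plot_tract_profile <- function(profiles, metric = "fw_fa") {
  d <- profiles |>
    dplyr::group_by(.data$tract, .data$hemisphere, .data$node) |>
    dplyr::summarise(value = mean(.data[[metric]], na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$node, y = .data$value,
                                  color = .data$hemisphere)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~tract, scales = "free_y") +
    ggplot2::labs(x = "Node", y = metric, color = "Hemisphere") +
    ggplot2::theme_minimal()
}

#' Plot a mid-axial slice of the fitted free-water fraction
#'
#' @param object An `fw_fit`.
#' @param slice Axial slice index (default: middle).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fw_fit <- function(object, slice = NULL, ...) {
  d <- dim(object$fwf_map)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$fwf <- as.vector(object$fwf_map[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$fwf)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Free-water fraction, slice %d", slice),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
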