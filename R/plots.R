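#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot depth profiles
#'
#' Mean profile with a per-depth interquartile ribbon across masked-in
#' vertices, depth 1 (pial) on the left.
#'
#' @param object A `laminar_profiles` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.laminar_profiles <- function(object, ...) {
  p <- unclass(object)[attr(object, "mask"), , drop = FALSE]
  df <- tibble::tibble(
    depth = seq_len(ncol(p)),
    mean = colMeans(p),
    q25 = apply(p, 2, stats::quantile, 0.25),
    q75 = apply(p, 2, stats::quantile, 0.75))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(p))) +
    ggplot2::labs(x = "cortical depth (1 = pial)", y = "intensity",
                  title = "Depth profiles (mean and IQR)") +
    ggplot2::theme_minimal()
}

#' Plot moment-sorted profile bins
#'
#' Heatmap of bin-averaged profiles against the sorting moment: the visual
#' summary of how profile shape changes with the center of gravity or
#' variance.
#'
#' @param bins Output of [moment_sorted_bins()].
#' @return A ggplot.
#' @export
plot_moment_bins <- function(bins) {
  long <- tidyr::pivot_longer(bins, dplyr::starts_with("depth_"),
                              names_to = "depth", values_to = "intensity")
  long$depth <- as.integer(sub("depth_", "", long$depth))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$depth,
                                     fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(breaks = unique(long$depth)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "moment-sorted bin", y = "cortical depth (1 = pial)",
                  fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a parcel effect map
#'
#' Per-parcel t-values with FDR significance marked.
#'
#' @param object An effect-map tibble from [parcelwise_effects()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tbl_effectmap <- function(object, ...) plot_effect_map(object)

#' @rdname autoplot.tbl_effectmap
#' @param effects Effect-map tibble.
#' @export
plot_effect_map <- function(effects) {
  df <- dplyr::arrange(effects, .data$statistic)
  df$parcel_id <- factor(df$parcel_id, levels = df$parcel_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parcel_id, y = .data$statistic,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "parcel", y = sprintf("t (%s)", df$term[1]),
                  fill = "FDR significant") +
    ggplot2::theme_minimal()
}

#' Plot a spin-test null distribution
#'
#' Histogram of permuted correlations with the observed value marked.
#'
#' @param object A `laminar_spin` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.laminar_spin <- function(object, ...) {
  df <- tibble::tibble(r = object$null_r[!is.na(object$null_r)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$r_obs, color = "red") +
    ggplot2::labs(x = "null correlation", y = "count",
                  title = sprintf("spin test: r = %.3f, p = %.4g",
                                  object$r_obs, object$p_spin)) +
    ggplot2::theme_minimal()
}
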