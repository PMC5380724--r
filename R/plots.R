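# Basic ggplot2 views of the main result types.

#' Plot a voxel-wise ERD map
#'
#' Axial projection (x-y plane) of the relative band-power change, with
#' significant voxels outlined when inference has been added.
#'
#' @param erd an `erd_map` from [differential_band_power()] /
#'   [erd_inference()].
#' @param grid the `meg_grid` the voxels refer to.
#' @return A ggplot object.
#' @export
plot_erd_map <- function(erd, grid) {
  df <- dplyr::mutate(erd,
                      x = grid$points[.data$voxel, 1],
                      y = grid$points[.data$voxel, 2])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        colour = .data$rel_power_change)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey90",
                                    high = "red", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m, left-right)", y = "y (m, post-ant)",
                  colour = "rel. power\nchange",
                  title = "Relative band-power change (active vs baseline)")
  if ("significant" %in% names(df) && any(df$significant, na.rm = TRUE))
    p <- p + ggplot2::geom_point(data = df[which(df$significant), ],
                                 shape = 1, size = 3.5, colour = "black")
  p
}

#' Plot parcel-level centrality
#'
#' Bars of a parcel metric split by hemisphere, the standard view for
#' spotting lateralized hubs.
#'
#' @param parcels a parcel tibble from [parcellate_and_scale()].
#' @param metric metric column to show.
#' @return A ggplot object.
#' @export
plot_parcel_centrality <- function(parcels, metric = "evc") {
  ggplot2::ggplot(parcels,
                  ggplot2::aes(x = stats::reorder(.data$name, .data[[metric]]),
                               y = .data[[metric]],
                               fill = .data$hemisphere)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = metric,
                  title = sprintf("Parcel %s (scaled)", metric))
}
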