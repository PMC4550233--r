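#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

field_raster_df <- function(m, pixel_size = 1) {
  tibble::tibble(
    x = rep((seq_len(ncol(m)) - 0.5) * pixel_size, each = nrow(m)),
    y = rep((seq_len(nrow(m)) - 0.5) * pixel_size, times = ncol(m)),
    intensity = as.vector(m))
}

#' Plot an excitation field
#'
#' @param object An `excitation_field`.
#' @param ... Unused.
#' @return A ggplot raster of the lateral excitation map (um axes).
#' @export
autoplot.excitation_field <- function(object, ...) {
  df <- field_raster_df(object$lateral, object$pixel_size)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "rel. excitation") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (μm)", y = "y (μm)",
                  title = object$mode_tag)
}

#' Plot an image stack as a maximum-intensity projection
#'
#' @param object An `image_stack` or `ratio_stack`.
#' @param frame_range Frames to project; default all.
#' @param ... Unused.
#' @return A ggplot raster (pixel axes).
#' @export
autoplot.image_stack <- function(object,
                                 frame_range = c(1L, length(object$frames)),
                                 ...) {
  m <- max_projection(object, frame_range)
  df <- field_raster_df(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "counts") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("max projection, frames %d-%d",
                                  frame_range[1], frame_range[2]))
}

#' @rdname autoplot.image_stack
#' @export
autoplot.ratio_stack <- function(object,
                                 frame_range = c(1L, length(object$frames)),
                                 ...) {
  m <- max_projection(object, frame_range)
  df <- field_raster_df(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * F / F[0])) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Plot ROI traces over time
#'
#' @param traces A trace tibble (possibly several ROIs bound together).
#' @return A ggplot line plot, one line per ROI.
#' @export
plot_traces <- function(traces) {
  ggplot2::ggplot(traces, ggplot2::aes(.data$time, .data$value,
                                       colour = .data$roi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mean ROI value")
}

#' Plot the TIRF/WF amplitude-ratio histogram of a puff analysis
#'
#' @param object A `puff_analysis`.
#' @param ... Unused.
#' @return A ggplot bar chart of event counts per ratio bin, coloured by
#'   site class; a dashed line marks ratio 1.
#' @export
autoplot.puff_analysis <- function(object, ...) {
  ev <- dplyr::filter(object$events, .data$included)
  ev <- dplyr::left_join(ev,
                         dplyr::select(object$sites, "site_id", "class"),
                         by = "site_id")
  ev$class[is.na(ev$class)] <- "unclassified"
  ggplot2::ggplot(ev, ggplot2::aes(.data$ratio, fill = .data$class)) +
    ggplot2::geom_histogram(binwidth = 0.1, boundary = 0,
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "puff amplitude ratio (TIRF / WF)", y = "events")
}
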