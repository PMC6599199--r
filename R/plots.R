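#' Plot a window track along the genome
#'
#' @param track A window track (windowed diversity, F_ST, mean score, or
#'   ratio).
#' @param ylab Axis label.
#' @return A ggplot.
#' @export
plot_window_track <- function(track, ylab = "value") {
  mid <- (track$start + track$end) / 2
  ggplot2::ggplot(dplyr::mutate(track, mid = mid),
                  ggplot2::aes(x = .data$mid / 1e6, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot an LD-decay curve
#'
#' @param curve An `ld_curve` from [ld_decay()].
#' @return A ggplot of mean r-squared against pair distance.
#' @export
plot_ld_curve <- function(curve) {
  mid <- (curve$bin_start + curve$bin_end) / 2
  ggplot2::ggplot(dplyr::mutate(curve, mid = mid),
                  ggplot2::aes(x = .data$mid / 1000, y = .data$mean_r2)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE, size = 0.8) +
    ggplot2::labs(x = "distance (kb)", y = expression(bar(r)^2)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sweep-scan score track
#'
#' @param object An `xpclr_scan`.
#' @param regions Optional `region_set` to shade.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot xpclr_scan
#' @export
autoplot.xpclr_scan <- function(object, regions = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$pos / 1e6, y = .data$score)) +
    ggplot2::geom_point(size = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "composite-likelihood score") +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(regions),
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "orange",
      inherit.aes = FALSE)
  }
  p
}
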