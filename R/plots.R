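#' Plot an image field
#'
#' Raster display with physical axes in micrometres.
#'
#' @param object An [image_field()].
#' @param trim Upper quantile used to clip the display range (robust
#'   against hot pixels).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot image_field
#' @export
autoplot.image_field <- function(object, trim = 0.999, ...) {
  m <- field_matrix(object)
  ps_um <- pixel_size(object) / 1000
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- pmin(as.vector(m), stats::quantile(m, trim))
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$col - 1) * ps_um,
                                   y = (.data$row - 1) * ps_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "counts") +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = attr(object, "frame")) +
    ggplot2::theme_minimal()
}

#' Histograms of per-cluster quantities
#'
#' Frequency distributions of cluster area, channel counts or molecular
#' density, the standard descriptive figures of a cluster analysis.
#'
#' @param records Cluster-record tibble.
#' @param what One of `"counts"`, `"area_um2"`, `"density_per_um2"`,
#'   `"diameter_nm"`.
#' @param binwidth Histogram bin width (sensible default per quantity).
#' @return A ggplot object.
#' @export
plot_cluster_histogram <- function(records,
                                   what = c("counts", "area_um2",
                                            "density_per_um2",
                                            "diameter_nm"),
                                   binwidth = NULL) {
  what <- match.arg(what)
  if (is.null(binwidth)) {
    binwidth <- switch(what, counts = 1, area_um2 = 0.002,
                       density_per_um2 = 50, diameter_nm = 10)
  }
  lab <- switch(what, counts = "channel counts per cluster",
                area_um2 = "cluster area (µm²)",
                density_per_um2 =
                  "molecular density (µm⁻²)",
                diameter_nm = "cluster diameter (nm)")
  ggplot2::ggplot(records, ggplot2::aes(x = .data[[what]])) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30",
                            color = "white") +
    ggplot2::labs(x = lab, y = "clusters") +
    ggplot2::theme_classic()
}

#' Plot a density-by-counts histogram
#'
#' Bar plot of cluster density per channel-count bin with standard-error
#' bars across fields, as produced by [density_by_count_histogram()].
#'
#' @param hist Result of [density_by_count_histogram()].
#' @return A ggplot object.
#' @export
plot_density_by_counts <- function(hist) {
  df <- hist$histogram
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid,
                                   y = .data$density_per_um2)) +
    ggplot2::geom_col(fill = "grey40", width = diff(df$mid[1:2]) * 0.9) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$density_per_um2 - .data$sem,
      ymax = .data$density_per_um2 + .data$sem), width = 0.3) +
    ggplot2::labs(x = "channel counts",
                  y = "cluster density (µm⁻²)") +
    ggplot2::theme_classic()
}
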