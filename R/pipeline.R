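#' Analyze one STED field end to end
#'
#' Segmentation ([segment_clusters()]), quantification
#' ([quantify_clusters()]) and the per-field summary ([field_summary()])
#' in one call.
#'
#' @param raw Raw [image_field()].
#' @param calib `calibration_model` or single-dye brightness (`NULL` skips
#'   counting).
#' @param config An [analysis_config()].
#' @param analyzed_area_um2 Analyzed membrane area; defaults to the full
#'   frame area. Supply the cell-footprint area when the frame contains
#'   empty glass.
#' @return A `cluster_analysis` list: `clusters` (record tibble), `summary`
#'   (one-row field summary), `rois`, `config`. `tidy()` returns the
#'   cluster records, `glance()` the field summary.
#' @export
analyze_field <- function(raw, calib = NULL, config = analysis_config(),
                          analyzed_area_um2 = NULL) {
  stopifnot(inherits(raw, "image_field"))
  if (is.null(analyzed_area_um2)) {
    analyzed_area_um2 <- prod(dim(raw)) * (pixel_size(raw) / 1000)^2
  }
  rois <- segment_clusters(raw, config)
  clusters <- quantify_clusters(raw, rois, calib, config)
  summary <- field_summary(clusters, analyzed_area_um2)
  structure(list(clusters = clusters, summary = summary, rois = rois,
                 config = config),
            class = "cluster_analysis")
}

#' @export
print.cluster_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<cluster_analysis> %d clusters over %.3g um^2 ",
                     "(%.3g clusters/um^2)\n"),
              s$n_clusters, s$analyzed_area_um2,
              s$cluster_density_per_um2))
  if (s$n_clusters > 0 && !all(is.na(x$clusters$counts))) {
    cat(sprintf("  mean counts %.3g, mean area %.3g um^2\n",
                mean(x$clusters$counts), mean(x$clusters$area_um2)))
  }
  invisible(x)
}

#' Tidy a cluster analysis
#'
#' `tidy()` returns the per-cluster records, `glance()` the one-row field
#' summary (without the nearest-neighbour list-column).
#'
#' @param x A `cluster_analysis`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cluster_analysis
#' @export
tidy.cluster_analysis <- function(x, ...) x$clusters

#' @rdname tidy.cluster_analysis
#' @method glance cluster_analysis
#' @export
glance.cluster_analysis <- function(x, ...) {
  dplyr::select(x$summary, -"nnd_nm")
}
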