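#' Write and read cluster tables
#'
#' Cluster records are exchanged as plain CSV with one row per cluster and a
#' documented column set (see [quantify_clusters()] for the semantics):
#' `frame`, `label`, `centroid_x_um`, `centroid_y_um`, `area_px`,
#' `area_um2`, `diameter_nm`, `roundness`, `background`, `brightness`,
#' `counts`, `density_per_um2`, `pixel_size_nm`. Values round-trip at full
#' double precision.
#'
#' @param records Tibble of cluster records; all rows must share one
#'   `pixel_size_nm` (records from one acquisition setting).
#' @param path Output CSV path.
#' @return `path` invisibly; [read_cluster_table()] returns a tibble.
#' @export
write_cluster_table <- function(records, path) {
  cols <- cluster_table_columns()
  if (nrow(records) > 0L) {
    missing_cols <- setdiff(cols, names(records))
    if (length(missing_cols) > 0L) {
      stop("cluster table lacks columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    ps <- unique(records$pixel_size_nm)
    if (length(ps) != 1L) {
      stop("records mix pixel sizes (", paste(ps, collapse = ", "),
           " nm); write one acquisition setting per table", call. = FALSE)
    }
  } else {
    records <- tibble::as_tibble(stats::setNames(
      lapply(cols, function(x) numeric(0)), cols))
    records$frame <- character(0)
  }
  readr::write_csv(records[, cols], path)
  log_stage("write_cluster_table", n = nrow(records), path = path)
  invisible(path)
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) {
  spec <- readr::cols(frame = readr::col_character(),
                      .default = readr::col_double())
  readr::read_csv(path, col_types = spec)
}

cluster_table_columns <- function() {
  c("frame", "label", "centroid_x_um", "centroid_y_um", "area_px",
    "area_um2", "diameter_nm", "roundness", "background", "brightness",
    "counts", "density_per_um2", "pixel_size_nm")
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the segmentation/quantification
#' pipeline. Defaults follow the published workflow where it states values
#' (bandpass 2.5--20 px, minimum 5 px per region, mean intensity at least
#' 50% above background, background ring by differential enlargement 2 vs
#' 4 px, endosome bandpass 4--30 px); the remaining defaults are declared
#' package choices documented in the methods vignette.
#'
#' @param band_low_px,band_high_px Structure-size bandpass cutoffs (px).
#' @param min_roi_px Minimum region size in pixels.
#' @param min_contrast Minimum relative contrast: regions are kept when the
#'   mean raw intensity is at least `(1 + min_contrast) * background`.
#' @param ring_inner_px,ring_outer_px Differential dilation radii (px) of
#'   the local-background ring.
#' @param threshold_method Marker binarization method: `"triangle"`,
#'   `"li"` or `"mean_of_background"`.
#' @param endo_band Bandpass (px) applied before marker binarization.
#' @param min_prominence Peak prominence threshold on the filtered image;
#'   `NULL` (default) uses 4x the robust noise scale (1.4826 x MAD), see
#'   [detect_maxima()].
#' @param min_particles Minimum accepted particles for calibration.
#' @param aperture_correction Rule converting brightness integrated over a
#'   half-maximum region into total spot brightness: `"gaussian"`
#'   (default) for the per-spot model-based correction of
#'   [aperture_fraction()], or a fixed numeric multiplier (2 is the
#'   continuous-Gaussian value; 1 disables the correction).
#' @param background_k `k` in the mean-of-background threshold
#'   (mean + k * sd of background pixels).
#' @param seed Integer seed recorded in outputs.
#' @return A list with class `analysis_config`.
#' @export
analysis_config <- function(band_low_px = 2.5, band_high_px = 20,
                            min_roi_px = 5L, min_contrast = 0.5,
                            ring_inner_px = 2L, ring_outer_px = 4L,
                            threshold_method = "triangle",
                            endo_band = c(4, 30),
                            min_prominence = NULL,
                            min_particles = 20L,
                            aperture_correction = "gaussian",
                            background_k = 2,
                            seed = 1L) {
  stopifnot(band_low_px > 0, band_low_px < band_high_px,
            ring_inner_px < ring_outer_px, min_roi_px >= 1,
            min_contrast > 0, length(endo_band) == 2L,
            endo_band[1] < endo_band[2],
            identical(aperture_correction, "gaussian") ||
              (is.numeric(aperture_correction) && aperture_correction > 0))
  structure(list(band_low_px = band_low_px, band_high_px = band_high_px,
                 min_roi_px = as.integer(min_roi_px),
                 min_contrast = min_contrast,
                 ring_inner_px = as.integer(ring_inner_px),
                 ring_outer_px = as.integer(ring_outer_px),
                 threshold_method = match.arg(threshold_method,
                   c("triangle", "li", "mean_of_background")),
                 endo_band = endo_band,
                 min_prominence = min_prominence,
                 min_particles = as.integer(min_particles),
                 aperture_correction = aperture_correction,
                 background_k = background_k,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param path YAML file path.
#' @export
write_config <- function(x, path) {
  stopifnot(inherits(x, "analysis_config"))
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname analysis_config
#' @param x An `analysis_config` (for `write_config`).
#' @export
read_config <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

# structured one-line log messages, silenced unless
# options(stedclust.verbose = TRUE)
log_stage <- function(stage, ...) {
  if (!isTRUE(getOption("stedclust.verbose", FALSE))) return(invisible())
  kv <- list(...)
  msg <- paste0("[", stage, "] ",
                paste(names(kv), unlist(kv), sep = "=", collapse = " "))
  message(msg)
  invisible()
}
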