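#' Describe a calibration standard
#'
#' Reference particles (DNA-origami-like) carrying a known nominal number
#' of dye binding sites, used to convert brightness into molecule counts.
#' The commercial standards used in STED brightness referencing carry
#' 23 +/- 3 or 7 +/- 1 dye sites; a labeling efficiency of about 70% has
#' been reported for such origami structures, which is the default
#' `reference_ele` (set 1 for naive counting that treats standards as
#' fully labeled).
#'
#' @param nominal_sites Nominal number of dye binding sites (>= 1).
#' @param sites_sd Standard deviation of the site number across particles.
#' @param reference_ele Fraction of sites actually carrying a dye, (0, 1].
#' @return A `calibration_standard` list.
#' @export
calibration_standard <- function(nominal_sites, sites_sd = 0,
                                 reference_ele = 0.7) {
  stopifnot(nominal_sites >= 1, sites_sd >= 0,
            reference_ele > 0, reference_ele <= 1)
  structure(list(nominal_sites = as.integer(nominal_sites),
                 sites_sd = sites_sd,
                 reference_ele = reference_ele),
            class = "calibration_standard")
}

#' Measure reference-particle brightnesses in a calibration field
#'
#' Runs the identical quantitative workflow as for cluster samples
#' (bandpass, maxima detection, half-maximum expansion, candidate filters,
#' ring background, integrated brightness with aperture correction) and
#' returns one total brightness per accepted particle.
#'
#' @param field Calibration [image_field()] imaged under the same settings
#'   as the samples.
#' @param config An [analysis_config()]; `min_particles` sets the floor
#'   below which the field is rejected.
#' @return Numeric vector of particle brightnesses.
#' @export
measure_particles <- function(field, config = analysis_config()) {
  rois <- segment_clusters(field, config)
  if (nrow(rois) < config$min_particles) {
    stop("insufficient particles: detected ", nrow(rois), ", need >= ",
         config$min_particles, call. = FALSE)
  }
  records <- quantify_clusters(field, rois, calib = NULL, config = config)
  log_stage("measure_particles", n = nrow(records))
  records$brightness
}

#' Fit the single-dye brightness from particle brightness distributions
#'
#' The single-dye brightness is the median particle brightness divided by
#' the expected number of dyes per particle
#' (`nominal_sites * reference_ele`). The median resists incomplete
#' structures and aggregates. When several standards are supplied (lists of
#' equal length), per-standard estimates are combined by a
#' particle-count-weighted mean.
#'
#' @param brightnesses Numeric vector of particle brightnesses from
#'   [measure_particles()], or a list of such vectors (one per standard).
#' @param standard A [calibration_standard()], or a list of them matching
#'   `brightnesses`.
#' @param min_particles Minimum particles per standard.
#' @return A `calibration_model`: `single_dye_brightness` (units/dye),
#'   `n_particles`, `per_standard` tibble and `dispersion` (1.4826 x MAD
#'   of the pooled brightnesses).
#' @examples
#' fit_single_dye(rep(230, 30), calibration_standard(23, reference_ele = 1))
#' @export
fit_single_dye <- function(brightnesses, standard, min_particles = 20L) {
  if (!is.list(brightnesses)) {
    brightnesses <- list(brightnesses)
    standard <- list(standard)
  }
  stopifnot(length(brightnesses) == length(standard))
  per <- dplyr::bind_rows(lapply(seq_along(standard), function(i) {
    b <- brightnesses[[i]]
    s <- standard[[i]]
    stopifnot(inherits(s, "calibration_standard"))
    if (length(b) < min_particles) {
      stop("insufficient particles for the ", s$nominal_sites,
           "-site standard: ", length(b), " < ", min_particles,
           call. = FALSE)
    }
    med <- stats::median(b)
    if (med <= 0) {
      stop("non-positive median particle brightness", call. = FALSE)
    }
    tibble::tibble(nominal_sites = s$nominal_sites,
                   reference_ele = s$reference_ele,
                   n_particles = length(b),
                   median_brightness = med,
                   estimate = med / (s$nominal_sites * s$reference_ele))
  }))
  pooled <- unlist(brightnesses)
  model <- structure(list(
    single_dye_brightness =
      sum(per$estimate * per$n_particles) / sum(per$n_particles),
    n_particles = sum(per$n_particles),
    per_standard = per,
    dispersion = stats::mad(pooled)),
    class = "calibration_model")
  log_stage("fit_single_dye", estimate = signif(model$single_dye_brightness, 4),
            n = model$n_particles)
  model
}

#' Calibrate from a calibration image field
#'
#' Convenience wrapper: [measure_particles()] then [fit_single_dye()].
#'
#' @inheritParams measure_particles
#' @param standard A [calibration_standard()].
#' @return A `calibration_model`.
#' @export
calibrate_field <- function(field, standard, config = analysis_config()) {
  fit_single_dye(measure_particles(field, config), standard,
                 min_particles = config$min_particles)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> single-dye brightness %.4g units/dye\n",
              x$single_dye_brightness))
  cat(sprintf("  %d particles, dispersion %.4g\n", x$n_particles,
              x$dispersion))
  print(x$per_standard)
  invisible(x)
}

#' Tidy a calibration model
#'
#' `tidy()` returns the per-standard estimates; `glance()` a one-row model
#' summary.
#'
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy calibration_model
#' @export
tidy.calibration_model <- function(x, ...) x$per_standard

#' @rdname tidy.calibration_model
#' @method glance calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(single_dye_brightness = x$single_dye_brightness,
                 n_particles = x$n_particles,
                 n_standards = nrow(x$per_standard),
                 dispersion = x$dispersion)
}
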