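#' Simulation parameters for synthetic STED fields
#'
#' Defaults emulate the published acquisition and sample conditions:
#' 25 nm pixels, an effective point-spread-function FWHM of 70 nm, cluster
#' densities of 0.7 per square micrometre, per-cluster channel numbers with
#' mean 8 and median 5.6 (right-skewed; modelled lognormal), and cluster
#' diameters of 120 nm with channel positions uniform in a disk. Dye
#' brightness (integrated photons per dye per frame) and the uniform
#' background are not reported for the source experiments; the defaults of
#' 100 and 5 photons give a realistic single-dye peak signal-to-background
#' for gated STED with avalanche photodiode detection (see the methods
#' vignette).
#'
#' @param field_um Field edge length in micrometres (square field).
#' @param pixel_nm Pixel size in nm.
#' @param psf_fwhm_nm Effective PSF full width at half maximum, nm.
#' @param cluster_density_per_um2 True cluster density.
#' @param counts_law `"lognormal"` (parameterized by `counts_mean` and
#'   `counts_median`) or `"fixed"` (every cluster has `counts_mean`
#'   channels).
#' @param counts_mean,counts_median Mean and median true channels per
#'   cluster.
#' @param cluster_diameter_nm Diameter of the disk holding the emitters.
#' @param dye_brightness Integrated brightness per dye (photons).
#' @param labeling_ele Probability that a channel carries a dye, (0, 1].
#' @param background Uniform background, photons per pixel.
#' @param noise `"poisson"` or `"none"`.
#' @param motion `NULL`, or `list(diffusion_um2_s =, line_time_s =)` for
#'   line-scan motion blur (see [apply_scan_motion()]).
#' @param seed Integer seed; every simulation output is deterministic for
#'   a fixed seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(field_um = 10, pixel_nm = 25, psf_fwhm_nm = 70,
                       cluster_density_per_um2 = 0.7,
                       counts_law = c("lognormal", "fixed"),
                       counts_mean = 8, counts_median = 5.6,
                       cluster_diameter_nm = 120,
                       dye_brightness = 100, labeling_ele = 1,
                       background = 5, noise = c("poisson", "none"),
                       motion = NULL, seed = 1L) {
  counts_law <- match.arg(counts_law)
  noise <- match.arg(noise)
  stopifnot(field_um > 0, pixel_nm > 0, psf_fwhm_nm > 0,
            cluster_density_per_um2 >= 0, counts_mean >= 1,
            counts_median > 0, counts_median <= counts_mean,
            cluster_diameter_nm > 0, dye_brightness > 0,
            labeling_ele > 0, labeling_ele <= 1, background >= 0)
  if (!is.null(motion)) {
    stopifnot(is.list(motion), motion$diffusion_um2_s >= 0,
              motion$line_time_s > 0)
  }
  structure(list(field_um = field_um, pixel_nm = pixel_nm,
                 psf_fwhm_nm = psf_fwhm_nm,
                 cluster_density_per_um2 = cluster_density_per_um2,
                 counts_law = counts_law, counts_mean = counts_mean,
                 counts_median = counts_median,
                 cluster_diameter_nm = cluster_diameter_nm,
                 dye_brightness = dye_brightness,
                 labeling_ele = labeling_ele, background = background,
                 noise = noise, motion = motion, seed = as.integer(seed)),
            class = "sim_params")
}

psf_sigma_nm <- function(params) params$psf_fwhm_nm / (2 * sqrt(2 * log(2)))

field_npx <- function(params) {
  as.integer(round(params$field_um * 1000 / params$pixel_nm))
}

# Gaussian integral over the pixels of one axis: pixel j (1-based) is
# centred at (j-1)*ps with edges at (j-1 +/- 0.5)*ps.
axis_weights <- function(x_nm, sigma_nm, pixel_nm, n_px, n_sigma = 5) {
  jc <- x_nm / pixel_nm + 1
  j0 <- max(1L, as.integer(floor(jc - n_sigma * sigma_nm / pixel_nm - 1)))
  j1 <- min(n_px, as.integer(ceiling(jc + n_sigma * sigma_nm / pixel_nm + 1)))
  if (j0 > j1) return(NULL)
  j <- j0:j1
  w <- stats::pnorm(((j - 0.5) * pixel_nm - x_nm) / sigma_nm) -
    stats::pnorm(((j - 1.5) * pixel_nm - x_nm) / sigma_nm)
  list(idx = j, w = w)
}

#' Render point emitters into an image field
#'
#' Each emitter is drawn as an isotropic 2-D Gaussian PSF integrated over
#' the pixel grid (mass-conserving away from the field border), scaled to
#' its brightness, on top of the uniform background. No noise is applied.
#'
#' @param emitters Tibble/data frame with columns `x_nm`, `y_nm`,
#'   `brightness` (may have zero rows).
#' @param params A [sim_params()].
#' @return An [image_field()].
#' @export
render_field <- function(emitters, params) {
  n_px <- field_npx(params)
  sigma <- psf_sigma_nm(params)
  img <- matrix(params$background, n_px, n_px)
  for (e in seq_len(nrow(emitters))) {
    wx <- axis_weights(emitters$x_nm[e], sigma, params$pixel_nm, n_px)
    wy <- axis_weights(emitters$y_nm[e], sigma, params$pixel_nm, n_px)
    if (is.null(wx) || is.null(wy)) next
    img[wy$idx, wx$idx] <- img[wy$idx, wx$idx] +
      emitters$brightness[e] * outer(wy$w, wx$w)
  }
  image_field(img, pixel_size = params$pixel_nm, channel = "simulated")
}

apply_noise <- function(field, params) {
  if (params$noise == "none") return(field)
  m <- field_matrix(field)
  noisy <- matrix(stats::rpois(length(m), m), nrow(m), ncol(m))
  image_field(noisy, pixel_size = pixel_size(field),
              channel = attr(field, "channel"), frame = attr(field, "frame"))
}

draw_counts <- function(n, params) {
  if (params$counts_law == "fixed") {
    return(rep(as.integer(round(params$counts_mean)), n))
  }
  meanlog <- log(params$counts_median)
  sdlog <- sqrt(2 * log(params$counts_mean / params$counts_median))
  pmax(1L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
}

# uniform points in a disk of the given radius around (cx, cy)
disk_points <- function(n, cx, cy, radius_nm) {
  r <- radius_nm * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  cbind(x = cx + r * cos(a), y = cy + r * sin(a))
}

#' Simulate a field of clustered channel emitters
#'
#' Clusters are placed by a homogeneous Poisson process at the requested
#' density; each cluster draws its true channel number from the counts law,
#' labels each channel independently with probability `labeling_ele`,
#' scatters the labeled emitters uniformly in a disk of the cluster
#' diameter, and renders them as Gaussian PSFs on a uniform background,
#' followed by Poisson shot noise if selected. With `params$motion` set,
#' rendering goes through the line-scan motion model of
#' [apply_scan_motion()].
#'
#' @param params A [sim_params()].
#' @param centers Optional explicit cluster centers (matrix with columns
#'   x/y in nm) overriding the Poisson placement.
#' @return List with `field` (the [image_field()]), `truth` (per-cluster
#'   tibble: `cluster`, `x_nm`, `y_nm`, `n_true`, `n_labeled`,
#'   `diameter_nm`, plus attributes `field_area_um2`, `density_per_um2`,
#'   `seed`), `emitters` (per-emitter tibble) and `params`.
#' @export
simulate_cluster_field <- function(params = sim_params(), centers = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (params$psf_fwhm_nm < params$pixel_nm) {
    warning("PSF FWHM below the pixel size: the field is undersampled",
            call. = FALSE)
  }
  set.seed(params$seed)
  field_nm <- field_npx(params) * params$pixel_nm
  area_um2 <- (field_nm / 1000)^2
  if (is.null(centers)) {
    n_cl <- stats::rpois(1L, params$cluster_density_per_um2 * area_um2)
    centers <- cbind(x = stats::runif(n_cl, 0, field_nm),
                     y = stats::runif(n_cl, 0, field_nm))
  } else {
    centers <- as.matrix(centers)
    n_cl <- nrow(centers)
  }
  n_true <- draw_counts(n_cl, params)
  n_labeled <- stats::rbinom(n_cl, n_true, params$labeling_ele)
  emitters <- purrr::map_dfr(seq_len(n_cl), function(i) {
    if (n_labeled[i] == 0L) return(NULL)
    xy <- disk_points(n_labeled[i], centers[i, 1], centers[i, 2],
                      params$cluster_diameter_nm / 2)
    tibble::tibble(cluster = i, x_nm = xy[, 1], y_nm = xy[, 2],
                   brightness = params$dye_brightness)
  })
  if (nrow(emitters) == 0L) {
    emitters <- tibble::tibble(cluster = integer(0), x_nm = numeric(0),
                               y_nm = numeric(0), brightness = numeric(0))
  }
  field <- if (is.null(params$motion)) {
    render_field(emitters, params)
  } else {
    apply_scan_motion(emitters, params)
  }
  field <- apply_noise(field, params)
  truth <- tibble::tibble(cluster = seq_len(n_cl),
                          x_nm = centers[, 1], y_nm = centers[, 2],
                          n_true = n_true, n_labeled = n_labeled,
                          diameter_nm = params$cluster_diameter_nm)
  attr(truth, "field_area_um2") <- area_um2
  attr(truth, "density_per_um2") <- n_cl / area_um2
  attr(truth, "seed") <- params$seed
  log_stage("simulate_cluster_field", clusters = n_cl,
            emitters = nrow(emitters))
  list(field = field, truth = truth, emitters = emitters, params = params)
}

#' Simulate a calibration-standard field
#'
#' Isolated point-like reference particles on a jittered grid. Each
#' particle draws its dye-site number as `round(Normal(nominal, sd))`
#' clipped at 1, labels each site with probability `reference_ele`
#' (binomial), and is rendered as a single PSF carrying the summed dye
#' brightness. The grid spacing (0.8 um) guarantees isolation; the field
#' grows with the particle number and ignores `params$field_um`.
#'
#' @param params A [sim_params()].
#' @param standard A [calibration_standard()].
#' @param n_particles Number of particles to place (>= 1).
#' @return List with `field`, `truth` (per-particle tibble: `particle`,
#'   `x_nm`, `y_nm`, `sites`, `labeled`, `brightness`) and `params`.
#' @export
simulate_calibration_field <- function(params, standard, n_particles) {
  stopifnot(inherits(params, "sim_params"),
            inherits(standard, "calibration_standard"), n_particles >= 1)
  set.seed(params$seed)
  spacing_nm <- 800
  g <- as.integer(ceiling(sqrt(n_particles)))
  field_um <- g * spacing_nm / 1000 + 0.8
  p <- params
  p$field_um <- field_um
  cells <- utils::head(expand.grid(gx = seq_len(g), gy = seq_len(g)),
                       n_particles)
  jitter <- 0.2 * spacing_nm
  x <- (cells$gx - 0.5) * spacing_nm + 400 +
    stats::runif(n_particles, -jitter, jitter)
  y <- (cells$gy - 0.5) * spacing_nm + 400 +
    stats::runif(n_particles, -jitter, jitter)
  sites <- pmax(1L, as.integer(round(stats::rnorm(n_particles,
                                                  standard$nominal_sites,
                                                  standard$sites_sd))))
  labeled <- stats::rbinom(n_particles, sites, standard$reference_ele)
  emitters <- tibble::tibble(x_nm = x, y_nm = y,
                             brightness = labeled * params$dye_brightness)
  field <- apply_noise(render_field(emitters, p), p)
  truth <- tibble::tibble(particle = seq_len(n_particles),
                          x_nm = x, y_nm = y, sites = sites,
                          labeled = labeled,
                          brightness = labeled * params$dye_brightness)
  attr(truth, "seed") <- params$seed
  log_stage("simulate_calibration_field", particles = n_particles)
  list(field = field, truth = truth, params = p)
}

#' Simulate a cluster/marker channel pair for colocalization tests
#'
#' The marker channel contains soft-edged disk blobs (radius
#' `blob_radius_nm`) placed without overlap until their summed area reaches
#' the requested foreground fraction; a fraction `coupling` of the clusters
#' is centered inside randomly chosen blobs, the rest is placed
#' independently of the marker.
#'
#' @param params A [sim_params()].
#' @param marker_area_fraction Target foreground area fraction of the true
#'   blob disks, achieved within +/-10% (0 gives an empty marker).
#' @param coupling Fraction of clusters centered inside blobs, in [0, 1].
#' @param blob_radius_nm Marker blob radius (default 250 nm).
#' @param marker_amplitude Peak marker intensity above background.
#' @return List with `cluster_field`, `marker_field` ([image_field()]s),
#'   `truth` (list: `clusters` tibble with `coupled` flag, `blobs` tibble)
#'   and `params`.
#' @export
simulate_coloc_pair <- function(params, marker_area_fraction,
                                coupling = 0, blob_radius_nm = 250,
                                marker_amplitude = 60) {
  stopifnot(inherits(params, "sim_params"),
            marker_area_fraction >= 0, marker_area_fraction < 1,
            coupling >= 0, coupling <= 1)
  set.seed(params$seed)
  n_px <- field_npx(params)
  field_nm <- n_px * params$pixel_nm
  area_um2 <- (field_nm / 1000)^2
  blob_area_um2 <- pi * (blob_radius_nm / 1000)^2
  n_blobs <- round(marker_area_fraction * area_um2 / blob_area_um2)
  if (marker_area_fraction > 0 && n_blobs == 0L) n_blobs <- 1L
  if (n_blobs * blob_area_um2 > 0.5 * area_um2) {
    stop("infeasible marker area fraction for non-overlapping blobs",
         call. = FALSE)
  }
  # rejection placement of non-overlapping blobs, fully inside the field
  blobs <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(blobs) < n_blobs && tries < 20000L) {
    tries <- tries + 1L
    cand <- stats::runif(2, blob_radius_nm, field_nm - blob_radius_nm)
    if (nrow(blobs) == 0L ||
        min(sqrt(colSums((t(blobs) - cand)^2))) > 2 * blob_radius_nm) {
      blobs <- rbind(blobs, cand)
    }
  }
  if (nrow(blobs) < n_blobs) {
    stop("could not place the requested marker blobs", call. = FALSE)
  }

  # marker channel: soft-edged disks + background + noise
  marker <- matrix(params$background, n_px, n_px)
  edge_nm <- 50
  for (b in seq_len(nrow(blobs))) {
    ctr <- blobs[b, ]
    r_ext <- blob_radius_nm + 4 * edge_nm
    j0 <- max(1L, floor((ctr[1] - r_ext) / params$pixel_nm))
    j1 <- min(n_px, ceiling((ctr[1] + r_ext) / params$pixel_nm) + 1L)
    i0 <- max(1L, floor((ctr[2] - r_ext) / params$pixel_nm))
    i1 <- min(n_px, ceiling((ctr[2] + r_ext) / params$pixel_nm) + 1L)
    xs <- ((j0:j1) - 1) * params$pixel_nm
    ys <- ((i0:i1) - 1) * params$pixel_nm
    d <- sqrt(outer((ys - ctr[2])^2, (xs - ctr[1])^2, `+`))
    marker[i0:i1, j0:j1] <- marker[i0:i1, j0:j1] +
      marker_amplitude * stats::pnorm((blob_radius_nm - d) / edge_nm)
  }
  marker_field <- apply_noise(
    image_field(marker, pixel_size = params$pixel_nm, channel = "marker"),
    params)

  # cluster channel: coupled clusters centered inside blobs, the rest
  # independent of the marker
  n_cl <- stats::rpois(1L, params$cluster_density_per_um2 * area_um2)
  n_coupled <- round(coupling * n_cl)
  if (n_coupled > 0L && nrow(blobs) == 0L) {
    stop("cannot couple clusters to an empty marker", call. = FALSE)
  }
  coupled <- rep(c(TRUE, FALSE), c(n_coupled, n_cl - n_coupled))
  centers <- matrix(NA_real_, n_cl, 2)
  if (n_coupled > 0L) {
    host <- sample.int(nrow(blobs), n_coupled, replace = TRUE)
    inside <- disk_points(n_coupled, 0, 0, 0.8 * blob_radius_nm)
    centers[coupled, ] <- blobs[host, , drop = FALSE] + inside
  }
  n_free <- n_cl - n_coupled
  if (n_free > 0L) {
    centers[!coupled, ] <- cbind(stats::runif(n_free, 0, field_nm),
                                 stats::runif(n_free, 0, field_nm))
  }
  n_true <- draw_counts(n_cl, params)
  n_labeled <- stats::rbinom(n_cl, n_true, params$labeling_ele)
  emitters <- purrr::map_dfr(seq_len(n_cl), function(i) {
    if (n_labeled[i] == 0L) return(NULL)
    xy <- disk_points(n_labeled[i], centers[i, 1], centers[i, 2],
                      params$cluster_diameter_nm / 2)
    tibble::tibble(cluster = i, x_nm = xy[, 1], y_nm = xy[, 2],
                   brightness = params$dye_brightness)
  })
  cluster_field <- apply_noise(render_field(emitters, params), params)
  truth <- list(
    clusters = tibble::tibble(cluster = seq_len(n_cl),
                              x_nm = centers[, 1], y_nm = centers[, 2],
                              n_true = n_true, n_labeled = n_labeled,
                              coupled = coupled),
    blobs = tibble::tibble(blob = seq_len(nrow(blobs)),
                           x_nm = blobs[, 1], y_nm = blobs[, 2],
                           radius_nm = blob_radius_nm))
  attr(truth$clusters, "field_area_um2") <- area_um2
  attr(truth$blobs, "area_fraction") <-
    nrow(blobs) * blob_area_um2 / area_um2
  log_stage("simulate_coloc_pair", clusters = n_cl, blobs = nrow(blobs))
  list(cluster_field = cluster_field, marker_field = marker_field,
       truth = truth, params = params)
}

#' Render emitters with line-scan motion blur
#'
#' Emulates the effect of lateral cluster diffusion during a raster scan:
#' every emitter performs an independent 2-D Brownian step of per-axis
#' variance `2 * D * line_time` between consecutive scan lines, and each
#' image row is rendered from the emitter positions current when that line
#' is scanned. With a diffusion coefficient of zero the output reproduces
#' the static render exactly.
#'
#' @param emitters Tibble with `x_nm`, `y_nm`, `brightness`.
#' @param params A [sim_params()] with `motion = list(diffusion_um2_s,
#'   line_time_s)`.
#' @return A noise-free [image_field()] (background included).
#' @export
apply_scan_motion <- function(emitters, params) {
  stopifnot(inherits(params, "sim_params"), !is.null(params$motion))
  n_px <- field_npx(params)
  sigma <- psf_sigma_nm(params)
  d_nm2_s <- params$motion$diffusion_um2_s * 1e6
  step_sd <- sqrt(2 * d_nm2_s * params$motion$line_time_s)
  n_e <- nrow(emitters)
  img <- matrix(params$background, n_px, n_px)
  x <- emitters$x_nm
  y <- emitters$y_nm
  b <- emitters$brightness
  for (r in seq_len(n_px)) {
    if (r > 1L && n_e > 0L) {
      x <- x + stats::rnorm(n_e) * step_sd
      y <- y + stats::rnorm(n_e) * step_sd
    }
    for (e in seq_len(n_e)) {
      wy <- axis_weights(y[e], sigma, params$pixel_nm, n_px)
      if (is.null(wy) || r < wy$idx[1] || r > wy$idx[length(wy$idx)]) next
      wx <- axis_weights(x[e], sigma, params$pixel_nm, n_px)
      if (is.null(wx)) next
      img[r, wx$idx] <- img[r, wx$idx] +
        b[e] * (wy$w[r - wy$idx[1] + 1L] * wx$w)
  }
  }
  image_field(img, pixel_size = params$pixel_nm, channel = "simulated")
}
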