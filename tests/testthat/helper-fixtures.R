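# Fixtures and independent oracles used across the suite. Everything is
# generated in code; no binary fixtures on disk.

# Gaussian spot sampled at pixel centres (not pixel-integrated): the
# analytic half-max isocontour of this raster is the disk of radius
# 1.1774 * sigma around the centre.
gaussian_spot <- function(dim = 64L, center = c(32, 32), sigma = 2.5,
                          amplitude = 100, pixel_size = 25,
                          baseline = 0) {
  r2 <- outer((seq_len(dim) - center[1])^2,
              (seq_len(dim) - center[2])^2, `+`)
  image_field(amplitude * exp(-r2 / (2 * sigma^2)) + baseline,
              pixel_size = pixel_size, allow_negative = TRUE)
}

# exhaustive 8-neighbourhood local-maximum search (plateau-free inputs)
oracle_local_maxima <- function(m, min_height = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- NULL
  for (r in 2:(h - 1)) {
    for (cl in 2:(w - 1)) {
      nb <- m[(r - 1):(r + 1), (cl - 1):(cl + 1)]
      if (m[r, cl] >= min_height && m[r, cl] == max(nb) &&
          sum(nb == m[r, cl]) == 1L) {
        out <- rbind(out, c(r, cl))
      }
    }
  }
  out
}

# ideal discrete-Fourier mask bandpass: keep components with period
# (px/cycle) strictly inside [low, high], zero everything else incl. DC
oracle_mask_bandpass <- function(m, low, high) {
  h <- nrow(m); w <- ncol(m)
  fr <- c(0, seq_len(h - 1)) / h
  fr[fr > 0.5] <- fr[fr > 0.5] - 1
  fc <- c(0, seq_len(w - 1)) / w
  fc[fc > 0.5] <- fc[fc > 0.5] - 1
  f <- sqrt(outer(fr^2, fc^2, `+`))
  keep <- f >= 1 / high & f <= 1 / low
  Re(stats::fft(stats::fft(m) * keep, inverse = TRUE)) / (h * w)
}

# brute-force ring pixel enumeration: centres within (inner, outer] of any
# region pixel centre, excluding the region itself
oracle_ring_pixels <- function(px, inner, outer, h, w) {
  out <- NULL
  in_roi <- matrix(FALSE, h, w)
  in_roi[(px[, 2] - 1L) * h + px[, 1]] <- TRUE
  for (r in seq_len(h)) {
    for (cl in seq_len(w)) {
      if (in_roi[r, cl]) next
      d <- sqrt(min((px[, 1] - r)^2 + (px[, 2] - cl)^2))
      if (d <= outer && d > inner) out <- rbind(out, c(r, cl))
    }
  }
  out
}

# one-row region tibble from an explicit pixel set
make_roi <- function(pixels, label = 1L, peak = pixels[1, ]) {
  tibble::tibble(label = label,
                 peak_row = peak[1], peak_col = peak[2],
                 height = NA_real_,
                 area_px = nrow(pixels),
                 pixels = list(cbind(row = pixels[, 1], col = pixels[, 2])))
}

# soft-edged disk markers for binarization tests
disk_marker_image <- function(dim = 200L, centers, radius_px = 10,
                              amplitude = 60, background = 5,
                              pixel_size = 25) {
  m <- matrix(background, dim, dim)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt(outer((seq_len(dim) - centers[i, 1])^2,
                    (seq_len(dim) - centers[i, 2])^2, `+`))
    m <- m + amplitude * stats::pnorm((radius_px - d) / 1.5)
  }
  image_field(m, pixel_size = pixel_size)
}

# minimal cluster-record tibble for reporting tests
make_records <- function(counts, area_um2 = 0.01, frame = "f1",
                         pixel_size_nm = 25) {
  n <- length(counts)
  tibble::tibble(frame = frame, label = seq_len(n),
                 centroid_x_um = stats::runif(n, 0, 10),
                 centroid_y_um = stats::runif(n, 0, 10),
                 area_px = area_um2 / (pixel_size_nm / 1000)^2,
                 area_um2 = area_um2,
                 diameter_nm = 2 * sqrt(area_um2 / pi) * 1000,
                 roundness = 0.9, background = 5,
                 brightness = counts * 100, counts = counts,
                 density_per_um2 = counts / area_um2,
                 pixel_size_nm = pixel_size_nm)
}
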