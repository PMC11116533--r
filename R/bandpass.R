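#' Structure-size bandpass filter
#'
#' Frequency-domain bandpass applied before spot segmentation and marker
#' binarization: removes the unstructured background (including the constant
#' component, exactly) and high-frequency noise, keeping structures with
#' sizes between `low_px` and `high_px` pixels.
#'
#' The transfer function is a difference of two isotropic Gaussians,
#' `H(f) = 2^-(low_px * f)^2 - 2^-(high_px * f)^2` with `f` the radial
#' frequency in cycles/px, so each cutoff size is the half-amplitude point
#' of its Gaussian edge. A sinusoid with period comfortably inside the band
#' passes with gain close to 1 (gain 0.92 at period 8 px for the default
#' 2.5--20 band) while periods beyond twice the upper cutoff or below the
#' lower cutoff are strongly attenuated; gains near the cutoffs themselves
#' are intermediate, as for any smooth filter. The image is mirror-padded to
#' twice its size before the FFT to suppress wrap-around artefacts, at the
#' cost of exact shift covariance within a few pixels of the border.
#'
#' @param image An [image_field()].
#' @param low_px Smallest retained structure size, in pixels (may be
#'   non-integer, e.g. 2.5).
#' @param high_px Largest retained structure size, in pixels; must be less
#'   than half the smaller raster dimension.
#' @return An [image_field()] of the same shape; values may be negative
#'   (the output is zero-mean by construction).
#' @examples
#' img <- image_field(matrix(500, 64, 64), pixel_size = 25)
#' filt <- bandpass(img)           # constant image -> all (numerically) zero
#' max(abs(filt))
#' @export
bandpass <- function(image, low_px = 2.5, high_px = 20) {
  stopifnot(inherits(image, "image_field"))
  if (!(low_px > 0 && low_px < high_px)) {
    stop("need 0 < low_px < high_px", call. = FALSE)
  }
  m <- field_matrix(image)
  h <- nrow(m); w <- ncol(m)
  if (high_px >= min(h, w) / 2) {
    stop("band wider than the raster supports: high_px must be below ",
         "min(dim)/2 = ", min(h, w) / 2, call. = FALSE)
  }
  # mirror (even) extension to 2h x 2w: continuous across the seams
  pad <- rbind(cbind(m, m[, w:1, drop = FALSE]),
               cbind(m[h:1, , drop = FALSE], m[h:1, w:1, drop = FALSE]))
  H <- bandpass_transfer(2L * h, 2L * w, low_px, high_px)
  out <- Re(stats::fft(stats::fft(pad) * H, inverse = TRUE)) / (4 * h * w)
  image_field(out[seq_len(h), seq_len(w), drop = FALSE],
              pixel_size = pixel_size(image),
              channel = attr(image, "channel"),
              frame = attr(image, "frame"),
              allow_negative = TRUE)
}

# Gaussian-difference transfer function on the (nr x nc) FFT grid.
# Gain of the size-s Gaussian at period p is exactly 2^-(s/p)^2, i.e. the
# cutoff size is the half-amplitude point.
bandpass_transfer <- function(nr, nc, low_px, high_px) {
  fr <- fft_freq(nr)
  fc <- fft_freq(nc)
  f2 <- outer(fr^2, fc^2, `+`)
  2^(-(low_px^2) * f2) - 2^(-(high_px^2) * f2)
}

# frequencies in cycles/pixel for an n-point DFT
fft_freq <- function(n) {
  k <- seq_len(n) - 1L
  k[k > n %/% 2] <- k[k > n %/% 2] - n
  k / n
}
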