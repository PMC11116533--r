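#' Binarize an endosomal-marker image
#'
#' Bandpass-filters the marker channel (default 4--30 px structure sizes)
#' and thresholds the filtered histogram with one of the named automated
#' methods: `"triangle"`, `"li"` (minimum cross entropy) or
#' `"mean_of_background"` (mean + k * sd of the pixels outside the detected
#' foreground, iterated once; `k` defaults to 2). A raster whose filtered
#' dynamic range is numerically nil falls back to thresholding the raw
#' image at half its maximum, so a blank frame yields an empty mask and a
#' uniformly bright frame a full one.
#'
#' @param image Marker [image_field()] (confocal channel).
#' @param band Length-2 bandpass sizes in px.
#' @param method Threshold method name.
#' @param k Multiplier for `"mean_of_background"`.
#' @return A `binary_map`: logical mask matrix with attributes
#'   `area_fraction`, `n_spots` (connected components, 8-connected),
#'   `method`, `threshold` and `pixel_size`.
#' @export
binarize_marker <- function(image, band = c(4, 30),
                            method = c("triangle", "li",
                                       "mean_of_background"),
                            k = 2) {
  method <- match.arg(method)
  stopifnot(inherits(image, "image_field"))
  filt <- field_matrix(bandpass(image, band[1], band[2]))
  raw <- field_matrix(image)
  rng <- diff(range(filt))
  if (rng <= 1e-8 * max(1, mean(abs(raw)))) {
    mask <- raw > max(raw) / 2          # degenerate: flat after filtering
    thr <- max(raw) / 2
  } else {
    thr <- switch(method,
                  triangle = threshold_triangle(filt),
                  li = threshold_li(filt),
                  mean_of_background = threshold_mean_background(filt, k))
    mask <- filt > thr
  }
  n_spots <- if (any(mask)) max(EBImage::bwlabel(mask)) else 0L
  structure(mask,
            area_fraction = mean(mask),
            n_spots = as.integer(n_spots),
            method = method,
            threshold = thr,
            pixel_size = pixel_size(image),
            class = c("binary_map", "matrix", "array"))
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map> %d x %d px, %s threshold, area fraction %.3f, %d spots\n",
              nrow(x), ncol(x), attr(x, "method"),
              attr(x, "area_fraction"), attr(x, "n_spots")))
  invisible(x)
}

# Triangle threshold (Zack): maximize the distance between the histogram
# and the line joining its peak to the far end of the longer tail.
threshold_triangle <- function(v, n_bins = 256L) {
  h <- graphics::hist(v, breaks = seq(min(v), max(v),
                                      length.out = n_bins + 1L),
                      plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  peak <- which.max(counts)
  nz <- which(counts > 0)
  lo <- min(nz); hi <- max(nz)
  # flip so that the longer tail lies to the right of the peak
  flipped <- (peak - lo) > (hi - peak)
  if (flipped) counts <- rev(counts)
  peak <- which.max(counts)
  end <- max(which(counts > 0))
  if (end <= peak) return(mids[if (flipped) n_bins + 1L - peak else peak])
  idx <- peak:end
  # distance from (i, counts[i]) to the chord (peak, cmax) -- (end, 0)
  dx <- end - peak; dy <- 0 - counts[peak]
  d <- abs(dy * (idx - peak) - dx * (counts[idx] - counts[peak]))
  split <- idx[which.max(d)]
  if (flipped) split <- n_bins + 1L - split
  mids[split]
}

# Li & Lee minimum cross entropy threshold, iterated to a fixed point on
# values shifted to be positive.
threshold_li <- function(v, tol = 1e-6, max_iter = 200L) {
  shift <- min(v)
  x <- v - shift + 1e-9 * max(1, diff(range(v)))
  t_cur <- mean(x)
  for (i in seq_len(max_iter)) {
    fg <- x > t_cur
    if (!any(fg) || all(fg)) break
    m_b <- mean(x[!fg]); m_f <- mean(x[fg])
    t_new <- if (m_b <= 0 || abs(log(m_f) - log(m_b)) < 1e-12) {
      (m_b + m_f) / 2
    } else {
      (m_f - m_b) / (log(m_f) - log(m_b))
    }
    if (abs(t_new - t_cur) < tol * max(1, t_cur)) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  t_cur + shift - 1e-9 * max(1, diff(range(v)))
}

# mean + k * sd of background pixels; background re-estimated once after an
# initial whole-image pass.
threshold_mean_background <- function(v, k = 2) {
  t0 <- mean(v) + k * stats::sd(v)
  bg <- v[v < t0]
  if (length(bg) < 2L) return(t0)
  mean(bg) + k * stats::sd(bg)
}

#' Object-based colocalization with random-overlap correction
#'
#' A cluster colocalizes when at least half of its pixels (by default; see
#' `min_overlap`) lie on marker foreground. The specific
#' fraction subtracts the marker's foreground area fraction, which
#' approximates the probability of random overlap; negative values are
#' reported unclamped and flagged.
#'
#' @param clusters Region tibble (from [segment_clusters()]).
#' @param endo A `binary_map` from [binarize_marker()], same raster
#'   geometry as the cluster image.
#' @param marker_label Free-text label stored in the result.
#' @param min_overlap Minimum fraction of cluster pixels on foreground
#'   required to call an overlap. The default 0.5 (majority of the
#'   cluster's pixels) keeps the area-fraction correction unbiased: an
#'   extended spot touches foreground with probability above the area
#'   fraction, so any-pixel overlap (`min_overlap = 0`, also available)
#'   over-counts random colocalization for objects larger than a point.
#' @return One-row tibble: `marker_label`, `n_clusters`, `n_overlapping`,
#'   `raw_fraction`, `area_fraction`, `specific_fraction`,
#'   `negative_specific` flag.
#' @export
coloc_fraction <- function(clusters, endo, marker_label = "",
                           min_overlap = 0.5) {
  stopifnot(inherits(endo, "binary_map"))
  if (nrow(clusters) == 0L) stop("zero clusters", call. = FALSE)
  mask <- unclass(endo)
  h <- nrow(mask)
  overlap <- vapply(clusters$pixels, function(px) {
    if (max(px[, 1]) > h || max(px[, 2]) > ncol(mask)) {
      stop("cluster regions exceed the marker raster: geometry mismatch",
           call. = FALSE)
    }
    frac <- mean(mask[(px[, 2] - 1L) * h + px[, 1]])
    if (min_overlap > 0) frac >= min_overlap else frac > 0
  }, logical(1))
  raw_fraction <- mean(overlap)
  af <- attr(endo, "area_fraction")
  specific <- raw_fraction - af
  if (specific < 0) {
    warning("specific colocalization is negative (raw fraction below the ",
            "random-overlap estimate)", call. = FALSE)
  }
  tibble::tibble(marker_label = marker_label,
                 n_clusters = nrow(clusters),
                 n_overlapping = sum(overlap),
                 raw_fraction = raw_fraction,
                 area_fraction = af,
                 specific_fraction = specific,
                 negative_specific = specific < 0)
}

#' Density of marker spots
#'
#' Connected foreground components per analyzed area.
#'
#' @param map A `binary_map`.
#' @param analyzed_area_um2 Analyzed area in square micrometres (> 0).
#' @return Spots per square micrometre.
#' @export
spot_density <- function(map, analyzed_area_um2) {
  stopifnot(inherits(map, "binary_map"))
  if (analyzed_area_um2 <= 0) stop("area must be positive", call. = FALSE)
  attr(map, "n_spots") / analyzed_area_um2
}
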