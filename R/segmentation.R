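#' Detect candidate spot maxima in a filtered image
#'
#' Finds all local maxima of the bandpass-filtered raster (8-neighbourhood;
#' plateaus are merged to one representative, the member with the lowest
#' `(row, col)`) and computes each maximum's topographic prominence: the
#' height difference to the saddle at which its peak merges with a higher
#' peak (peaks that never merge are measured down to `floor`). Only maxima
#' with prominence at or above `min_prominence` are returned.
#'
#' The default threshold is 4x the robust noise scale of the filtered
#' image (1.4826 x median absolute deviation), a reproducible stand-in for
#' the interactive thresholds of GUI spot pickers. The multiplier is set
#' so that the expected number of false noise maxima clearing it is well
#' below one per typical field; see the methods vignette for the false
#' discovery argument.
#'
#' @param filtered An [image_field()], normally the output of [bandpass()].
#' @param min_prominence Non-negative prominence cutoff; `NULL` for the
#'   robust default.
#' @param floor Reference level for the prominence of never-merged peaks
#'   and lower bound of the flooding; 0 by default because the filtered
#'   image is zero-mean.
#' @return Tibble with one row per accepted peak, columns `row`, `col`
#'   (1-based pixel indices), `height` and `prominence`, sorted by
#'   descending height.
#' @export
detect_maxima <- function(filtered, min_prominence = NULL, floor = 0) {
  stopifnot(inherits(filtered, "image_field"))
  v <- field_matrix(filtered)
  if (is.null(min_prominence)) min_prominence <- 4 * stats::mad(v)
  if (min_prominence < 0) stop("min_prominence must be >= 0", call. = FALSE)
  h <- nrow(v); w <- ncol(v)
  inc <- which(v > floor)
  empty <- tibble::tibble(row = integer(0), col = integer(0),
                          height = numeric(0), prominence = numeric(0))
  if (length(inc) == 0L) return(empty)

  rr <- ((inc - 1L) %% h) + 1L
  cc <- ((inc - 1L) %/% h) + 1L
  ord <- order(-v[inc], (rr - 1L) * w + cc)   # desc value, row-major ties
  inc <- inc[ord]; rr <- rr[ord]; cc <- cc[ord]

  comp <- integer(h * w)              # pixel -> component id (0 = unseen)
  parent <- integer(0)                # union-find over components
  peak_px <- integer(0)               # component -> peak pixel
  peak_val <- numeric(0)
  prom <- numeric(0)                  # assigned when a peak dies (merges)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  for (k in seq_along(inc)) {
    p <- inc[k]; r <- rr[k]; cl <- cc[k]
    vp <- v[p]
    roots <- integer(0)
    for (dr in -1:1) {
      nr <- r + dr
      if (nr < 1L || nr > h) next
      for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        nc <- cl + dc
        if (nc < 1L || nc > w) next
        cq <- comp[p + dr + dc * h]
        if (cq > 0L) roots <- c(roots, find(cq))
      }
    }
    roots <- unique(roots)
    if (length(roots) == 0L) {
      id <- length(parent) + 1L
      parent[id] <- id
      peak_px[id] <- p
      peak_val[id] <- vp
      prom[id] <- NA_real_
      comp[p] <- id
    } else if (length(roots) == 1L) {
      comp[p] <- roots
    } else {
      # the component with the highest peak survives; ties by the peak's
      # lower row-major position (deterministic)
      key <- order(-peak_val[roots],
                   ((peak_px[roots] - 1L) %% h) * w +
                     ((peak_px[roots] - 1L) %/% h))
      roots <- roots[key]
      win <- roots[1L]
      for (lose in roots[-1L]) {
        prom[lose] <- peak_val[lose] - vp   # saddle = current pixel
        parent[lose] <- win
      }
      comp[p] <- win
    }
  }

  alive <- which(parent == seq_along(parent))
  prom[alive] <- peak_val[alive] - floor
  keep <- which(prom >= min_prominence)
  if (length(keep) == 0L) return(empty)
  px <- peak_px[keep]
  out <- tibble::tibble(row = ((px - 1L) %% h) + 1L,
                        col = ((px - 1L) %/% h) + 1L,
                        height = peak_val[keep],
                        prominence = prom[keep])
  out <- out[order(-out$height, (out$row - 1L) * w + out$col), ]
  log_stage("detect_maxima", n = nrow(out))
  out
}

#' Expand peaks to their half-maximum regions
#'
#' Each peak grows into the 4-connected set of pixels reachable from it with
#' filtered value at or above `floor + (height - floor) / 2` (the FWHM
#' criterion). Pixels claimable by more than one peak are assigned by a
#' watershed-style descent: pixels are visited in order of decreasing value
#' and join the region of their steepest already-labeled 4-neighbour whose
#' threshold they satisfy, so the dividing line between competing peaks
#' follows the intensity valley. Regions are mutually disjoint.
#'
#' @param filtered The [image_field()] the peaks were detected on.
#' @param peaks Tibble from [detect_maxima()].
#' @param floor Reference level of the half-maximum criterion (default 0 on
#'   the zero-mean filtered raster).
#' @return Tibble with one row per region: `label`, `peak_row`, `peak_col`,
#'   `height`, `area_px` and a `pixels` list-column of 2-column `(row, col)`
#'   index matrices.
#' @export
expand_to_half_max <- function(filtered, peaks, floor = 0) {
  stopifnot(inherits(filtered, "image_field"))
  v <- field_matrix(filtered)
  h <- nrow(v); w <- ncol(v)
  n <- nrow(peaks)
  if (n == 0L) {
    return(tibble::tibble(label = integer(0), peak_row = integer(0),
                          peak_col = integer(0), height = numeric(0),
                          area_px = integer(0), pixels = list()))
  }
  pk <- (peaks$col - 1L) * h + peaks$row
  if (anyDuplicated(pk)) stop("duplicate peak positions", call. = FALSE)
  # every peak must be a local maximum of this raster
  for (i in seq_len(n)) {
    r <- peaks$row[i]; cl <- peaks$col[i]
    nb <- v[max(1L, r - 1L):min(h, r + 1L), max(1L, cl - 1L):min(w, cl + 1L)]
    if (v[r, cl] < max(nb)) {
      stop("peak ", i, " at (", r, ",", cl,
           ") is not a local maximum of the given raster", call. = FALSE)
    }
  }
  thr <- floor + (v[pk] - floor) / 2
  lab <- matrix(0L, h, w)
  lab[pk] <- seq_len(n)

  cand <- which(v >= min(thr) & lab == 0L)
  if (length(cand) > 0L) {
    rr <- ((cand - 1L) %% h) + 1L
    cc <- ((cand - 1L) %/% h) + 1L
    ord <- order(-v[cand], (rr - 1L) * w + cc)
    cand <- cand[ord]; rr <- rr[ord]; cc <- cc[ord]
    for (k in seq_along(cand)) {
      p <- cand[k]; r <- rr[k]; cl <- cc[k]
      vp <- v[p]
      best <- 0L; best_v <- -Inf
      if (r > 1L) { q <- p - 1L
        if (lab[q] > 0L && vp >= thr[lab[q]] && v[q] > best_v) {
          best <- q; best_v <- v[q] } }
      if (r < h) { q <- p + 1L
        if (lab[q] > 0L && vp >= thr[lab[q]] && v[q] > best_v) {
          best <- q; best_v <- v[q] } }
      if (cl > 1L) { q <- p - h
        if (lab[q] > 0L && vp >= thr[lab[q]] && v[q] > best_v) {
          best <- q; best_v <- v[q] } }
      if (cl < w) { q <- p + h
        if (lab[q] > 0L && vp >= thr[lab[q]] && v[q] > best_v) {
          best <- q; best_v <- v[q] } }
      if (best > 0L) lab[p] <- lab[best]
    }
    # pixels reachable only through lower-valued neighbours (non-monotone
    # paths): sweep until stable
    repeat {
      assigned <- relax_labels(v, lab, thr)
      if (assigned == 0L) break
    }
  }

  pixels <- split_label_pixels(lab, n)
  out <- tibble::tibble(label = seq_len(n),
                        peak_row = peaks$row, peak_col = peaks$col,
                        height = v[pk],
                        area_px = vapply(pixels, nrow, integer(1)),
                        pixels = pixels)
  log_stage("expand_to_half_max", n = nrow(out),
            px = sum(out$area_px))
  out
}

# one vectorized relaxation sweep: label unassigned above-threshold pixels
# adjacent (4-conn) to a labeled pixel; steepest labeled neighbour wins.
# Modifies `lab` in the caller via returned environment trick is avoided:
# operates on matrices by reference semantics through parent.frame().
relax_labels <- function(v, lab, thr) {
  h <- nrow(v); w <- ncol(v)
  best_val <- matrix(-Inf, h, w)
  best_lab <- matrix(0L, h, w)
  consider <- function(rows, cols, nrows, ncols) {
    # candidate target pixels [rows, cols]; neighbour at [nrows, ncols]
    l <- lab[nrows, ncols, drop = FALSE]
    ok <- l > 0L & lab[rows, cols, drop = FALSE] == 0L
    if (!any(ok)) return()
    vv <- v[nrows, ncols, drop = FALSE]
    tt <- matrix(0, nrow(l), ncol(l)); tt[ok] <- thr[l[ok]]
    ok <- ok & v[rows, cols, drop = FALSE] >= tt
    upd <- ok & vv > best_val[rows, cols, drop = FALSE]
    if (!any(upd)) return()
    bv <- best_val[rows, cols, drop = FALSE]
    bl <- best_lab[rows, cols, drop = FALSE]
    bv[upd] <- vv[upd]; bl[upd] <- l[upd]
    best_val[rows, cols] <<- bv
    best_lab[rows, cols] <<- bl
  }
  consider(2:h, 1:w, 1:(h - 1L), 1:w)      # neighbour above
  consider(1:(h - 1L), 1:w, 2:h, 1:w)      # below
  consider(1:h, 2:w, 1:h, 1:(w - 1L))      # left
  consider(1:h, 1:(w - 1L), 1:h, 2:w)      # right
  newly <- which(best_lab > 0L)
  if (length(newly) > 0L) {
    lab[newly] <- best_lab[newly]
    # write back into the caller's `lab`
    assign("lab", lab, envir = parent.frame())
  }
  length(newly)
}

split_label_pixels <- function(lab, n) {
  h <- nrow(lab)
  idx <- which(lab > 0L)
  lapply(seq_len(n), function(k) {
    p <- idx[lab[idx] == k]
    cbind(row = ((p - 1L) %% h) + 1L, col = ((p - 1L) %/% h) + 1L)
  })
}

# integer label matrix from a region tibble
label_matrix <- function(rois, dim_hw) {
  lab <- matrix(0L, dim_hw[1], dim_hw[2])
  for (i in seq_len(nrow(rois))) {
    px <- rois$pixels[[i]]
    lab[(px[, 2] - 1L) * dim_hw[1] + px[, 1]] <- rois$label[i]
  }
  lab
}

#' Apply the candidate filters to segmented regions
#'
#' Regions are discarded if they contain fewer than `min_px` pixels or if
#' their mean raw intensity is less than `100 * min_contrast` percent above
#' the local background (defaults: 5 px and 50%). Both criteria are
#' evaluated on the raw (unfiltered) image; backgrounds come from
#' [ring_background()].
#'
#' @param rois Region tibble from [expand_to_half_max()].
#' @param raw The raw [image_field()].
#' @param backgrounds Numeric vector, one local background per region.
#' @param min_px Minimum pixel count (kept when `area_px >= min_px`).
#' @param min_contrast Minimum relative contrast (kept when mean raw
#'   intensity `>= (1 + min_contrast) * background`).
#' @return The filtered region tibble (input order preserved) with a
#'   `background` column appended.
#' @export
filter_candidates <- function(rois, raw, backgrounds, min_px = 5L,
                              min_contrast = 0.5) {
  stopifnot(inherits(raw, "image_field"))
  if (length(backgrounds) != nrow(rois) || anyNA(backgrounds)) {
    stop("need one finite background per region", call. = FALSE)
  }
  if (nrow(rois) == 0L) {
    return(dplyr::mutate(rois, background = numeric(0)))
  }
  m <- field_matrix(raw)
  h <- nrow(m)
  mean_raw <- vapply(rois$pixels, function(px) {
    mean(m[(px[, 2] - 1L) * h + px[, 1]])
  }, numeric(1))
  keep <- rois$area_px >= min_px &
    mean_raw >= (1 + min_contrast) * backgrounds
  out <- dplyr::mutate(rois, background = backgrounds)[keep, ]
  log_stage("filter_candidates", kept = nrow(out), dropped = sum(!keep))
  out
}

#' Segment clusters in a raw STED image
#'
#' The full detection pipeline: bandpass filter, prominence-thresholded
#' maxima detection, half-maximum region growth, ring-background estimation
#' and the size/contrast candidate filters. Regions whose background ring
#' is unusable (clipped below 8 px at the image border) are dropped.
#'
#' @param raw Raw [image_field()].
#' @param config An [analysis_config()].
#' @return Region tibble as from [filter_candidates()], with relabeled
#'   consecutive `label`s and the filtered image attached as attribute
#'   `"filtered"`.
#' @export
segment_clusters <- function(raw, config = analysis_config()) {
  filt <- bandpass(raw, config$band_low_px, config$band_high_px)
  peaks <- detect_maxima(filt, config$min_prominence)
  rois <- expand_to_half_max(filt, peaks)
  if (nrow(rois) > 0L) {
    lab <- label_matrix(rois, dim(field_matrix(raw)))
    bg <- vapply(seq_len(nrow(rois)), function(i) {
      ring_background(raw, rois[i, ], lab,
                      inner_px = config$ring_inner_px,
                      outer_px = config$ring_outer_px, strict = FALSE)
    }, numeric(1))
    usable <- !is.na(bg)
    rois <- filter_candidates(rois[usable, ], raw, bg[usable],
                              min_px = config$min_roi_px,
                              min_contrast = config$min_contrast)
  } else {
    rois <- dplyr::mutate(rois, background = numeric(0))
  }
  rois$label <- seq_len(nrow(rois))
  attr(rois, "filtered") <- filt
  log_stage("segment_clusters", n = nrow(rois))
  rois
}
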