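#' Construct an image field
#'
#' An `image_field` is the unit of acquisition in this package: a 2-D raster
#' of photon counts (or arbitrary linear brightness units) together with the
#' physical pixel size. All geometric quantities downstream (areas, diameters,
#' densities, distances) are derived from `pixel_size`.
#'
#' Pixel coordinates are 0-based `(row, col)` with pixel centers at integer
#' coordinates, so the physical position of pixel `(r, c)` is
#' `(c * pixel_size, r * pixel_size)`.
#'
#' @param pixels Numeric matrix with at least 2 rows and 2 columns. Values
#'   must be finite, and non-negative unless `allow_negative = TRUE` (used
#'   for filtered rasters, which are zero-mean by construction).
#' @param pixel_size Physical edge length of one pixel, in nanometres.
#' @param channel Free-text channel label.
#' @param frame Free-text frame identifier.
#' @param allow_negative Permit negative pixel values (filtered images).
#'
#' @return An `image_field` object: the pixel matrix carrying `pixel_size`
#'   (nm), `channel` and `frame` attributes.
#' @examples
#' img <- image_field(matrix(5, 16, 16), pixel_size = 25)
#' pixel_size(img)
#' @export
image_field <- function(pixels, pixel_size, channel = "", frame = "",
                        allow_negative = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop("raster must have at least 2 rows and 2 columns", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("all pixel values must be finite", call. = FALSE)
  }
  if (!allow_negative && any(pixels < 0)) {
    stop("pixel values must be non-negative", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (nm)", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  structure(pixels,
            pixel_size = as.numeric(pixel_size),
            channel = as.character(channel),
            frame = as.character(frame),
            class = c("image_field", "matrix", "array"))
}

#' @rdname image_field
#' @param x An `image_field`.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size")
  if (is.null(ps)) stop("object carries no pixel size", call. = FALSE)
  ps
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf("<image_field> %d x %d px, %.4g nm/px", nrow(x), ncol(x),
              pixel_size(x)))
  ch <- attr(x, "channel"); fr <- attr(x, "frame")
  if (nzchar(ch)) cat(", channel:", ch)
  if (nzchar(fr)) cat(", frame:", fr)
  cat(sprintf("\n  range [%.4g, %.4g], mean %.4g\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

# strip class/attrs, keep the bare matrix
field_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "pixel_size") <- NULL
  attr(y, "channel") <- NULL
  attr(y, "frame") <- NULL
  y
}

#' Read a single-plane TIFF as an image field
#'
#' Accepts 8/16-bit unsigned and 32-bit float grayscale TIFF, promoted
#' internally to a real-valued raster (integer files keep their integer
#' values; no rescaling is applied). The pixel size is taken from the
#' embedded X/Y resolution tags when present (inch or cm units), otherwise
#' from `pixel_size`; it is an error if neither is available.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size Fallback pixel size in nm, used only when the file has
#'   no resolution metadata.
#' @param channel,frame Labels attached to the result; `frame` defaults to
#'   the file name.
#' @return An [image_field()].
#' @export
read_image <- function(path, pixel_size = NULL, channel = "", frame = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  planes <- tryCatch(
    tiff::readTIFF(path, info = TRUE, as.is = TRUE, all = TRUE),
    error = function(e) {
      # float TIFFs refuse as.is; their values are returned unscaled anyway
      tiff::readTIFF(path, info = TRUE, all = TRUE)
    })
  if (length(planes) != 1L) {
    stop("multi-plane TIFF: ", length(planes),
         " planes found, expected a single plane per channel", call. = FALSE)
  }
  px <- planes[[1L]]
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] == 1L) {
      px <- px[, , 1L]
    } else {
      stop("multi-channel raster: expected single-channel 2-D input",
           call. = FALSE)
    }
  }
  ps <- tiff_pixel_size(attributes(planes[[1L]]))
  if (is.null(ps)) ps <- pixel_size
  if (is.null(ps)) {
    stop("missing pixel size: no resolution metadata in file and no ",
         "`pixel_size` given", call. = FALSE)
  }
  storage.mode(px) <- "double"
  image_field(px, pixel_size = ps, channel = channel,
              frame = frame %||% basename(path))
}

# pixel size (nm) from TIFF resolution tags; NULL when absent
tiff_pixel_size <- function(info) {
  xres <- info[["x.resolution"]]
  if (is.null(xres) || !is.finite(xres) || xres <= 0) return(NULL)
  unit <- info[["resolution.unit"]] %||% "inch"
  per_nm <- switch(unit,
                   cm = 1e7,
                   inch = 2.54e7,
                   return(NULL))
  # libtiff hands resolutions back in single precision; sub-0.0001 nm
  # pixel sizes are physically meaningless, so snap to that grid
  round(per_nm / xres, 4)
}

#' Write an image field to TIFF with pixel-size metadata
#'
#' Writes a single-strip uncompressed grayscale TIFF carrying X/Y resolution
#' tags (centimetre unit) so that [read_image()] round-trips the pixel size.
#' Integer-valued rasters up to 65535 are stored as 16-bit unsigned and
#' round-trip bit-exactly; anything else is stored as 32-bit float.
#'
#' @param image An [image_field()].
#' @param path Output path.
#' @param bits `"auto"` (default), `16` or `"float"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = "auto") {
  stopifnot(inherits(image, "image_field"))
  m <- field_matrix(image)
  is_int <- all(m == round(m)) && min(m) >= 0 && max(m) <= 65535
  if (identical(bits, "auto")) bits <- if (is_int) 16L else "float"
  if (identical(bits, 16L) || identical(bits, 16) || identical(bits, "16")) {
    if (!is_int) {
      stop("16-bit output requires integer values in [0, 65535]",
           call. = FALSE)
    }
    write_tiff_gray(m, path, pixel_size(image), format = "uint16")
  } else if (identical(bits, "float")) {
    write_tiff_gray(m, path, pixel_size(image), format = "float32")
  } else {
    stop("unsupported `bits`: ", bits, call. = FALSE)
  }
  invisible(path)
}

# Minimal little-endian TIFF writer: single strip, grayscale, uncompressed,
# with XResolution/YResolution/ResolutionUnit tags. Written by hand because
# the established writer offers neither resolution tags nor brightness
# values outside [0, 1].
write_tiff_gray <- function(m, path, pixel_size_nm, format = "uint16") {
  h <- nrow(m); w <- ncol(m)
  bps <- if (format == "uint16") 16L else 32L
  sample_format <- if (format == "uint16") 1L else 3L
  bytes_px <- bps %/% 8L
  n_entries <- 13L
  ifd_off <- 8L
  ifd_size <- 2L + n_entries * 12L + 4L
  rat_off <- ifd_off + ifd_size           # two RATIONALs, 8 bytes each
  data_off <- rat_off + 16L
  n_bytes <- h * w * bytes_px

  # XResolution = pixels per cm = 1e7 / pixel_size_nm, stored as a rational
  # 1e9 / round(100 * pixel_size_nm): exact for pixel sizes with <= 2
  # decimals, otherwise accurate to < 1e-6 relative.
  rat_num <- 1e9
  rat_den <- round(100 * pixel_size_nm)

  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  u32 <- function(x) {
    x <- as.numeric(x)
    # writeBin has no unsigned type; split into two 16-bit halves
    u16(x %% 65536); u16(x %/% 65536)
  }
  entry <- function(tag, type, count, value) {
    u16(tag); u16(type); u32(count)
    if (type == 3L) { u16(value); u16(0L) } else u32(value)  # 3 = SHORT
  }
  writeBin(charToRaw("II"), con); u16(42L); u32(ifd_off)
  u16(n_entries)
  entry(256L, 4L, 1L, w)              # ImageWidth
  entry(257L, 4L, 1L, h)              # ImageLength
  entry(258L, 3L, 1L, bps)            # BitsPerSample
  entry(259L, 3L, 1L, 1L)             # Compression: none
  entry(262L, 3L, 1L, 1L)             # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_off)       # StripOffsets
  entry(277L, 3L, 1L, 1L)             # SamplesPerPixel
  entry(278L, 4L, 1L, h)              # RowsPerStrip
  entry(279L, 4L, 1L, n_bytes)        # StripByteCounts
  entry(282L, 5L, 1L, rat_off)        # XResolution
  entry(283L, 5L, 1L, rat_off + 8L)   # YResolution
  entry(296L, 3L, 1L, 3L)             # ResolutionUnit: cm
  entry(339L, 3L, 1L, sample_format)  # SampleFormat
  u32(0L)                             # next IFD: none
  u32(rat_num); u32(rat_den)          # XResolution value
  u32(rat_num); u32(rat_den)          # YResolution value
  v <- as.vector(t(m))                # TIFF strips are row-major
  if (format == "uint16") {
    v <- as.numeric(v)
    raw2 <- rbind(as.raw(v %% 256), as.raw(v %/% 256))
    writeBin(as.vector(raw2), con)
  } else {
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
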