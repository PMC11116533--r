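test_that("integer rasters round-trip bit-exactly with their pixel size", {
  set.seed(1)
  img <- image_field(matrix(sample(0:65535, 64 * 64, TRUE), 64, 64),
                     pixel_size = 30, frame = "f0")
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(img, path)
  back <- read_image(path)
  expect_identical(as.vector(unclass(back)), as.numeric(unclass(img)))
  expect_equal(pixel_size(back), 30)
})

test_that("embedded resolution metadata yields the pixel size", {
  img <- image_field(matrix(100, 32, 32), pixel_size = 30)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(img, path)
  # no override given: the pixel size must come from the file tags
  expect_equal(pixel_size(read_image(path)), 30)
  # the file really carries TIFF resolution tags readable by libtiff
  info <- attributes(tiff::readTIFF(path, info = TRUE)[])
  expect_equal(info$resolution.unit, "cm")
  expect_equal(1e7 / info$x.resolution, 30, tolerance = 1e-6)
})

test_that("a file without resolution metadata requires an explicit pixel size", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 16, 16), path)   # writes no resolution tags
  expect_error(read_image(path), "missing pixel size")
  expect_equal(pixel_size(read_image(path, pixel_size = 25)), 25)
})

test_that("float rasters and non-TIFF conditions are handled", {
  img <- image_field(matrix(runif(256) * 500, 16, 16), pixel_size = 25)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(img, path)                      # auto-selects float storage
  back <- read_image(path)
  expect_equal(as.vector(unclass(back)), as.vector(unclass(img)),
               tolerance = 1e-6)
  expect_error(read_image(withr::local_tempfile()), "not found")
  multi <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.1, 8, 8), matrix(0.2, 8, 8)), multi)
  expect_error(read_image(multi, pixel_size = 25), "multi-plane")
})

test_that("image_field enforces its invariants", {
  expect_error(image_field(matrix(1, 1, 5), 25), "at least 2")
  expect_error(image_field(matrix(-1, 4, 4), 25), "non-negative")
  expect_error(image_field(matrix(NA_real_, 4, 4), 25), "finite")
  expect_error(image_field(matrix(1, 4, 4), 0), "positive")
  expect_silent(image_field(matrix(-1, 4, 4), 25, allow_negative = TRUE))
})

test_that("cluster tables round-trip at full precision", {
  recs <- make_records(c(2.25, 8.5, 17.125))
  recs$brightness <- recs$brightness * pi    # non-terminating decimals
  path <- withr::local_tempfile(fileext = ".csv")
  write_cluster_table(recs, path)
  back <- read_cluster_table(path)
  expect_equal(as.data.frame(back), as.data.frame(recs))
})

test_that("empty and inconsistent cluster tables are handled", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cluster_table(make_records(numeric(0)), path)
  back <- read_cluster_table(path)
  expect_equal(nrow(back), 0L)
  expect_setequal(names(back), stedclust:::cluster_table_columns())

  mixed <- dplyr::bind_rows(make_records(5, pixel_size_nm = 25),
                            make_records(5, pixel_size_nm = 30))
  expect_error(write_cluster_table(mixed, path), "mix pixel sizes")
})

test_that("analysis configuration round-trips through YAML", {
  cfg <- analysis_config(band_low_px = 3, min_contrast = 0.4, seed = 9L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  expect_equal(read_config(path), cfg)
  expect_error(analysis_config(band_low_px = 30, band_high_px = 20))
  expect_error(analysis_config(ring_inner_px = 4, ring_outer_px = 2))
})
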