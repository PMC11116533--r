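test_that("a flat image yields no maxima", {
  img <- image_field(matrix(0, 32, 32), 25, allow_negative = TRUE)
  expect_equal(nrow(detect_maxima(img, min_prominence = 0)), 0L)
})

test_that("isolated spots are found once each, at their centres", {
  spot <- gaussian_spot(64, c(31, 37), sigma = 1.5, amplitude = 100)
  pk <- detect_maxima(spot, min_prominence = 1)
  expect_equal(nrow(pk), 1L)
  expect_lte(sqrt((pk$row - 31)^2 + (pk$col - 37)^2), 0.5)
  expect_equal(pk$height, 100)

  two <- unclass(gaussian_spot(64, c(30, 25), sigma = 1.5)) +
    unclass(gaussian_spot(64, c(30, 35), sigma = 1.5))
  img <- image_field(two, 25, allow_negative = TRUE)
  pk2 <- detect_maxima(img, min_prominence = 1)
  expect_equal(nrow(pk2), 2L)
  # exhaustive neighbourhood-comparison oracle agrees
  orc <- oracle_local_maxima(two, min_height = 1)
  expect_equal(nrow(orc), 2L)
  expect_setequal(paste(pk2$row, pk2$col), paste(orc[, 1], orc[, 2]))
})

test_that("prominence separates merged peaks from independent ones", {
  # a tall and a short spot close enough to merge through a high saddle
  m <- unclass(gaussian_spot(64, c(32, 28), sigma = 3, amplitude = 100)) +
    unclass(gaussian_spot(64, c(32, 36), sigma = 3, amplitude = 60))
  img <- image_field(m, 25, allow_negative = TRUE)
  both <- detect_maxima(img, min_prominence = 2)
  expect_equal(nrow(both), 2L)
  # the smaller peak's prominence is its height above the saddle, far
  # below its absolute height
  small <- both[which.min(both$height), ]
  saddle <- min(m[32, 28:36])
  expect_equal(small$prominence, small$height - saddle, tolerance = 0.05)
  only_tall <- detect_maxima(img, min_prominence = small$prominence + 1)
  expect_equal(nrow(only_tall), 1L)
  expect_equal(only_tall$height, max(m))
})

test_that("half-max regions match the analytic isocontour area", {
  # sigma >= 2.5 px: below that, whole-pixel inclusion at the contour
  # inflates the discrete region beyond the 15% analytic band
  for (sigma in c(2.5, 3, 4)) {
    spot <- gaussian_spot(64, c(32, 32), sigma = sigma)
    pk <- detect_maxima(spot, min_prominence = 1)
    roi <- expand_to_half_max(spot, pk)
    analytic <- pi * (1.1774 * sigma)^2
    expect_equal(roi$area_px, analytic, tolerance = 0.15)
    expect_true(any(roi$pixels[[1]][, 1] == pk$row &
                      roi$pixels[[1]][, 2] == pk$col))
  }
})

test_that("half-max regions are invariant to amplitude scaling", {
  spot <- gaussian_spot(64, c(32, 32), sigma = 2.5, amplitude = 50)
  double <- image_field(2 * unclass(spot), 25, allow_negative = TRUE)
  r1 <- expand_to_half_max(spot, detect_maxima(spot, 1))
  r2 <- expand_to_half_max(double, detect_maxima(double, 1))
  expect_identical(r1$pixels[[1]], r2$pixels[[1]])
})

test_that("equal twin spots split into disjoint regions of equal area", {
  m <- unclass(gaussian_spot(64, c(30, 27), sigma = 2.5)) +
    unclass(gaussian_spot(64, c(30, 37), sigma = 2.5))
  img <- image_field(m, 25, allow_negative = TRUE)
  rois <- expand_to_half_max(img, detect_maxima(img, 1))
  expect_equal(nrow(rois), 2L)
  expect_lte(abs(rois$area_px[1] - rois$area_px[2]), 1)
  keys <- lapply(rois$pixels, function(p) paste(p[, 1], p[, 2]))
  expect_length(intersect(keys[[1]], keys[[2]]), 0L)
})

test_that("region pixel sets partition their support on noisy fields", {
  sim <- simulate_cluster_field(sim_params(field_um = 5, seed = 21))
  filt <- bandpass(sim$field)
  rois <- expand_to_half_max(filt, detect_maxima(filt))
  all_px <- do.call(rbind, rois$pixels)
  expect_equal(nrow(all_px), nrow(unique(all_px)))
  expect_equal(sum(rois$area_px), nrow(all_px))
})

test_that("expansion rejects peaks that are not maxima of the raster", {
  spot <- gaussian_spot(32, c(16, 16), sigma = 2)
  bad <- tibble::tibble(row = 5L, col = 5L, height = unclass(spot)[5, 5],
                        prominence = 1)
  expect_error(expand_to_half_max(spot, bad), "not a local maximum")
})

test_that("candidate filters enforce the size and contrast rules", {
  flat <- image_field(matrix(100, 32, 32), 25)
  roi4 <- make_roi(cbind(10, 10:13))                 # 4 px: too small
  roi9 <- make_roi(expand.grid(15:17, 15:17), label = 2L,
                   peak = c(16, 16))                 # 9 px
  rois <- dplyr::bind_rows(roi4, roi9)
  rois$area_px <- vapply(rois$pixels, nrow, integer(1))

  kept <- filter_candidates(rois, flat, backgrounds = c(100, 100) * 0.66)
  expect_equal(kept$label, 2L)                       # 4 px always dropped

  # mean 140 on background 100 is below the 50%-above rule; 160 passes
  img <- matrix(100, 32, 32)
  img[cbind(rois$pixels[[2]][, 1], rois$pixels[[2]][, 2])] <- 140
  r140 <- filter_candidates(rois[2, ], image_field(img, 25), 100)
  expect_equal(nrow(r140), 0L)
  img[cbind(rois$pixels[[2]][, 1], rois$pixels[[2]][, 2])] <- 160
  r160 <- filter_candidates(rois[2, ], image_field(img, 25), 100)
  expect_equal(nrow(r160), 1L)

  empty <- rois[0, ]
  expect_equal(nrow(filter_candidates(empty, flat, numeric(0))), 0L)
  expect_error(filter_candidates(rois, flat, 100), "one finite background")
})

test_that("well-separated spots segment into exactly K regions", {
  centers <- as.matrix(expand.grid(c(20, 45, 70), c(20, 45, 70)))
  m <- matrix(5, 90, 90)
  for (i in seq_len(nrow(centers))) {
    m <- m + unclass(gaussian_spot(90, centers[i, ], sigma = 1.3,
                                   amplitude = 80))
  }
  cfg <- analysis_config(min_prominence = 10)
  rois <- segment_clusters(image_field(m, 25), cfg)
  expect_equal(nrow(rois), nrow(centers))
  # each region contains the generating centre
  hit <- vapply(seq_len(nrow(centers)), function(i) {
    any(vapply(rois$pixels, function(px) {
      any(px[, 1] == centers[i, 1] & px[, 2] == centers[i, 2])
    }, logical(1)))
  }, logical(1))
  expect_true(all(hit))
})
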