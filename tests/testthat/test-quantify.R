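test_that("ring background equals the flat level and the enumerated ring mean", {
  flat <- image_field(matrix(7.5, 40, 40), 25)
  roi <- make_roi(as.matrix(expand.grid(18:22, 18:22)), peak = c(20, 20))
  expect_equal(ring_background(flat, roi), 7.5)

  # linear intensity ramp: compare against brute-force pixel enumeration
  ramp <- image_field(outer(seq_len(40), seq_len(40),
                            function(r, cl) 2 * r + 0.5 * cl), 25)
  ring_px <- oracle_ring_pixels(roi$pixels[[1]], inner = 2, outer = 4,
                                h = 40, w = 40)
  oracle <- mean(unclass(ramp)[(ring_px[, 2] - 1) * 40 + ring_px[, 1]])
  expect_equal(ring_background(ramp, roi), oracle)
})

test_that("neighbouring regions are excluded from the ring", {
  flat <- image_field(matrix(3, 40, 40), 25)
  roi_a <- make_roi(as.matrix(expand.grid(18:22, 14:18)), label = 1L,
                    peak = c(20, 16))
  roi_b <- make_roi(as.matrix(expand.grid(18:22, 21:25)), label = 2L,
                    peak = c(20, 23))
  lab <- matrix(0L, 40, 40)
  lab[(roi_a$pixels[[1]][, 2] - 1) * 40 + roi_a$pixels[[1]][, 1]] <- 1L
  lab[(roi_b$pixels[[1]][, 2] - 1) * 40 + roi_b$pixels[[1]][, 1]] <- 2L
  # on a flat image the exclusion changes the pixel set, not the mean
  expect_equal(ring_background(flat, roi_a, lab), 3)
  # contaminate the neighbour's pixels: exclusion must shield the ring
  hot <- unclass(flat)
  hot[(roi_b$pixels[[1]][, 2] - 1) * 40 + roi_b$pixels[[1]][, 1]] <- 1000
  expect_equal(ring_background(image_field(hot, 25), roi_a, lab), 3)

  # ring clipped to fewer than 8 usable pixels errors (or NA when lax)
  corner <- make_roi(cbind(c(1, 1, 2, 2), c(1, 2, 1, 2)), peak = c(1, 1))
  big <- matrix(2L, 40, 40)   # everything claimed by another region
  expect_error(ring_background(flat, corner, big), "usable pixels")
  expect_true(is.na(ring_background(flat, corner, big, strict = FALSE)))
})

test_that("integrated brightness is the background-corrected partial sum", {
  flat <- image_field(matrix(12, 32, 32), 25)
  roi <- make_roi(as.matrix(expand.grid(10:14, 10:14)), peak = c(12, 12))
  expect_equal(integrated_brightness(flat, roi, background = 12), 0)

  # pixel-integrated Gaussian spot: the partial sum over the half-max
  # region equals a midpoint-rule numeric integration over those pixels
  p <- sim_params(field_um = 1.6, noise = "none", background = 0)
  em <- tibble::tibble(x_nm = 800, y_nm = 800, brightness = 500)
  fld <- render_field(em, p)
  pk <- detect_maxima(fld, 1)
  roi_g <- expand_to_half_max(fld, pk)
  got <- integrated_brightness(fld, roi_g, background = 0)
  sigma <- 70 / (2 * sqrt(2 * log(2)))
  fine <- seq(-0.5 + 1 / 40, 0.5 - 1 / 40, length.out = 20)
  oracle <- sum(apply(roi_g$pixels[[1]], 1, function(rc) {
    xs <- ((rc[2] - 1) + fine) * 25
    ys <- ((rc[1] - 1) + fine) * 25
    g <- outer(exp(-(ys - 800)^2 / (2 * sigma^2)),
               exp(-(xs - 800)^2 / (2 * sigma^2)))
    500 * sum(g) / (2 * pi * (sigma / 25)^2) / 400
  }))
  expect_equal(got, oracle, tolerance = 0.02)

  # linearity: doubling the image doubles the brightness
  fld2 <- image_field(2 * unclass(fld), 25)
  expect_equal(integrated_brightness(fld2, roi_g, 0), 2 * got)
})

test_that("brightness referencing divides by the single-dye brightness", {
  expect_equal(count_channels(0, 10), 0)
  expect_equal(count_channels(80, 10), 8)
  expect_equal(count_channels(5, 10), 0.5)    # counts below 1 are kept
  expect_error(count_channels(80, 0), "positive")
  expect_error(count_channels(80, -3), "positive")
})

test_that("a compact 12-emitter cluster counts 12 channels", {
  # twelve dyes of 10 units each, colocated at a pixel centre, counted
  # through the full pipeline with the true single-dye brightness
  p <- sim_params(field_um = 2, noise = "none", background = 8,
                  dye_brightness = 10)
  em <- tibble::tibble(x_nm = rep(1000, 12), y_nm = rep(1000, 12),
                       brightness = 10)
  fld <- render_field(em, p)
  cfg <- analysis_config(min_prominence = 1)
  rois <- segment_clusters(fld, cfg)
  rec <- quantify_clusters(fld, rois, calib = 10, config = cfg)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$counts, 12, tolerance = 0.5 / 12)
})

test_that("counts are offset-invariant and amplitude-linear", {
  p <- sim_params(field_um = 2, noise = "none", background = 10)
  set.seed(3)
  em <- tibble::tibble(x_nm = 1000 + runif(6, -50, 50),
                       y_nm = 1000 + runif(6, -50, 50), brightness = 100)
  fld <- render_field(em, p)
  cfg <- analysis_config(min_prominence = 1)
  rois <- segment_clusters(fld, cfg)
  base <- quantify_clusters(fld, rois, calib = 100, config = cfg)$counts

  shifted <- image_field(unclass(fld) + 50, 25)
  rois_s <- segment_clusters(shifted, cfg)
  shifted_counts <- quantify_clusters(shifted, rois_s, calib = 100,
                                      config = cfg)$counts
  expect_equal(shifted_counts, base, tolerance = 1e-9)

  doubled <- image_field(2 * unclass(fld), 25)
  rois_d <- segment_clusters(doubled, cfg)
  doubled_counts <- quantify_clusters(doubled, rois_d, calib = 100,
                                      config = cfg)$counts
  expect_equal(doubled_counts, 2 * base, tolerance = 1e-9)
})

test_that("shape metrics follow their closed forms", {
  roi16 <- make_roi(as.matrix(expand.grid(10:13, 10:13)), peak = c(11, 11))
  s <- shape_metrics(roi16, pixel_size = 25)
  expect_equal(s$area_um2, 0.01)
  expect_equal(s$diameter_nm, 2 * sqrt(0.01 / pi) * 1000)

  # the published mean area corresponds to a 128 nm diameter
  expect_equal(2 * sqrt(0.012868 / pi) * 1000, 128, tolerance = 1e-3)

  # digital disk of radius 10 px is round
  px <- which(outer((-15:15)^2, (-15:15)^2, `+`) <= 100, arr.ind = TRUE)
  disk <- make_roi(px, peak = c(16, 16))
  expect_gte(shape_metrics(disk, 25)$roundness, 0.95)
  expect_lte(shape_metrics(disk, 25)$roundness, 1)

  # a 1 x 8 px line is far from round
  line <- make_roi(cbind(5, 1:8), peak = c(5, 4))
  expect_lt(shape_metrics(line, 25)$roundness, 0.5)
})

test_that("molecular density is counts per area with the dense-packing scale", {
  expect_equal(molecular_density(0, 0.01), 0)
  # one channel per 10 nm x 10 nm = dense packing at 10,000 per um^2
  expect_equal(molecular_density(1, 1e-4), 10000)
  expect_equal(molecular_density(8, 0.014), 571.4286, tolerance = 1e-6)
  expect_error(molecular_density(1, 0), "positive")
})

test_that("nearest-neighbour distances match brute force", {
  expect_equal(nearest_neighbor_distances(rbind(c(0, 0), c(500, 0))),
               c(500, 500))
  grid <- as.matrix(expand.grid(x = (0:4) * 600, y = (0:4) * 600))
  expect_true(all(nearest_neighbor_distances(grid) == 600))

  set.seed(11)
  pts <- matrix(runif(400, 0, 1e4), ncol = 2)
  brute <- vapply(seq_len(nrow(pts)), function(i) {
    min(sqrt((pts[-i, 1] - pts[i, 1])^2 + (pts[-i, 2] - pts[i, 2])^2))
  }, numeric(1))
  expect_equal(nearest_neighbor_distances(pts), brute)
  expect_error(nearest_neighbor_distances(pts[1, , drop = FALSE]),
               "at least 2")
})

test_that("field summaries conserve totals", {
  expect_equal(field_summary(make_records(numeric(0)),
                             10)$cluster_density_per_um2, 0)
  recs <- make_records(rep(3, 69))
  fs <- field_summary(recs, 100)
  expect_equal(fs$cluster_density_per_um2, 0.69)
  expect_equal(fs$channel_counts_per_um2, sum(recs$counts) / 100)
  expect_length(fs$nnd_nm[[1]], 69)
  expect_error(field_summary(recs, 0))
})

test_that("labeling-efficiency correction reproduces the published factors", {
  expect_equal(ele_correction_factor(0.8, 1.0), 1.25)
  expect_equal(ele_correction_factor(0.4, 1.0), 2.5)
  expect_equal(ele_correction_factor(0.8, 0.7), 0.875)
  expect_equal(ele_correction_factor(0.4, 0.7), 1.75)
  expect_equal(ele_correction_factor(0.63, 0.63), 1)
  expect_error(ele_correction_factor(0, 1), "efficiencies")
  expect_error(ele_correction_factor(0.5, 1.2), "efficiencies")
})
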