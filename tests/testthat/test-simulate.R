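test_that("zero density yields a pure background field with empty truth", {
  p <- sim_params(field_um = 3, cluster_density_per_um2 = 0,
                  noise = "none", seed = 2)
  sim <- simulate_cluster_field(p)
  expect_equal(nrow(sim$truth), 0L)
  expect_true(all(unclass(sim$field) == p$background))
})

test_that("rendered PSFs conserve photons in the field interior", {
  p <- sim_params(field_um = 3, noise = "none", background = 0)
  set.seed(4)
  em <- tibble::tibble(x_nm = 1500 + runif(10, -60, 60),
                       y_nm = 1500 + runif(10, -60, 60),
                       brightness = p$dye_brightness)
  fld <- render_field(em, p)
  expect_equal(sum(fld), 10 * p$dye_brightness, tolerance = 0.005)
})

test_that("simulations are bit-identical for a fixed seed", {
  p <- sim_params(field_um = 4, seed = 77)
  a <- simulate_cluster_field(p)
  b <- simulate_cluster_field(p)
  expect_identical(unclass(a$field), unclass(b$field))
  expect_identical(a$truth$n_labeled, b$truth$n_labeled)
  c1 <- simulate_cluster_field(sim_params(field_um = 4, seed = 78))
  expect_false(identical(unclass(a$field), unclass(c1$field)))
})

test_that("expected field brightness follows photon bookkeeping", {
  p <- sim_params(field_um = 5, seed = 13)     # Poisson noise on
  sim <- simulate_cluster_field(p)
  npx <- nrow(sim$field)^2
  # clusters near the border lose some PSF mass; allow a small deficit
  expected <- p$background * npx +
    sum(sim$truth$n_labeled) * p$dye_brightness
  total <- sum(sim$field)
  expect_lt(abs(total - expected) / expected, 0.02)
})

test_that("calibration fields honour site statistics exactly when frozen", {
  std <- calibration_standard(23, 0, reference_ele = 1)
  p <- sim_params(noise = "none", seed = 5)
  sim <- simulate_calibration_field(p, std, 40)
  expect_true(all(sim$truth$sites == 23L))
  expect_true(all(sim$truth$brightness == 23 * p$dye_brightness))

  one <- simulate_calibration_field(p, std, 1)
  expect_equal(nrow(one$truth), 1L)
})

test_that("labeled sites follow the binomial law at scale", {
  std <- calibration_standard(23, 3, reference_ele = 0.7)
  sim <- simulate_calibration_field(sim_params(seed = 6), std, 500)
  expect_equal(mean(sim$truth$brightness), 23 * 0.7 * 100,
               tolerance = 0.03)
  expect_true(all(sim$truth$labeled <= sim$truth$sites))
})

test_that("coloc pairs honour area fraction and coupling geometry", {
  p <- sim_params(field_um = 10, seed = 9)
  pair <- simulate_coloc_pair(p, marker_area_fraction = 0.12,
                              coupling = 0.5)
  expect_equal(attr(pair$truth$blobs, "area_fraction"), 0.12,
               tolerance = 0.10)
  expect_equal(mean(pair$truth$clusters$coupled), 0.5, tolerance = 0.02)
  # coupled clusters sit inside a blob
  coupled <- pair$truth$clusters[pair$truth$clusters$coupled, ]
  d_blob <- vapply(seq_len(nrow(coupled)), function(i) {
    min(sqrt((pair$truth$blobs$x_nm - coupled$x_nm[i])^2 +
               (pair$truth$blobs$y_nm - coupled$y_nm[i])^2))
  }, numeric(1))
  expect_true(all(d_blob <= 250))

  empty <- simulate_coloc_pair(p, marker_area_fraction = 0, coupling = 0)
  expect_equal(nrow(empty$truth$blobs), 0L)
  expect_error(simulate_coloc_pair(p, marker_area_fraction = 0.9),
               "infeasible")
})

test_that("zero diffusion reproduces the static render bit-exactly", {
  p0 <- sim_params(field_um = 3, noise = "none",
                   motion = list(diffusion_um2_s = 0, line_time_s = 1e-3))
  set.seed(8)
  em <- tibble::tibble(x_nm = runif(15, 500, 2500),
                       y_nm = runif(15, 500, 2500), brightness = 100)
  static <- render_field(em, sim_params(field_um = 3, noise = "none"))
  moving <- apply_scan_motion(em, p0)
  expect_identical(unclass(moving)[, ], unclass(static)[, ])
})

test_that("diffusion during the scan blurs the apparent cluster", {
  apparent_area <- function(D, s) {
    p <- sim_params(field_um = 3, noise = "none", seed = s,
                    motion = list(diffusion_um2_s = D, line_time_s = 1e-3))
    set.seed(s + 500)
    ang <- runif(8, 0, 2 * pi); rad <- 60 * sqrt(runif(8))
    em <- tibble::tibble(x_nm = 1500 + rad * cos(ang),
                         y_nm = 1500 + rad * sin(ang), brightness = 100)
    set.seed(s)
    fld <- apply_scan_motion(em, p)
    rois <- segment_clusters(fld, analysis_config(min_prominence = 1))
    sum(rois$area_px)
  }
  static <- mean(vapply(1:8, function(s) apparent_area(0, s), numeric(1)))
  blurred <- mean(vapply(1:8, function(s) apparent_area(0.01, s),
                         numeric(1)))
  expect_gt(blurred, static)
})
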