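# analytic tube image: value `inside` within radius r of the axis through
# the volume centre along SI, `outside` elsewhere, optional Gaussian blur
tube_image <- function(grid = c(48, 32, 32), spacing = 1.4, r = 5,
                       inside = 1, outside = 0, blur_sigma = 0) {
  co <- wholeheart:::coord_arrays(grid, spacing)
  cy <- grid[2] * spacing / 2; cz <- grid[3] * spacing / 2
  img <- ifelse((co$y - cy)^2 + (co$z - cz)^2 <= r^2, inside, outside)
  if (blur_sigma > 0) {
    img <- wholeheart:::gaussian_smooth(img, blur_sigma / spacing)
  }
  img
}

tube_centerline <- function(grid = c(48, 32, 32), spacing = 1.4) {
  s <- seq(2, grid[1] * spacing - 2, by = spacing / 2)
  cbind(s, grid[2] * spacing / 2, grid[3] * spacing / 2)
}

test_that("a hard-edged tube scores the capped 100% sharpness", {
  img <- tube_image()
  vm <- vessel_metrics(img, tube_centerline(), background_level = 0,
                       spacing = 1.4)
  expect_equal(vm$vs_pct, 100)
  expect_gt(vm$vl_cm, 5)
})

test_that("Gaussian edge blur reproduces the error-function oracle", {
  sigma <- 2.5
  img <- tube_image(r = 8, blur_sigma = sigma)
  vm <- vessel_metrics(img, tube_centerline(), background_level = 0,
                       spacing = 1.4, profile_halflength = 14)
  # closed form: d2080 = 2 sqrt(2) erfinv(0.6) sigma
  erfinv <- function(p) stats::qnorm((p + 1) / 2) / sqrt(2)
  d_expected <- 2 * sqrt(2) * erfinv(0.6) * sigma
  expected <- 100 * 1.4 / d_expected
  expect_lt(abs(vm$vs_pct - expected) / expected, 0.12)
})

test_that("zero contrast yields zero visible length", {
  img <- tube_image(inside = 0.5, outside = 0.5)
  vm <- vessel_metrics(img, tube_centerline(), background_level = 0.5,
                       spacing = 1.4)
  expect_equal(vm$vl_cm, 0)
})

test_that("vessel metrics are invariant to affine intensity rescaling", {
  img <- tube_image(r = 6, blur_sigma = 2)
  cl <- tube_centerline()
  a <- 3.2; b <- 0.7
  v1 <- vessel_metrics(img, cl, 0, spacing = 1.4)
  v2 <- vessel_metrics(a * img + b, cl, a * 0 + b, spacing = 1.4)
  expect_equal(v1$vs_pct, v2$vs_pct, tolerance = 1e-8)
  expect_equal(v1$vl_cm, v2$vl_cm, tolerance = 1e-8)
})

test_that("a centerline leaving the volume is truncated with a warning", {
  img <- tube_image()
  cl <- tube_centerline()
  cl[nrow(cl), 1] <- 1e4
  expect_warning(vm <- vessel_metrics(img, cl, 0, spacing = 1.4),
                 "truncated")
  expect_gt(vm$vl_cm, 0)
})

test_that("SNR and CNR follow their defining arithmetic", {
  set.seed(47)
  grid <- c(16, 16, 8)
  img <- array(0, grid)
  rois <- list(venous = array(FALSE, grid), arterial = array(FALSE, grid),
               myocardium = array(FALSE, grid),
               background = array(FALSE, grid))
  rois$venous[1:4, 1:4, 1] <- TRUE; img[rois$venous] <- 10
  rois$arterial[5:8, 1:4, 1] <- TRUE; img[rois$arterial] <- 12
  rois$myocardium[9:12, 1:4, 1] <- TRUE; img[rois$myocardium] <- 10
  rois$background[1:8, 9:16, ] <- TRUE
  img[rois$background] <- stats::rnorm(sum(rois$background), 0, 2)
  r <- snr_cnr(img, rois)
  sd_bg <- stats::sd(abs(img[rois$background]))
  expect_equal(r$snr_ven, 10 / sd_bg)
  expect_equal(r$cnr_ven, 0)                # blood mean == myocardium mean
  expect_equal(r$cnr_art, (12 - 10) / sd_bg)
  img2 <- img; img2[rois$background] <- 0
  expect_error(snr_cnr(img2, rois), "zero background")
})

# spherical-shell (annulus) phantom for wall-thickness tests
annulus_volume <- function(grid = c(48, 48, 32), spacing = 1.4,
                           r_in = 12, th = 2.8, wall = 1, lumen = 0,
                           outside = 0, blur_vox = 0.5) {
  co <- wholeheart:::coord_arrays(grid, spacing)
  c0 <- grid * spacing / 2
  d <- sqrt((co$x - c0[1])^2 + (co$y - c0[2])^2 + (co$z - c0[3])^2)
  img <- array(outside, grid)
  img[d < r_in + th] <- wall
  img[d < r_in] <- lumen
  # mild band-limiting: reconstructed volumes never carry a hard edge
  if (blur_vox > 0) img <- wholeheart:::gaussian_smooth(img, blur_vox)
  img
}

annulus_contour <- function(grid = c(48, 48, 32), spacing = 1.4,
                            r_in = 12, th = 2.8) {
  c0 <- grid * spacing / 2
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  list(side = "left",
       points = cbind(c0[1] + (r_in + th / 2) * cos(ang),
                      c0[2] + (r_in + th / 2) * sin(ang), c0[3]),
       normals = cbind(cos(ang), sin(ang), 0))
}

test_that("wall thickness of a 2.8 mm annulus is recovered to half a voxel", {
  vol <- annulus_volume()
  ct <- annulus_contour()
  r <- awt_measure(vol, ct, spacing = 1.4)
  expect_gt(r$n_defined, 20)
  expect_lt(abs(r$mean - 2.8), 0.7)
})

test_that("wall thickness is stable under 2x zero-fill interpolation", {
  vol <- annulus_volume()
  ct <- annulus_contour()
  r1 <- awt_measure(vol, ct, spacing = 1.4)
  vol2 <- zero_fill_interpolate(vol, 2)
  r2 <- awt_measure(vol2, ct, spacing = 0.7)
  expect_lt(abs(r1$mean - r2$mean), 0.2)
})

test_that("wall thickness is invariant to sign flip with inverted contrast", {
  vol <- annulus_volume()
  ct <- annulus_contour()
  r1 <- awt_measure(vol, ct, spacing = 1.4)
  r2 <- awt_measure(-vol, ct, spacing = 1.4, invert = TRUE)
  expect_equal(r1$thickness, r2$thickness)
})

test_that("an absent wall leaves every contour point undefined", {
  vol <- annulus_volume(wall = 0)        # blood touching lung, no band
  ct <- annulus_contour()
  r <- awt_measure(vol, ct, spacing = 1.4)
  expect_equal(r$n_defined, 0)
  expect_true(is.na(r$mean))
  ct_out <- ct; ct_out$points[1, 1] <- -50
  expect_error(awt_measure(vol, ct_out, spacing = 1.4), "outside")
})

test_that("paired comparisons follow the textbook t statistic", {
  eq <- paired_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t_statistic, 0)
  expect_false(eq$significant)
  # differences 1,2,3,4 against zero: t = dbar / (sd/sqrt(n))
  d <- c(1, 2, 3, 4)
  r <- paired_compare(d, rep(0, 4), n_comparisons = 3)
  expect_equal(r$t_statistic, mean(d) / (sd(d) / sqrt(4)), tolerance = 1e-12)
  expect_equal(r$threshold, 0.05 / 3)
  expect_error(paired_compare(c(2, 3, 4), c(1, 2, 3)), "zero-variance")
  # the conventional three-decimal truncation of 0.05/3
  expect_identical(bonferroni_threshold(3, digits = 3), 0.016)
})
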