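# Lens-power -> magnification model, metrology and examination-distance
# lookups.

test_that("catalog magnification factors are returned verbatim and flagged", {
  expect_equal(mag_factor(90)$mag_factor, 0.75)
  expect_equal(mag_factor(60)$mag_factor, 1.15)
  expect_equal(mag_factor(40)$mag_factor, 1.67)
  expect_true(all(vapply(c(90, 60, 40),
                         function(p) mag_factor(p)$catalog, logical(1))))
  expect_false(mag_factor(55)$catalog)
  expect_error(mag_factor(-5), "positive")
  expect_error(mag_factor(0), "positive")
})

test_that("reciprocal-proportionality fit matches the catalog within 3% and interpolates", {
  # independent oracle: closed-form least squares for m = c/P over the
  # three catalog pairs
  P <- c(90, 60, 40); m <- c(0.75, 1.15, 1.67)
  c_hat <- sum(m / P) / sum(1 / P^2)
  expect_equal(mag_factor(55)$mag_factor, c_hat / 55, tolerance = 1e-12)
  expect_equal(mag_factor(55)$mag_factor, 1.23, tolerance = 0.005)
  rel_res <- abs(c_hat / P - m) / m
  expect_true(all(rel_res < 0.03))
  # (1/m)/power constant within 3% of the common constant
  k <- 1 / (m * P)
  expect_true(all(abs(k - mean(k)) / mean(k) < 0.03))
})

test_that("projected aperture diameters reproduce the printed ring diameters", {
  expect_equal(projected_aperture_diameter(3.5, fundus_lens(90), round = TRUE), 4.7)
  expect_equal(projected_aperture_diameter(3.5, fundus_lens(40), round = TRUE), 2.1)
  # the +60D value computes to 3.04; the printed 3.1 agrees within 2%
  d60 <- projected_aperture_diameter(3.5, fundus_lens(60))
  expect_equal(d60, 3.5 / 1.15, tolerance = 1e-12)
  expect_lt(abs(d60 - 3.1) / 3.1, 0.02)
  expect_equal(projected_aperture_diameter(0, fundus_lens(90)), 0)
  expect_error(projected_aperture_diameter(-1, fundus_lens(90)), "non-negative")
})

test_that("projection ratios depend only on magnification factors", {
  l1 <- fundus_lens(90); l2 <- fundus_lens(40)
  for (a in c(0.3, 3.5, 8, 14)) {
    expect_equal(projected_aperture_diameter(a, l1) /
                   projected_aperture_diameter(a, l2),
                 l2$mag_factor / l1$mag_factor)
  }
  # lens-collection power steps of exactly 1.5
  expect_identical(90 / 60, 1.5)
  expect_identical(60 / 40, 1.5)
})

test_that("retinal metrology converts px to mm linearly and errors when uncalibrated", {
  cal <- scale_calibration(20)
  l90 <- fundus_lens(90)
  expect_equal(retinal_length(100, cal, l90), 3.75)
  expect_equal(retinal_length(0, cal, l90), 0)
  # linear in px and mag_factor
  expect_equal(retinal_length(200, cal, l90), 2 * retinal_length(100, cal, l90))
  l <- fundus_lens(60)
  expect_equal(retinal_length(100, cal, l) / retinal_length(100, cal, l90),
               l$mag_factor / l90$mag_factor)
  # area metrology = length metrology squared on a square patch
  expect_equal(retinal_area(100^2, cal, l90), retinal_length(100, cal, l90)^2)
  expect_error(retinal_length(100, NULL, l90), "uncalibrated")
  expect_error(retinal_area(100, NULL, l90), "uncalibrated")
  # round trip: aerial px of a projected aperture measures back to a/m
  a <- 3.5
  px <- (a / l90$mag_factor) / l90$mag_factor * cal$px_per_mm_aerial
  expect_equal(retinal_length(px, cal, l90), a / l90$mag_factor)
})

test_that("scale calibration recovers a synthetic ruler within 1%, also rotated", {
  r0 <- generate_ruler(spacing_px = 20, n_lines = 9)
  cal0 <- calibrate_scale(r0, 1)
  expect_equal(cal0$px_per_mm_aerial, 20, tolerance = 0.01)
  r5 <- generate_ruler(spacing_px = 20, n_lines = 9, angle_deg = 5)
  cal5 <- calibrate_scale(r5, 1)
  expect_equal(cal5$px_per_mm_aerial, 20, tolerance = 0.01)
  expect_error(calibrate_scale(matrix(0.5, 100, 100), 1), "calibration failure")
  # two lines only is not a usable scale
  r2 <- generate_ruler(spacing_px = 60, n_lines = 2, size_px = 150)
  expect_error(calibrate_scale(r2, 1), "calibration failure")
})

test_that("drawback distances match the printed anchors and interpolate in focal length", {
  expect_equal(drawback_distance(fundus_lens(90))$cm, 3)
  expect_equal(drawback_distance(fundus_lens(60))$cm, 4)
  expect_equal(drawback_distance(fundus_lens(40))$cm, 6)
  expect_equal(drawback_distance(fundus_lens(20))$cm, 10)
  expect_false(drawback_distance(fundus_lens(90))$fitted)
  d55 <- drawback_distance(fundus_lens(55))
  expect_true(d55$fitted)
  expect_equal(d55$cm, 4.5, tolerance = 0.05)
  # the affine fit reproduces every printed anchor within 0.5 cm
  anchors <- data.frame(power = c(90, 60, 40, 20), cm = c(3, 4, 6, 10))
  f <- 100 / anchors$power
  cf <- stats::coef(stats::lm(anchors$cm ~ f))
  expect_true(all(abs(cf[1] + cf[2] * f - anchors$cm) < 0.5))
  expect_error(drawback_distance(fundus_lens(10)), "unsupported lens")
  expect_error(drawback_distance(fundus_lens(150)), "unsupported lens")
})

test_that("ametropia correction has the right sign, symmetry and monotonicities", {
  l90 <- fundus_lens(90)
  expect_equal(ametropia_factor(schematic_eye(refraction_D = 0), l90), 1)
  fp <- ametropia_factor(schematic_eye(refraction_D = 3), l90)
  fm <- ametropia_factor(schematic_eye(refraction_D = -3), l90)
  expect_gt(fp, 1)   # hyperopia: higher magnification
  expect_lt(fm, 1)   # myopia: lower
  # first-order symmetric within 10%
  expect_equal(fp - 1, -(fm - 1), tolerance = 0.1)
  # deviation shrinks with lens power and with |refraction|
  for (r in c(3, -3)) {
    d90 <- abs(ametropia_factor(schematic_eye(refraction_D = r), fundus_lens(90)) - 1)
    d40 <- abs(ametropia_factor(schematic_eye(refraction_D = r), fundus_lens(40)) - 1)
    expect_lt(d90, d40)
  }
  d1 <- abs(ametropia_factor(schematic_eye(refraction_D = 1), l90) - 1)
  d5 <- abs(ametropia_factor(schematic_eye(refraction_D = 5), l90) - 1)
  expect_lt(d1, d5)
  expect_error(ametropia_factor(schematic_eye(refraction_D = 20), l90), "15")
})

test_that("metrology table carries provenance and flags calibration", {
  l <- fundus_lens(90)
  df <- metrology_table(c("disc", "cup"), c(240, 80), scale_calibration(20), l)
  expect_equal(df$mm, c(9, 3))
  expect_true(all(df$calibrated))
  df2 <- metrology_table("disc", 240, NULL, l)
  expect_false(df2$calibrated)
  expect_true(is.na(df2$mm))
})
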