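# Slit-beam surface contour reconstruction: centerline, baseline,
# triangulation, lesion summaries.

test_that("centerline of a clean synthetic band is found to subpixel accuracy", {
  img <- band_image(center_px = 120.4)
  ctr <- detect_centerline(img)
  expect_true(all(abs(ctr - 120.4) <= 0.3))
  expect_error(detect_centerline(matrix(0.5, 40, 40)), "no slit band")
  # two distinct bands in a row raise an ambiguity error
  two <- band_image(60) + band_image(150) - 0.05
  expect_error(detect_centerline(two), "ambiguous")
})

test_that("centerline is robust to additive noise (Monte Carlo)", {
  errs <- vapply(1:100, function(s) {
    img <- band_image(center_px = 120.4, noise_sd = 0.04, seed = s)
    ctr <- detect_centerline(img)
    mean(abs(ctr - 120.4), na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(errs), 0.5)
})

test_that("baseline fit is robust to an excluded central bump", {
  rows <- 1:120
  straight <- 80 + 0.05 * rows
  base <- fit_baseline(straight)
  expect_true(all(abs(base - straight) < 0.2))
  bumped <- straight + ifelse(rows > 50 & rows < 80, 5, 0)
  excl <- rows > 50 & rows < 80
  base2 <- fit_baseline(bumped, excl)
  expect_true(all(abs(base2[!excl] - straight[!excl]) < 0.3))
  expect_error(fit_baseline(bumped, rep(TRUE, 120)), "baseline error")
  expect_error(fit_baseline(straight[1:10]), "baseline error")
})

test_that("deflection-to-height triangulation follows d / tan(theta) with the documented signs", {
  expect_equal(height_from_deflection(0, 5), 0)
  expect_equal(height_from_deflection(1.0, 45), 1.0)
  # deflection away from the arm of 0.0481 mm at 5 degrees: 0.55 mm deep
  expect_equal(height_from_deflection(-0.0481, 5), -0.55, tolerance = 0.001)
  expect_error(height_from_deflection(1, 0), "invalid geometry")
  expect_error(height_from_deflection(1, 95), "invalid geometry")
})

test_that("pit depth is recovered within 5% across arm angles and sides", {
  ph <- fixture_phantom()
  hm <- make_height_map(ph, "pit", depth_mm = 0.5, radius_mm = 0.5)
  for (th in c(5, 10, 15)) for (arm in c("right", "left")) {
    obs <- render_slit(ph, hm, angle_deg = th, arm_side = arm)
    prof <- reconstruct_profile(obs)
    met <- lesion_metrics(prof)
    expect_equal(met$depth_mm, 0.5, tolerance = 0.05,
                 label = sprintf("depth at theta=%d arm=%s", th, arm))
    expect_lt(min(prof$height_mm, na.rm = TRUE), 0)  # a depression
  }
})

test_that("flat retina reconstructs to near-zero height", {
  ph <- fixture_phantom()
  prof <- reconstruct_profile(render_slit(ph, make_height_map(ph, "flat")))
  expect_lt(max(abs(prof$height_mm), na.rm = TRUE), 0.02)
  expect_false(lesion_metrics(prof)$lesion)
})

test_that("elevations give positive heights; arm swap flips deflection, not height", {
  ph <- fixture_phantom()
  hb <- make_height_map(ph, "bump", depth_mm = 0.3, radius_mm = 0.4)
  pr_r <- reconstruct_profile(render_slit(ph, hb, angle_deg = 10, arm_side = "right"))
  pr_l <- reconstruct_profile(render_slit(ph, hb, angle_deg = 10, arm_side = "left"))
  expect_equal(max(pr_r$height_mm, na.rm = TRUE), 0.3, tolerance = 0.05)
  expect_equal(max(pr_l$height_mm, na.rm = TRUE), 0.3, tolerance = 0.05)
  # deflection mirrors between arms, reconstructed height does not
  i <- which.max(pr_r$height_mm)
  expect_equal(pr_r$deflection_mm[i], -pr_l$deflection_mm[i], tolerance = 0.01)
  expect_equal(pr_r$height_mm[i], pr_l$height_mm[i], tolerance = 0.05)
})

test_that("height scales linearly and deflection doubles with tan(theta)", {
  ph <- fixture_phantom()
  hm1 <- make_height_map(ph, "pit", depth_mm = 0.4, radius_mm = 0.5)
  hm2 <- make_height_map(ph, "pit", depth_mm = 0.8, radius_mm = 0.5)
  d1 <- lesion_metrics(reconstruct_profile(render_slit(ph, hm1, angle_deg = 10)))$depth_mm
  d2 <- lesion_metrics(reconstruct_profile(render_slit(ph, hm2, angle_deg = 10)))$depth_mm
  expect_equal(d2 / d1, 2, tolerance = 0.03)
  # same pit at doubled angle: same height, roughly doubled deflection
  p5 <- reconstruct_profile(render_slit(ph, hm1, angle_deg = 5))
  p10 <- reconstruct_profile(render_slit(ph, hm1, angle_deg = 10))
  expect_equal(lesion_metrics(p10)$depth_mm, lesion_metrics(p5)$depth_mm,
               tolerance = 0.05)
  r_tan <- tan(10 * pi / 180) / tan(5 * pi / 180)
  expect_equal(min(p10$deflection_mm, na.rm = TRUE) /
                 min(p5$deflection_mm, na.rm = TRUE),
               r_tan, tolerance = 0.1)
})

test_that("lesion metrics report depth, threshold-crossing extent and the no-lesion case", {
  # synthetic profile, oracle by direct scan of threshold crossings
  pos <- seq(0, 5, by = 0.01)
  h <- -0.5 * exp(-((pos - 2.5) / 0.4)^2)
  prof <- structure(list(position_mm = pos, height_mm = h,
                         valid = rep(TRUE, length(pos)),
                         angle_deg = 5, arm_side = "right"),
                    class = "height_profile")
  met <- lesion_metrics(prof)
  expect_equal(met$depth_mm, 0.5)
  below <- which(h < -0.05)
  expect_equal(met$extent_mm, pos[max(below)] - pos[min(below)])
  # two disjoint pits: extent spans the outermost crossings
  h2 <- -0.3 * exp(-((pos - 1.5) / 0.2)^2) - 0.5 * exp(-((pos - 3.5) / 0.2)^2)
  prof2 <- prof; prof2$height_mm <- h2
  met2 <- lesion_metrics(prof2)
  below2 <- which(h2 < -0.05)
  expect_equal(met2$extent_mm, pos[max(below2)] - pos[min(below2)])
  flat <- prof; flat$height_mm <- rep(0, length(pos))
  expect_equal(lesion_metrics(flat),
               list(depth_mm = 0, extent_mm = 0, lesion = FALSE))
})

test_that("profiles export to CSV with position, height and validity", {
  ph <- fixture_phantom()
  prof <- reconstruct_profile(render_slit(ph, make_height_map(ph, "flat")))
  f <- file.path(withr::local_tempdir(), "profile.csv")
  write_profile(prof, f)
  back <- read.csv(f)
  expect_named(back, c("position_mm", "height_mm", "valid"))
  expect_equal(nrow(back), length(prof$position_mm))
})
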