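# The synthetic fundus generator: determinism and ground-truth fidelity.

test_that("phantom generation is deterministic per seed", {
  a <- generate_phantom(seed = 2, size_px = 128)
  b <- generate_phantom(seed = 2, size_px = 128)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$vessel_points, b$truth$vessel_points)
  c <- generate_phantom(seed = 3, size_px = 128)
  expect_false(identical(a$image, c$image))
})

test_that("phantom anatomy: disc and fovea inside the frame, vessels optional", {
  ph <- fixture_phantom()
  n <- dim(ph$image)[1]
  expect_true(all(ph$truth$disc_center_px > 0 & ph$truth$disc_center_px < n))
  expect_true(all(ph$truth$fovea_px > 0 & ph$truth$fovea_px < n))
  expect_equal(ph$truth$disc_diameter_px * ph$mm_per_px, 1.8)
  no_vessels <- generate_phantom(seed = 1, size_px = 128, vessel_density = 0)
  expect_equal(sum(no_vessels$truth$vessel_mask), 0)
  expect_error(generate_phantom(seed = 1, size_px = 16), "size_px")
  expect_error(generate_phantom(seed = 1, vessel_density = -1), "vessel_density")
})

test_that("vessel contrast is concentrated in the green channel", {
  ph <- fixture_phantom()
  vm <- ph$truth$vessel_mask
  expect_gt(sum(vm), 0)
  bg <- !vm & !EBImage::dilate(vm, EBImage::makeBrush(7, "disc"))
  contrast <- function(ch) mean(ph$image[, , ch][bg]) - mean(ph$image[, , ch][vm])
  expect_gt(contrast(2), 2 * contrast(1))
})

test_that("height maps are zero outside the lesion support", {
  ph <- fixture_phantom()
  hm <- make_height_map(ph, "pit", depth_mm = 0.5, radius_mm = 0.3)
  expect_equal(min(hm$height_mm), -0.5, tolerance = 1e-6)
  n <- nrow(hm$height_mm)
  ax <- seq_len(n)
  d2 <- outer((ax - hm$center_px[2])^2, (ax - hm$center_px[1])^2, "+")
  outside <- d2 > (3 * 0.3 / ph$mm_per_px)^2 + 1   # 1 px^2 rounding slack
  expect_true(all(hm$height_mm[outside] == 0))
  expect_true(all(is.finite(hm$height_mm)))
  expect_error(make_height_map(ph, "pit", depth_mm = -1), "depth_mm")
})

test_that("slit rendering displaces the band by height x tan(angle), mirrored by arm side", {
  ph <- fixture_phantom()
  hm <- make_height_map(ph, "pit", depth_mm = 0.5, radius_mm = 0.5)
  obs_r <- render_slit(ph, hm, angle_deg = 5, arm_side = "right")
  tr <- attr(obs_r, "truth")
  # max displacement: 0.5 mm x tan(5 deg) = 0.0437 mm
  expect_equal(max(abs(tr$disp_px)) * ph$mm_per_px,
               0.5 * tan(5 * pi / 180), tolerance = 1e-6)
  obs_l <- render_slit(ph, hm, angle_deg = 5, arm_side = "left")
  expect_equal(attr(obs_l, "truth")$disp_px, -tr$disp_px)
  # flat map: perfectly straight band
  flat <- render_slit(ph, make_height_map(ph, "flat"))
  expect_true(all(attr(flat, "truth")$disp_px == 0))
  expect_error(render_slit(ph, hm, width_mm = 0), "width")
  expect_error(render_slit(ph, hm, angle_deg = 0), "angle")
})

test_that("tile sets carry consistent ground truth and respect the layout", {
  ph <- fixture_phantom(seed = 8)
  pair <- make_tiles(ph, "pair", tile_px = 160, overlap_deg = 2)
  expect_length(pair, 2)
  # overlap equal in both sidecars and non-empty at 2 degrees
  sep <- abs(pair[[2]]$truth$dx_px - pair[[1]]$truth$dx_px)
  expect_lt(sep, 160)
  expect_equal(160 - sep,
               2 * slitfundus:::mm_per_degree() / ph$mm_per_px,
               tolerance = 1)
  # zero overlap: adjacent, non-overlapping crops
  pair0 <- make_tiles(ph, "pair", tile_px = 160, overlap_deg = 0)
  expect_equal(abs(pair0[[2]]$truth$dx_px - pair0[[1]]$truth$dx_px), 160)
  grid <- make_tiles(ph, "3x3", tile_px = 120)
  expect_length(grid, 9)
  expect_setequal(vapply(grid, `[[`, character(1), "gaze_label")[5], "center")
  expect_error(make_tiles(ph, "3x3", tile_px = 300), "exceeds phantom")
  # tiles are exact crops: truth transform reproduces the tile content
  t1 <- pair[[1]]
  n <- dim(ph$image)[1]
  ctr <- (n + 1) / 2
  x1 <- t1$truth$dx_px + ctr - (160 - 1) / 2
  y1 <- t1$truth$dy_px + ctr - (160 - 1) / 2
  expect_equal(t1$image, ph$image[, , 2][y1:(y1 + 159), x1:(x1 + 159)])
})

test_that("video generation is deterministic with declared sharp frames ranking top", {
  ph <- fixture_phantom(seed = 5, size_px = 256)
  v1 <- make_video(ph, 12, blur_schedule = c(0, 2, 3), seed = 6)
  v2 <- make_video(ph, 12, blur_schedule = c(0, 2, 3), seed = 6)
  expect_identical(v1$frames, v2$frames)
  # all-sharp schedule: frames score alike
  vs <- make_video(ph, 6, jitter_px = 2, blur_schedule = 0, seed = 3)
  scores <- vapply(vs$frames, sharpness_score, numeric(1))
  expect_lt((max(scores) - min(scores)) / min(scores), 0.2)
  # declared sharp frames outrank all blurred frames
  sc <- vapply(v1$frames, sharpness_score, numeric(1))
  sharp <- v1$truth$sharp
  expect_gt(min(sc[sharp]), max(sc[!sharp]))
})

test_that("change pairs differ only inside the change mask with landmark truth", {
  ph <- fixture_phantom(seed = 12)
  cp <- make_change_pair(ph, "vessel_shift", magnitude = 2)
  expect_equal(max(abs(cp$after - cp$before)[!cp$change_mask]), 0)
  expect_gt(nrow(cp$landmarks), 0)
  expect_true(all(sqrt(cp$landmarks$dx_px^2 + cp$landmarks$dy_px^2) == 2))
  for (type in c("atrophy_growth", "hemorrhage")) {
    cpi <- make_change_pair(ph, type, magnitude = 0.2)
    expect_equal(max(abs(cpi$after - cpi$before)[!cpi$change_mask]), 0)
    expect_gt(max(abs(cpi$after - cpi$before)), 0.05)
  }
  expect_error(make_change_pair(ph, "vessel_shift", magnitude = 0), "magnitude")
})

test_that("the ruler generator and slit renderer are seed-deterministic", {
  expect_identical(generate_ruler(seed = 4, noise_sd = 0.02),
                   generate_ruler(seed = 4, noise_sd = 0.02))
  ph <- fixture_phantom(seed = 5, size_px = 256)
  hm <- make_height_map(ph, "flat")
  expect_identical(render_slit(ph, hm, seed = 2)$image,
                   render_slit(ph, hm, seed = 2)$image)
})
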