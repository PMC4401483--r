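# Synthetic fundus generator: deterministic phantoms with full ground
# truth (vessel tree, disc, fovea, height maps, slit renderings, tile
# sets, change pairs, video).  Every generator is reproducible per seed.

#' Generate a synthetic fundus phantom
#'
#' Builds a green-dominant RGB fundus phantom: a bright optic disc, a
#' darker fovea, and a vessel tree grown from the disc by recursive random
#' branching with decreasing caliber.  Vessels are drawn mainly into the
#' green channel (where real fundus vessel contrast lives), with only a
#' weak red-channel imprint; mild vignetting and additive Gaussian noise
#' emulate video capture.  Same seed, same image, bit for bit.
#'
#' @param seed RNG seed.
#' @param size_px side length of the square phantom, px.
#' @param mm_per_px retinal-plane scale (default 0.01 mm/px).
#' @param disc_diameter_mm optic disc diameter (default 1.8 mm, normal
#'   papilla).
#' @param vessel_density multiplier on the number of vessel trunks; 0
#'   disables vessels.
#' @param pigmentation background pigmentation level in \[0, 1\].
#' @param noise_sd additive Gaussian noise sd.
#' @param vignette peripheral darkening strength in \[0, 1).
#' @return object of class `fundus_phantom`: `image` (RGB array), `truth`
#'   (vessel mask and centerline points, disc center/diameter px, fovea
#'   px), `mm_per_px`, `seed`.
#' @export
generate_phantom <- function(seed = 1, size_px = 512, mm_per_px = 0.01,
                             disc_diameter_mm = 1.8, vessel_density = 1,
                             pigmentation = 0.5, noise_sd = 0.01,
                             vignette = 0.15) {
  if (size_px < 64) stopf("size_px must be >= 64")
  if (mm_per_px <= 0) stopf("mm_per_px must be positive")
  if (vessel_density < 0) stopf("vessel_density must be >= 0")
  if (pigmentation < 0 || pigmentation > 1) stopf("pigmentation must be in [0, 1]")
  if (vignette < 0 || vignette >= 1) stopf("vignette must be in [0, 1)")
  disc_r_px <- disc_diameter_mm / 2 / mm_per_px
  fovea <- c(size_px / 2, size_px / 2)
  disc <- c(size_px / 2 - min(1.5 / mm_per_px, size_px / 2 - disc_r_px - 10),
            size_px / 2)
  if (disc[1] - disc_r_px < 1) stopf("degenerate params: disc does not fit")

  with_seed(seed, {
    n <- size_px
    ax <- seq_len(n)
    X <- matrix(ax, n, n, byrow = TRUE)   # x = col
    Y <- matrix(ax, n, n)                 # y = row

    # vessel tree: trunks leave the disc rim as superior/inferior arcades
    vmask <- matrix(FALSE, n, n)
    vpts <- list()
    n_trunks <- round(4 * vessel_density)
    trunk_angles <- if (n_trunks > 0)
      rep(c(-55, 55, -20, 20), length.out = n_trunks) * pi / 180 else numeric(0)
    stamp <- function(x, y, w) {
      r <- ceiling(w / 2)
      xs <- max(1, round(x) - r):min(n, round(x) + r)
      ys <- max(1, round(y) - r):min(n, round(y) + r)
      if (length(xs) && length(ys)) {
        d2 <- outer((ys - y)^2, (xs - x)^2, "+")
        vmask[ys, xs] <<- vmask[ys, xs] | (d2 <= (w / 2)^2)
      }
    }
    grow <- function(x, y, dir, width, depth) {
      steps <- 0L
      while (width >= 0.9 && steps < 400L) {
        steps <- steps + 1L
        x <- x + 3 * cos(dir); y <- y + 3 * sin(dir)
        if (x < 3 || x > n - 2 || y < 3 || y > n - 2) return(invisible())
        stamp(x, y, width)
        vpts[[length(vpts) + 1L]] <<- c(x, y, width)
        dir <- dir + stats::rnorm(1, 0, 0.06) - 0.015 * sin(dir)
        width <- width * 0.995
        if (depth < 3L && stats::runif(1) < 0.025) {
          branch_dir <- dir + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 0.9)
          grow(x, y, branch_dir, width * 0.7, depth + 1L)
        }
      }
    }
    for (a in trunk_angles) {
      sx <- disc[1] + disc_r_px * cos(a)
      sy <- disc[2] + disc_r_px * sin(a)
      grow(sx, sy, a, stats::runif(1, 4.5, 6), 0L)
    }

    # soft-edged masks
    vsoft <- as.matrix(EBImage::gblur(matrix(as.numeric(vmask), n, n), 0.8))
    dd <- sqrt((X - disc[1])^2 + (Y - disc[2])^2)
    disc_soft <- clamp01((disc_r_px - dd) / 3 + 0.5)
    fd2 <- (X - fovea[1])^2 + (Y - fovea[2])^2
    # broad, gentle foveal darkening (sigma 0.25 mm, as in real fundus
    # images, where the luteal dip spans about half a millimetre)
    fovea_soft <- exp(-fd2 / (2 * (0.25 / mm_per_px)^2))

    rmax2 <- 2 * (n / 2)^2
    vig <- 1 - vignette * ((X - n / 2)^2 + (Y - n / 2)^2) / rmax2

    base_r <- 0.50 + 0.12 * pigmentation
    base_g <- 0.42 - 0.06 * pigmentation
    base_b <- 0.14
    R <- base_r + 0.25 * disc_soft - 0.06 * vsoft - 0.015 * fovea_soft
    G <- base_g + 0.22 * disc_soft - 0.28 * vsoft - 0.06 * fovea_soft
    B <- base_b + 0.10 * disc_soft - 0.03 * vsoft - 0.015 * fovea_soft
    img <- array(0, c(n, n, 3))
    img[, , 1] <- clamp01((R + stats::rnorm(n * n, 0, noise_sd)) * vig)
    img[, , 2] <- clamp01((G + stats::rnorm(n * n, 0, noise_sd)) * vig)
    img[, , 3] <- clamp01((B + stats::rnorm(n * n, 0, noise_sd)) * vig)

    vp <- if (length(vpts)) do.call(rbind, vpts) else
      matrix(numeric(0), 0, 3)
    colnames(vp) <- c("x", "y", "width_px")
    structure(list(image = img,
                   truth = list(vessel_mask = vmask, vessel_points = vp,
                                disc_center_px = disc,
                                disc_diameter_px = 2 * disc_r_px,
                                fovea_px = fovea),
                   mm_per_px = mm_per_px, seed = seed),
              class = "fundus_phantom")
  })
}

#' Synthetic retinal height map with one lesion
#'
#' Signed surface height on the phantom grid: a Gaussian-profile pit
#' (negative height, e.g. macular hole) or bump (positive, e.g. pigment
#' epithelial detachment), exactly zero outside a 3-sigma support.
#'
#' @param phantom a [generate_phantom()] result (supplies grid and scale).
#' @param type `"pit"` or `"bump"`, or `"flat"` for an all-zero map.
#' @param depth_mm lesion depth (pit) or height (bump), mm, positive.
#' @param radius_mm Gaussian sigma of the lesion profile, mm.
#' @param center_px lesion center (x, y) px; default the fovea.
#' @return object of class `height_map`: `height_mm` matrix plus lesion
#'   descriptors.
#' @export
make_height_map <- function(phantom, type = c("pit", "bump", "flat"),
                            depth_mm = 0.5, radius_mm = 0.5,
                            center_px = NULL) {
  type <- match.arg(type)
  n <- dim(phantom$image)[1]
  if (is.null(center_px)) center_px <- phantom$truth$fovea_px
  h <- matrix(0, n, n)
  if (type != "flat") {
    if (depth_mm <= 0) stopf("depth_mm must be positive")
    s_px <- radius_mm / phantom$mm_per_px
    ax <- seq_len(n)
    d2 <- outer((ax - center_px[2])^2, (ax - center_px[1])^2, "+")
    g <- exp(-d2 / (2 * s_px^2))
    g[d2 > (3 * s_px)^2] <- 0           # hard zero outside lesion support
    h <- (if (type == "pit") -depth_mm else depth_mm) * g
  }
  structure(list(height_mm = h, type = type, depth_mm = depth_mm,
                 radius_mm = radius_mm, center_px = center_px),
            class = "height_map")
}

#' Render an oblique slit-beam observation over a height map
#'
#' Exact forward model of the contour reconstruction: a narrow bright band
#' whose lateral position at each row is displaced by height x tan(angle)
#' (converted to px), toward the illumination arm for elevations and away
#' from it for depressions; the fundus outside the band is dimmed to near
#' invisibility, as through the oculars.
#'
#' @param phantom a [generate_phantom()] result.
#' @param height_map a [make_height_map()] result.
#' @param width_mm slit width on the retina, mm, positive.
#' @param angle_deg arm angle, degrees, in (0, 90).
#' @param arm_side `"right"` or `"left"`.
#' @param lens a [fundus_lens()] (sets the implied aerial-plane
#'   calibration).
#' @param x0_px undisturbed band column; default the lesion center.
#' @param amplitude band peak intensity.
#' @param background_dim multiplier on the non-illuminated fundus.
#' @param noise_sd additive noise sd.
#' @param seed RNG seed for the noise.
#' @return a [slit_observation()] carrying the rendered image, geometry,
#'   calibration and lens; attribute `truth` holds the ground-truth band
#'   center per row in px.
#' @export
render_slit <- function(phantom, height_map, width_mm = 0.2, angle_deg = 5,
                        arm_side = c("right", "left"),
                        lens = fundus_lens(90), x0_px = NULL,
                        amplitude = 0.75, background_dim = 0.15,
                        noise_sd = 0.005, seed = 1) {
  arm_side <- match.arg(arm_side)
  if (width_mm <= 0) stopf("slit width must be positive")
  if (angle_deg <= 0 || angle_deg >= 90) stopf("angle_deg must be in (0, 90)")
  n <- dim(phantom$image)[1]
  if (is.null(x0_px)) x0_px <- height_map$center_px[1]
  g <- phantom$image[, , 2]
  mmpp <- phantom$mm_per_px
  s <- if (arm_side == "right") 1 else -1
  h_line <- height_map$height_mm[, round(x0_px)]
  disp_px <- s * h_line * tan(angle_deg * pi / 180) / mmpp
  xc <- x0_px + disp_px
  sigma_px <- width_mm / mmpp / 2.355          # FWHM = slit width
  X <- matrix(seq_len(n), n, n, byrow = TRUE)
  band <- exp(-0.5 * ((X - xc)^2) / sigma_px^2)
  img <- background_dim * g + amplitude * band * (0.85 + 0.15 * g)
  img <- clamp01(img + with_seed(seed, matrix(stats::rnorm(n * n, 0, noise_sd), n, n)))
  cal <- scale_calibration(lens$mag_factor / mmpp, source = "synthetic")
  obs <- slit_observation(img, angle_deg, arm_side, cal, lens)
  attr(obs, "truth") <- list(center_px = xc, x0_px = x0_px,
                             disp_px = disp_px)
  obs
}

# on-retina mm per degree of eccentricity for a schematic eye
mm_per_degree <- function(eye = schematic_eye()) {
  eye$globe_radius_mm * pi / 180
}

#' Cut gaze-directed tiles with ground-truth placements from a phantom
#'
#' Crops square tiles at the positions of a documentation layout with a
#' configurable angular overlap between neighbours, each carrying its
#' ground-truth placement (translation into the phantom frame) in the
#' sidecar.
#'
#' @param phantom a [generate_phantom()] result.
#' @param layout `"pair"` (2 side-by-side tiles), `"3x3"`, `"ring6"` (6
#'   tiles on a circle), or an n x 2 matrix of tile centers (x, y) px.
#' @param tile_px tile side length, px.
#' @param overlap_deg angular overlap between adjacent tiles, degrees
#'   (converted to px via the schematic eye; the customary minimum is
#'   about 2 degrees).
#' @param field_diameter_deg nominal field diameter stored in each tile.
#' @param eye a [schematic_eye()].
#' @return list of [fundus_tile()] objects; each `truth` transform maps
#'   tile coordinates to phantom-centered coordinates.
#' @export
make_tiles <- function(phantom, layout = "pair", tile_px = 160,
                       overlap_deg = 2, field_diameter_deg = 45,
                       eye = schematic_eye()) {
  if (overlap_deg < 0) stopf("overlap_deg must be >= 0")
  n <- dim(phantom$image)[1]
  ctr <- (n + 1) / 2
  overlap_px <- overlap_deg * mm_per_degree(eye) / phantom$mm_per_px
  spacing <- tile_px - overlap_px
  centers <- if (is.matrix(layout)) layout else switch(layout,
    pair = cbind(ctr + c(-spacing / 2, spacing / 2), c(ctr, ctr)),
    "3x3" = as.matrix(expand.grid(x = ctr + spacing * (-1:1),
                                  y = ctr + spacing * (-1:1)))[, 1:2],
    ring6 = {
      th <- seq(0, 2 * pi, length.out = 7)[-7]
      r <- spacing
      cbind(ctr + r * cos(th), ctr + r * sin(th))
    },
    stopf("unknown layout '%s'", layout))
  half <- tile_px / 2
  if (any(centers[, 1] - half < 0.5) || any(centers[, 1] + half > n + 0.5) ||
      any(centers[, 2] - half < 0.5) || any(centers[, 2] + half > n + 0.5))
    stopf("layout exceeds phantom extent")
  g <- phantom$image[, , 2]
  labels <- if (is.matrix(layout)) sprintf("tile%d", seq_len(nrow(centers)))
    else switch(layout,
      pair = c("center", "temporal"),
      "3x3" = c("up-nasal", "up", "up-temporal", "nasal", "center",
                "temporal", "down-nasal", "down", "down-temporal"),
      ring6 = sprintf("ring%d", 1:6))
  lapply(seq_len(nrow(centers)), function(i) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    # integer-aligned crop so tiles are exact sub-rasters of the phantom
    x1 <- round(cx - half); y1 <- round(cy - half)
    tile_img <- g[y1:(y1 + tile_px - 1), x1:(x1 + tile_px - 1)]
    truth <- rigid_transform(dx_px = x1 + (tile_px - 1) / 2 - ctr,
                             dy_px = y1 + (tile_px - 1) / 2 - ctr)
    fundus_tile(tile_img, gaze_label = labels[i],
                field_diameter_deg = field_diameter_deg, truth = truth)
  })
}

#' Generate a jittered, blurred, blink-containing fundus video
#'
#' Frame sequence emulating hand-held fundus video: per-frame random
#' translation of the phantom (fixation jitter), per-frame Gaussian blur
#' following a schedule (defocus episodes), and near-black blink frames.
#' The indices of the declared-sharp frames are recorded as ground truth.
#'
#' @param phantom a [generate_phantom()] result.
#' @param n_frames number of frames, >= 1.
#' @param jitter_px maximum absolute per-frame translation, px; drawn as
#'   whole pixels so resampling does not add blur of its own and declared
#'   sharp frames are exactly equally sharp.
#' @param blur_schedule numeric vector (recycled) of Gaussian blur sigmas
#'   per frame; 0 = sharp.  Default mixes sharp and defocused frames.
#' @param blink_frames integer indices rendered as blinks.
#' @param noise_sd per-frame additive noise sd.
#' @param seed RNG seed.
#' @return list `frames` (list of grayscale matrices), `truth`
#'   (data.frame: frame, blur_sigma, blink, dx_px, dy_px, sharp), `seed`.
#' @export
make_video <- function(phantom, n_frames = 50, jitter_px = 3,
                       blur_schedule = NULL, blink_frames = integer(0),
                       noise_sd = 0.005, seed = 1) {
  if (n_frames < 1) stopf("n_frames must be >= 1")
  if (is.null(blur_schedule))
    blur_schedule <- rep(c(0, 1, 2, 3, 2), length.out = n_frames)
  sigma <- rep(blur_schedule, length.out = n_frames)
  blink <- seq_len(n_frames) %in% blink_frames
  g <- phantom$image[, , 2]
  n <- nrow(g)
  # central crop margin removes the undefined border the jitter drags in,
  # so frame sharpness reflects content, not warp edges
  margin <- ceiling(jitter_px) + 1
  keep <- (margin + 1):(n - margin)
  with_seed(seed, {
    dx <- round(stats::runif(n_frames, -jitter_px, jitter_px))
    dy <- round(stats::runif(n_frames, -jitter_px, jitter_px))
    frames <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      f <- warp_rigid(g, rigid_transform(dx[i], dy[i]), fill = 0)
      if (sigma[i] > 0) f <- as.matrix(EBImage::gblur(f, sigma[i]))
      f <- f[keep, keep]
      if (blink[i]) f <- f * 0.05
      frames[[i]] <- clamp01(f + matrix(stats::rnorm(length(keep)^2, 0, noise_sd),
                                        length(keep), length(keep)))
    }
    truth <- data.frame(frame = seq_len(n_frames), blur_sigma = sigma,
                        blink = blink, dx_px = dx, dy_px = dy,
                        sharp = sigma == 0 & !blink)
    list(frames = frames, truth = truth, seed = seed)
  })
}

#' Generate a longitudinal change pair with ground truth
#'
#' Two green-channel images of the same fundus differing only inside a
#' known change region: a local vessel displacement, a growing bright
#' atrophic patch, or a dark hemorrhage.  Pixels outside the change mask
#' are bitwise identical between the two images.
#'
#' @param phantom a [generate_phantom()] result.
#' @param type `"vessel_shift"` (content inside the region displaced by
#'   `magnitude` px), `"atrophy_growth"` (brightening, `magnitude` =
#'   intensity step), or `"hemorrhage"` (darkening).
#' @param magnitude change magnitude, > 0 (px for vessel_shift, intensity
#'   for the others).
#' @param center_px region center (x, y); default a vessel point near the
#'   image center (vessel_shift) or the fovea.
#' @param region_radius_px radius of the change region.
#' @param direction unit-ish vector of the vessel shift.
#' @return list `before`, `after` (matrices), `change_mask` (logical),
#'   `landmarks` (data.frame x, y, dx_px, dy_px on ground-truth displaced
#'   structure; empty for intensity-only changes), `type`, `magnitude`.
#' @export
make_change_pair <- function(phantom,
                             type = c("vessel_shift", "atrophy_growth",
                                      "hemorrhage"),
                             magnitude = 2, center_px = NULL,
                             region_radius_px = 40, direction = c(1, 0)) {
  type <- match.arg(type)
  if (!is.numeric(magnitude) || magnitude <= 0)
    stopf("magnitude must be > 0")
  before <- phantom$image[, , 2]
  n <- nrow(before)
  if (is.null(center_px)) {
    vp <- phantom$truth$vessel_points
    if (type == "vessel_shift" && nrow(vp) > 0) {
      d2 <- (vp[, 1] - n / 2)^2 + (vp[, 2] - n / 2)^2
      center_px <- vp[which.min(d2), 1:2]
    } else center_px <- phantom$truth$fovea_px
  }
  ax <- seq_len(n)
  d2 <- outer((ax - center_px[2])^2, (ax - center_px[1])^2, "+")
  mask <- d2 <= region_radius_px^2
  after <- before
  landmarks <- data.frame(x = numeric(0), y = numeric(0),
                          dx_px = numeric(0), dy_px = numeric(0))
  if (type == "vessel_shift") {
    dirv <- direction / sqrt(sum(direction^2)) * magnitude
    idx <- which(mask, arr.ind = TRUE)        # (row, col)
    src_x <- idx[, 2] - dirv[1]
    src_y <- idx[, 1] - dirv[2]
    cc <- center_coords(dim(before))
    after[idx] <- bilinear_sample(before, src_x - cc$x0, src_y - cc$y0,
                                  fill = 0)
    vp <- phantom$truth$vessel_points
    if (nrow(vp) > 0) {
      inside <- (vp[, 1] - center_px[1])^2 + (vp[, 2] - center_px[2])^2 <=
        (region_radius_px * 0.5)^2
      pts <- vp[inside, , drop = FALSE]
      if (nrow(pts) > 5) pts <- pts[seq(1, nrow(pts), length.out = 5), , drop = FALSE]
      if (nrow(pts) > 0)
        landmarks <- data.frame(x = pts[, 1], y = pts[, 2],
                                dx_px = dirv[1], dy_px = dirv[2])
    }
  } else {
    soft <- clamp01((region_radius_px - sqrt(d2)) / (0.3 * region_radius_px))
    delta <- magnitude * soft
    after <- if (type == "atrophy_growth") clamp01(before + delta * mask)
             else clamp01(before - delta * mask)
  }
  list(before = before, after = after, change_mask = mask,
       landmarks = landmarks, type = type, magnitude = magnitude,
       center_px = center_px)
}

#' Synthetic ruler image for scale calibration
#'
#' Evenly spaced dark ruled lines on a light background, optionally
#' rotated, with additive noise; the known line spacing is the calibration
#' ground truth.
#'
#' @param spacing_px line spacing, px.
#' @param n_lines number of lines.
#' @param size_px image side length.
#' @param line_width_px line thickness.
#' @param angle_deg ruler rotation.
#' @param noise_sd additive noise sd.
#' @param seed RNG seed.
#' @return grayscale matrix.
#' @export
generate_ruler <- function(spacing_px = 20, n_lines = 9, size_px = 220,
                           line_width_px = 3, angle_deg = 0,
                           noise_sd = 0.01, seed = 1) {
  img <- matrix(0.9, size_px, size_px)
  x0 <- (size_px - (n_lines - 1) * spacing_px) / 2
  X <- matrix(seq_len(size_px), size_px, size_px, byrow = TRUE)
  for (k in seq_len(n_lines)) {
    xk <- x0 + (k - 1) * spacing_px
    img[abs(X - xk) <= line_width_px / 2] <- 0.15
  }
  if (angle_deg != 0) {
    img <- warp_rigid(img, rigid_transform(theta_deg = angle_deg), fill = NA)
    img[!is.finite(img)] <- 0.9
  }
  clamp01(img + with_seed(seed,
    matrix(stats::rnorm(size_px^2, 0, noise_sd), size_px, size_px)))
}

#' Write an image to PNG
#' @param img grayscale matrix or RGB array in \[0, 1\].
#' @param path output path.
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp01(img), path)
  invisible(path)
}
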