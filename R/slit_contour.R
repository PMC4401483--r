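#' Oblique slit-beam observation
#'
#' A single frame showing one narrow bright slit band projected onto the
#' fundus with a small angle between the illumination and observation arms.
#' Run over a depression (e.g. a macular hole) the band deflects away from
#' the side of the illumination arm; over an elevation (tumour, pigment
#' epithelial detachment, large drusen) it deflects toward it.  All
#' coordinates are in the viewed (inverted) frame as seen through the
#' oculars, the convention in which fundus video is normally kept.
#'
#' @param image grayscale matrix containing one bright, roughly vertical
#'   band.
#' @param angle_deg angle between illumination and observation arms,
#'   degrees, in (0, 90).
#' @param arm_side side of the viewed image the illumination arm is on,
#'   `"left"` or `"right"`.
#' @param cal a [scale_calibration()].
#' @param lens a [fundus_lens()].
#' @param viewed_frame flag that coordinates are in the inverted
#'   through-the-oculars frame (the default and the frame all analysis
#'   runs in).
#' @export
slit_observation <- function(image, angle_deg, arm_side = c("right", "left"),
                             cal, lens, viewed_frame = TRUE) {
  assert_image(image)
  if (!is.numeric(angle_deg) || angle_deg <= 0 || angle_deg >= 90)
    stopf("invalid geometry: angle_deg must be in (0, 90)")
  arm_side <- match.arg(arm_side)
  structure(list(image = image, angle_deg = angle_deg, arm_side = arm_side,
                 cal = cal, lens = lens, viewed_frame = viewed_frame),
            class = "slit_observation")
}

#' Detect the subpixel centerline of a slit band
#'
#' For each row intersecting the band, the intensity-weighted centroid of
#' the pixels above a contrast threshold gives the band position to
#' subpixel precision.
#'
#' @param obs a [slit_observation()] (or a bare grayscale matrix).
#' @param threshold_frac band threshold as a fraction of the row's dynamic
#'   range above background.
#' @param min_contrast minimum image dynamic range; below it no band is
#'   declared.
#' @param max_gap_px candidate clusters further apart than this in one row
#'   raise an ambiguity error (two bands in frame).
#' @return numeric vector, one entry per row: centerline x-position in px
#'   (NA where the band does not cross the row).
#' @export
detect_centerline <- function(obs, threshold_frac = 0.5,
                              min_contrast = 0.08, max_gap_px = 30) {
  img <- if (inherits(obs, "slit_observation")) obs$image else obs
  assert_image(img)
  bg <- stats::quantile(img, 0.25)
  top <- max(img)
  if (top - bg < min_contrast)
    stopf("no slit band detected: image contrast %.3f below %.3f",
          top - bg, min_contrast)
  thr <- bg + threshold_frac * (top - bg)
  nr <- nrow(img)
  ctr <- rep(NA_real_, nr)
  for (r in seq_len(nr)) {
    row <- img[r, ]
    idx <- which(row > thr)
    if (length(idx) < 2) next
    if (max(diff(idx)) > max_gap_px)
      stopf("ambiguous slit detection: multiple bands in row %d (candidate columns around %s)",
            r, paste(round(stats::quantile(idx, c(0, 1))), collapse = " and "))
    w <- row[idx] - thr
    ctr[r] <- sum(idx * w) / sum(w)
  }
  if (all(is.na(ctr))) stopf("no slit band detected in any row")
  ctr
}

#' Fit the undisturbed reference line of a slit band
#'
#' Robust straight-line fit (least absolute deviations) to the centerline
#' over rows outside the lesion region; the fitted line is the course the
#' slit would take over locally flat retina.
#'
#' @param centerline output of [detect_centerline()].
#' @param exclusion_mask logical vector, `TRUE` for rows to exclude from
#'   the fit (the lesion region); `NULL` for none.
#' @param min_support minimum number of usable rows outside the exclusion.
#' @return numeric vector of baseline x per row, with attribute `coef`
#'   (intercept, slope in x-per-row).
#' @export
fit_baseline <- function(centerline, exclusion_mask = NULL, min_support = 20) {
  n <- length(centerline)
  if (is.null(exclusion_mask)) exclusion_mask <- rep(FALSE, n)
  use <- !exclusion_mask & !is.na(centerline)
  if (sum(use) < min_support)
    stopf("baseline error: only %d support rows outside the exclusion region (need %d)",
          sum(use), min_support)
  rows <- seq_len(n)
  cf <- l1_line_fit(rows[use], centerline[use])
  base <- cf["intercept"] + cf["slope"] * rows
  attr(base, "coef") <- cf
  base
}

#' Convert slit deflection to surface height
#'
#' The optic section applied to the retina: a lateral band deflection d at
#' arm angle theta corresponds to a surface height h = d / tan(theta).
#' Deflection toward the illumination arm means elevation (positive
#' height), away from it depression (negative height, e.g. a macular
#' hole).
#'
#' @param deflection_mm signed deflection on the retina, mm; positive
#'   toward the illumination arm side.
#' @param angle_deg arm angle, degrees, in (0, 90).
#' @return signed height, mm (negative = depression).
#' @export
height_from_deflection <- function(deflection_mm, angle_deg) {
  if (!is.numeric(angle_deg) || angle_deg <= 0 || angle_deg >= 90)
    stopf("invalid geometry: angle_deg must be in (0, 90)")
  deflection_mm / tan(angle_deg * pi / 180)
}

# auto-detection of the lesion region when the examiner supplies none:
# largest contiguous run of absolute baseline residuals above 3x their MAD
auto_exclusion <- function(centerline, n_pass = 2) {
  n <- length(centerline)
  excl <- rep(FALSE, n)
  for (i in seq_len(n_pass)) {
    base <- tryCatch(fit_baseline(centerline, excl),
                     error = function(e) return(NULL))
    if (is.null(base)) break
    r <- abs(centerline - base)
    madr <- stats::mad(r[!excl], na.rm = TRUE)
    if (!is.finite(madr) || madr == 0) madr <- 1e-3
    hot <- !is.na(r) & r > 3 * madr
    runs <- rle(hot)
    if (!any(runs$values)) break
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    k <- which(runs$values)[which.max(runs$lengths[runs$values])]
    excl[starts[k]:ends[k]] <- TRUE
  }
  excl
}

#' Reconstruct the surface height profile along a slit
#'
#' Full pipeline over one oblique slit observation: centerline detection,
#' robust baseline fit over the undisturbed rows, pixel-to-retinal-mm
#' conversion via the scale calibration and lens magnification, and
#' deflection-to-height triangulation with the sign fixed by the arm side.
#'
#' @param obs a [slit_observation()].
#' @param exclusion_mask logical per-row lesion mask for the baseline fit;
#'   `NULL` auto-detects the largest run of outlier residuals.
#' @param smooth_k odd window of a running-median filter applied to the
#'   centerline along the band (suppresses localized centroid spikes where
#'   vessels cross the slit); 1 disables.
#' @param ... passed to [detect_centerline()].
#' @return object of class `height_profile`: data.frame-like list with
#'   `position_mm` (arc position along the slit), `height_mm` (signed,
#'   negative = depression), `valid`, plus `deflection_mm`, `angle_deg`,
#'   `arm_side`.
#' @export
reconstruct_profile <- function(obs, exclusion_mask = NULL, smooth_k = 15, ...) {
  if (!inherits(obs, "slit_observation")) stopf("obs must be a slit_observation")
  ctr <- detect_centerline(obs, ...)
  if (smooth_k > 1) {
    v <- !is.na(ctr)
    if (sum(v) > smooth_k) ctr[v] <- stats::runmed(ctr[v], smooth_k)
  }
  if (is.null(exclusion_mask)) exclusion_mask <- auto_exclusion(ctr)
  base <- fit_baseline(ctr, exclusion_mask)
  defl_px <- ctr - base
  # deflection in the viewed frame (positive = rightward); its sign flips
  # with the arm side, the reconstructed height's does not
  defl_mm <- sign(defl_px) * retinal_length(abs(defl_px), obs$cal, obs$lens)
  toward_arm_mm <- if (obs$arm_side == "right") defl_mm else -defl_mm
  height <- height_from_deflection(toward_arm_mm, obs$angle_deg)
  rows <- seq_along(ctr)
  pos_mm <- retinal_length(rows - 1, obs$cal, obs$lens)
  structure(list(position_mm = pos_mm, height_mm = height,
                 deflection_mm = defl_mm, valid = !is.na(ctr),
                 angle_deg = obs$angle_deg, arm_side = obs$arm_side),
            class = "height_profile")
}

#' Depth and lateral extent of a lesion in a height profile
#'
#' Depth is the magnitude of the deepest point below the reference level;
#' extent is the arc distance between the outermost crossings of a
#' threshold set at a fraction of that depth (the "bird's eye" width of
#' the lesion, which for a bulging-edged macular hole can be smaller than
#' its true anatomical extent).
#'
#' @param profile a `height_profile`.
#' @param threshold_frac extent threshold as a fraction of peak depth.
#' @param min_depth_mm below this depth the profile is reported as
#'   lesion-free.
#' @return list `depth_mm`, `extent_mm`, `lesion` (logical flag).
#' @export
lesion_metrics <- function(profile, threshold_frac = 0.1,
                           min_depth_mm = 0.02) {
  h <- profile$height_mm
  ok <- profile$valid & !is.na(h)
  if (!any(ok)) return(list(depth_mm = 0, extent_mm = 0, lesion = FALSE))
  depth <- -min(h[ok])
  if (!is.finite(depth) || depth < min_depth_mm)
    return(list(depth_mm = 0, extent_mm = 0, lesion = FALSE))
  thr <- -threshold_frac * depth
  below <- which(ok & h < thr)
  extent <- profile$position_mm[max(below)] - profile$position_mm[min(below)]
  list(depth_mm = depth, extent_mm = extent, lesion = TRUE)
}

#' Write a height profile as CSV
#' @param profile a `height_profile`.
#' @param file output CSV path.
#' @export
write_profile <- function(profile, file) {
  utils::write.csv(data.frame(position_mm = profile$position_mm,
                              height_mm = profile$height_mm,
                              valid = profile$valid),
                   file, row.names = FALSE)
  invisible(file)
}
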