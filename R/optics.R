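#' Hand-held converging fundus lens
#'
#' Constructs a `fundus_lens` object for a hand-held converging lens
#' (indirect fundus biomicroscopy).  The manufacturer fundus-magnification
#' factor m relates aerial-image size to true retinal size
#' (aerial = m x retinal) for an emmetropic schematic eye.  For the standard
#' lens collection the printed catalog values are m = 0.75 (+90 D),
#' 1.15 (+60 D) and 1.67 (+40 D); other powers get a fitted factor from the
#' reciprocal-proportionality rule (see [mag_factor()]) and are flagged
#' `catalog = FALSE`.
#'
#' @param power refractive power in diopters, positive.
#' @param mag_factor optional explicit magnification factor; by default
#'   looked up or fitted from `power`.
#' @return object of class `fundus_lens` with fields `power`, `mag_factor`,
#'   `catalog`.
#' @examples
#' fundus_lens(90)$mag_factor   # 0.75, catalog value
#' fundus_lens(55)$mag_factor   # ~1.23, fitted
#' @export
fundus_lens <- function(power, mag_factor = NULL) {
  if (!is.numeric(power) || length(power) != 1L || !is.finite(power) || power <= 0)
    stopf("lens power must be a single positive number of diopters")
  if (is.null(mag_factor)) {
    mf <- mag_factor(power)
    m <- mf$mag_factor
    catalog <- mf$catalog
  } else {
    if (mag_factor <= 0) stopf("mag_factor must be positive")
    m <- mag_factor
    catalog <- FALSE
  }
  structure(list(power = power, mag_factor = m, catalog = catalog),
            class = "fundus_lens")
}

#' @export
print.fundus_lens <- function(x, ...) {
  cat(sprintf("<fundus_lens> +%gD, m = %.3f (%s)\n", x$power, x$mag_factor,
              if (x$catalog) "catalog" else "fitted"))
  invisible(x)
}

# catalog triple: manufacturer magnification factors
.lens_catalog <- data.frame(power = c(90, 60, 40),
                            mag   = c(0.75, 1.15, 1.67))

# least-squares constant of the reciprocal-proportionality rule m = c / P,
# fitted once to the three catalog points
.lens_fit_constant <- local({
  p <- .lens_catalog$power; m <- .lens_catalog$mag
  sum(m / p) / sum(1 / p^2)
})

#' Fundus magnification factor for a lens power
#'
#' Returns the manufacturer catalog factor for +90/+60/+40 D.  For any other
#' power the factor follows the reciprocal-proportionality rule 1/m = P / c
#' (image magnification 1/m is directly proportional to lens power), with c
#' the least-squares constant fitted to the three catalog points; such
#' values are flagged `catalog = FALSE`.  The fit reproduces every catalog
#' factor within 3%.
#'
#' @param power lens power in diopters, positive.
#' @return list with `mag_factor` and logical `catalog`.
#' @export
mag_factor <- function(power) {
  if (!is.numeric(power) || length(power) != 1L || !is.finite(power) || power <= 0)
    stopf("lens power must be a single positive number of diopters")
  hit <- match(power, .lens_catalog$power)
  if (!is.na(hit))
    return(list(mag_factor = .lens_catalog$mag[hit], catalog = TRUE))
  list(mag_factor = .lens_fit_constant / power, catalog = FALSE)
}

#' Schematic eye model
#'
#' Reduced emmetropic schematic eye used for magnification and coverage
#' geometry: 24 mm axial length, 12 mm globe radius.  `retina_halfangle_deg`
#' is the angular half-extent of the retina from the posterior pole as seen
#' from the globe center; the default 117 degrees puts the ora serrata so
#' that the retina covers about 73% of the globe.
#'
#' @param axial_length_mm axial length, mm.
#' @param refraction_D spherical-equivalent refraction in diopters
#'   (0 = emmetropic, positive = hyperopic).
#' @param globe_radius_mm globe radius, mm.
#' @param retina_halfangle_deg retinal half-extent, degrees, in (0, 180\].
#' @export
schematic_eye <- function(axial_length_mm = 24, refraction_D = 0,
                          globe_radius_mm = 12, retina_halfangle_deg = 117) {
  if (axial_length_mm <= 0) stopf("axial_length_mm must be positive")
  if (globe_radius_mm <= 0) stopf("globe_radius_mm must be positive")
  if (retina_halfangle_deg <= 0 || retina_halfangle_deg > 180)
    stopf("retina_halfangle_deg must be in (0, 180]")
  structure(list(axial_length_mm = axial_length_mm,
                 refraction_D = refraction_D,
                 globe_radius_mm = globe_radius_mm,
                 retina_halfangle_deg = retina_halfangle_deg),
            class = "schematic_eye")
}

#' Pixel scale calibration at the aerial image plane
#'
#' Holds the pixel density of the captured image measured with a linear
#' scale held in front of the slit-lamp objective, i.e. at the plane of the
#' aerial fundus image.  All on-retina metrology requires one.
#'
#' @param px_per_mm_aerial pixels per millimetre at the aerial image plane.
#' @param source identifier of the calibration image.
#' @export
scale_calibration <- function(px_per_mm_aerial, source = "unspecified") {
  if (!is.numeric(px_per_mm_aerial) || length(px_per_mm_aerial) != 1L ||
      !is.finite(px_per_mm_aerial) || px_per_mm_aerial <= 0)
    stopf("px_per_mm_aerial must be a single positive number")
  structure(list(px_per_mm_aerial = px_per_mm_aerial, source = source),
            class = "scale_calibration")
}

#' Diameter of an illuminated aperture field projected onto the retina
#'
#' The illuminated field visible through the oculars has the size of the
#' chosen aperture; its projection on the retina scales with the reciprocal
#' of the lens magnification factor, so stronger lenses illuminate a larger
#' fundus area.  Projecting the 3.5 mm circular aperture gives on-retina
#' diameters of 4.7 mm (+90 D), 3.0 mm (+60 D) and 2.1 mm (+40 D).
#'
#' @param aperture_mm aperture diameter in mm, non-negative.
#' @param lens a [fundus_lens()].
#' @param round if `TRUE`, round to one decimal (half-up), the convention
#'   used for reported mm values.
#' @return diameter on the retina, mm.
#' @export
projected_aperture_diameter <- function(aperture_mm, lens, round = FALSE) {
  if (!is.numeric(aperture_mm) || any(aperture_mm < 0))
    stopf("aperture_mm must be non-negative")
  d <- aperture_mm / lens$mag_factor
  if (round) round_half_up(d, 1) else d
}

#' Convert an on-screen pixel distance to millimetres on the retina
#'
#' The captured image lives at the aerial image plane; dividing by the
#' calibrated pixel density gives aerial mm, and multiplying by the lens
#' magnification factor converts aerial mm to true retinal mm.
#'
#' @param px distance in pixels, non-negative.
#' @param cal a [scale_calibration()]; an explicit error is raised when
#'   missing, a raw pixel value is never returned silently.
#' @param lens a [fundus_lens()].
#' @return length on the retina, mm.
#' @export
retinal_length <- function(px, cal, lens) {
  if (missing(cal) || is.null(cal) || !inherits(cal, "scale_calibration"))
    stopf("uncalibrated: retinal metrology requires a scale_calibration")
  if (any(px < 0)) stopf("px must be non-negative")
  (px / cal$px_per_mm_aerial) * lens$mag_factor
}

#' Convert a pixel area to square millimetres on the retina
#'
#' Area scales with the square of the length conversion.
#'
#' @param px2 area in pixels^2, non-negative.
#' @inheritParams retinal_length
#' @return area on the retina, mm^2.
#' @export
retinal_area <- function(px2, cal, lens) {
  if (missing(cal) || is.null(cal) || !inherits(cal, "scale_calibration"))
    stopf("uncalibrated: retinal metrology requires a scale_calibration")
  if (any(px2 < 0)) stopf("px2 must be non-negative")
  px2 * (lens$mag_factor / cal$px_per_mm_aerial)^2
}

#' Calibrate the pixel scale from an image of a linear scale
#'
#' Detects the dark ruled lines of a linear scale (ruler) imaged in front of
#' the slit-lamp objective and returns the pixel density at that plane.
#' Robust to moderate rotation of the ruler: the line direction is found by
#' maximizing the variance of the projection profile over candidate angles,
#' line centers are localized to subpixel precision by intensity-weighted
#' centroids, and the spacing is the median inter-line distance.
#'
#' @param image grayscale matrix of the ruler, dark lines on a light
#'   background, at least 3 lines.
#' @param line_spacing_mm known spacing of the ruled lines, mm.
#' @param angle_range_deg half-range of ruler rotations searched, degrees.
#' @param source identifier stored in the calibration.
#' @return a [scale_calibration()].
#' @export
calibrate_scale <- function(image, line_spacing_mm, angle_range_deg = 10,
                            source = "ruler") {
  assert_image(image, "calibration image")
  if (line_spacing_mm <= 0) stopf("line_spacing_mm must be positive")

  profile_var <- function(theta_deg) {
    rot <- warp_rigid(image, rigid_transform(theta_deg = theta_deg), fill = NA)
    stats::var(colMeans(rot, na.rm = TRUE), na.rm = TRUE)
  }
  coarse <- seq(-angle_range_deg, angle_range_deg, by = 1)
  v <- vapply(coarse, profile_var, numeric(1))
  best <- coarse[which.max(v)]
  fine <- seq(best - 1, best + 1, by = 0.2)
  vf <- vapply(fine, profile_var, numeric(1))
  theta <- fine[which.max(vf)]

  rot <- warp_rigid(image, rigid_transform(theta_deg = theta), fill = NA)
  prof <- colMeans(rot, na.rm = TRUE)
  prof <- prof[is.finite(prof)]
  # dark lines = peaks of the inverted profile above half its dynamic range
  inv <- max(prof) - prof
  thr <- 0.5 * max(inv)
  above <- inv > thr
  if (!any(above) || max(inv) < 1e-3)
    stopf("calibration failure: no ruled lines detected")
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  centers <- numeric(0)
  for (i in which(runs$values)) {
    idx <- starts[i]:ends[i]
    centers <- c(centers, sum(idx * inv[idx]) / sum(inv[idx]))
  }
  if (length(centers) < 3)
    stopf("calibration failure: %d ruled lines detected, need at least 3",
          length(centers))
  spacing_px <- stats::median(diff(sort(centers)))
  scale_calibration(spacing_px / line_spacing_mm, source = source)
}

# printed drawback anchors: extra working distance (cm) the slit lamp must
# retreat, vs anterior segment focus, to reach the aerial image
.drawback_anchors <- data.frame(power = c(90, 60, 40, 20),
                                cm    = c(3, 4, 6, 10))

# affine fit of drawback distance to focal length (cm), least squares over
# the four printed anchors; reproduces each anchor within 0.4 cm
.drawback_fit <- local({
  f <- 100 / .drawback_anchors$power
  stats::coef(stats::lm(.drawback_anchors$cm ~ f))
})

#' Slit-lamp drawback distance for a fundus lens
#'
#' Extra distance (vs anterior-segment focus) between the patient's eye and
#' the slit-lamp objective needed to focus the aerial fundus image: 3 cm for
#' +90 D, 4 cm for +60 D, 6 cm for +40 D, 10 cm for +20 D.  Other powers in
#' the supported range are interpolated by an affine fit in focal length
#' (f = 1000/power mm) and flagged `fitted`.
#'
#' @param lens a [fundus_lens()] with power in \[20, 120\] D.
#' @return list with `cm` and logical `fitted`.
#' @export
drawback_distance <- function(lens) {
  p <- lens$power
  if (p < 20 || p > 120)
    stopf("unsupported lens: drawback model covers 20-120 D, got %g D", p)
  hit <- match(p, .drawback_anchors$power)
  if (!is.na(hit)) return(list(cm = .drawback_anchors$cm[hit], fitted = FALSE))
  f_cm <- 100 / p
  list(cm = unname(.drawback_fit[1] + .drawback_fit[2] * f_cm), fitted = TRUE)
}

#' Ametropia magnification correction
#'
#' First-order vergence correction for refractive error: a hyperopic eye
#' (positive spherical equivalent) shows the fundus at slightly higher
#' magnification, a myopic eye at lower.  The multiplicative factor applied
#' to magnification-dependent measurements is P / (P - R) with lens power P
#' and refraction R; it equals 1 for emmetropia and its deviation from 1
#' shrinks with stronger lenses and smaller refractive errors.  The
#' magnitude is a first-order approximation, not a calibrated per-lens
#' curve.
#'
#' @param eye a [schematic_eye()] with |refraction_D| <= 15.
#' @param lens a [fundus_lens()].
#' @return dimensionless correction factor.
#' @export
ametropia_factor <- function(eye, lens) {
  r <- eye$refraction_D
  if (abs(r) > 15) stopf("|refraction_D| must be <= 15 D")
  lens$power / (lens$power - r)
}

#' Export metrology measurements as a CSV-ready data frame
#'
#' Converts labelled pixel measurements to retinal mm with provenance
#' columns, the table written next to clinical reports.
#'
#' @param labels character vector naming each measurement.
#' @param px pixel distances.
#' @param cal a [scale_calibration()] or `NULL` (uncalibrated rows carry
#'   `NA` mm and `calibrated = FALSE`).
#' @param lens a [fundus_lens()].
#' @param file optional path; when given the table is also written as CSV.
#' @return data.frame with columns label, px, mm, lens_power, mag_factor,
#'   calibrated.
#' @export
metrology_table <- function(labels, px, cal, lens, file = NULL) {
  calibrated <- !is.null(cal) && inherits(cal, "scale_calibration")
  mm <- if (calibrated) retinal_length(px, cal, lens) else rep(NA_real_, length(px))
  df <- data.frame(label = labels, px = px, mm = mm,
                   lens_power = lens$power, mag_factor = lens$mag_factor,
                   calibrated = calibrated)
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
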