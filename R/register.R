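#' Rigid (+ optional isotropic scale) planar transform
#'
#' Maps moving-image coordinates to reference coordinates, both taken
#' relative to the image center in pixels: x_ref = s R(theta) x_mov + t.
#' Positive `theta_deg` rotates x toward y (clockwise on screen, y points
#' down).
#'
#' @param dx_px,dy_px translation, px.
#' @param theta_deg rotation, degrees.
#' @param scale isotropic scale, positive; fixed at 1 unless scale
#'   estimation is explicitly enabled.
#' @export
rigid_transform <- function(dx_px = 0, dy_px = 0, theta_deg = 0, scale = 1) {
  if (scale <= 0) stopf("scale must be positive")
  structure(list(dx_px = unname(dx_px), dy_px = unname(dy_px),
                 theta_deg = unname(theta_deg), scale = unname(scale)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> dx = %.3f px, dy = %.3f px, theta = %.3f deg, scale = %.4f\n",
              x$dx_px, x$dy_px, x$theta_deg, x$scale))
  invisible(x)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @export
invert_transform <- function(tf) {
  th <- -tf$theta_deg * pi / 180
  s <- 1 / tf$scale
  # x_mov = s' R(-theta) (x_ref - t)
  dx <- -s * (cos(th) * tf$dx_px - sin(th) * tf$dy_px)
  dy <- -s * (sin(th) * tf$dx_px + cos(th) * tf$dy_px)
  rigid_transform(dx, dy, -tf$theta_deg, s)
}

#' Compose two rigid transforms (apply `b` first, then `a`)
#' @param a,b [rigid_transform()] objects.
#' @export
compose_transforms <- function(a, b) {
  th <- a$theta_deg * pi / 180
  dx <- a$scale * (cos(th) * b$dx_px - sin(th) * b$dy_px) + a$dx_px
  dy <- a$scale * (sin(th) * b$dx_px + cos(th) * b$dy_px) + a$dy_px
  rigid_transform(dx, dy, a$theta_deg + b$theta_deg, a$scale * b$scale)
}

#' Warp an image with a rigid transform
#'
#' Resamples `img` into the reference frame of `tf` (bilinear
#' interpolation), so that `apply_transform(img, tf)` aligns with the
#' reference image `tf` was estimated against.
#'
#' @param img grayscale matrix.
#' @param tf a [rigid_transform()].
#' @param dims output dimensions (rows, cols), default those of `img`.
#' @param fill value for pixels sampled outside `img`.
#' @export
apply_transform <- function(img, tf, dims = dim(img), fill = 0) {
  assert_image(img)
  warp_rigid(img, tf, dims = dims, fill = fill)
}

# circular cross-correlation of two equally sized, zero-padded images;
# returns the integer shift (dx, dy) moving b onto a plus the peak map
xcorr_shift <- function(a, b) {
  nr <- nrow(a) * 2L; ncl <- ncol(a) * 2L
  pa <- matrix(0, nr, ncl); pb <- matrix(0, nr, ncl)
  pa[seq_len(nrow(a)), seq_len(ncol(a))] <- a - mean(a)
  pb[seq_len(nrow(b)), seq_len(ncol(b))] <- b - mean(b)
  cc <- Re(stats::fft(stats::fft(pa) * Conj(stats::fft(pb)), inverse = TRUE))
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # unwrap: shift s means b displaced by s matches a
  dy <- peak[1] - 1L; if (dy > nr / 2) dy <- dy - nr
  dx <- peak[2] - 1L; if (dx > ncl / 2) dx <- dx - ncl
  # subpixel: separable parabolic fit around the peak
  get_cc <- function(r, c) cc[(r %% nr) + 1L, (c %% ncl) + 1L]
  r0 <- peak[1] - 1L; c0 <- peak[2] - 1L
  denom_y <- get_cc(r0 - 1, c0) - 2 * get_cc(r0, c0) + get_cc(r0 + 1, c0)
  denom_x <- get_cc(r0, c0 - 1) - 2 * get_cc(r0, c0) + get_cc(r0, c0 + 1)
  sub_y <- if (denom_y < 0) 0.5 * (get_cc(r0 - 1, c0) - get_cc(r0 + 1, c0)) / denom_y else 0
  sub_x <- if (denom_x < 0) 0.5 * (get_cc(r0, c0 - 1) - get_cc(r0, c0 + 1)) / denom_x else 0
  list(dx = dx + sub_x, dy = dy + sub_y, peak = max(cc))
}

# normalized correlation of the overlap after warping mov by tf onto ref
overlap_score <- function(ref, mov, tf) {
  w <- apply_transform(mov, tf, fill = NA)
  ok <- is.finite(w)
  if (sum(ok) < 64) return(-1)
  suppressWarnings(stats::cor(ref[ok], w[ok]))
}

# photometric normalization applied before correlation: the standard
# documentation enhancement (contrast up, brightness down) followed by
# zero-mean scaling
prep_for_corr <- function(img, contrast_gain = 1.2, brightness_offset = -0.1) {
  x <- enhance(img, contrast_gain, brightness_offset)
  x - mean(x)
}

#' Estimate the rigid transform aligning two fundus images
#'
#' Automates the geometric alignment step of the flicker test: a
#' coarse-to-fine search over rotation (and optionally isotropic scale in
#' \[0.9, 1.1\]) with FFT cross-correlation for translation at each
#' candidate, subpixel refinement by parabolic interpolation, and a final
#' robust translation polish from per-block correlations with the worst 20%
#' of blocks discarded (so changed tissue cannot drag the global fit).
#' Images are photometrically normalized before correlation.
#'
#' @param ref,mov grayscale matrices of the same size with overlapping
#'   content.
#' @param allow_scale estimate isotropic scale as well (default fixed 1,
#'   since follow-up sessions use the same lens and magnification).
#' @param max_rotation_deg half-range of the rotation search, degrees.
#' @param min_correlation registration fails below this normalized overlap
#'   correlation (images likely show different regions).
#' @return a [rigid_transform()] with attributes `score` (overlap
#'   correlation) and `residual` (RMS intensity difference in the overlap).
#' @export
estimate_rigid <- function(ref, mov, allow_scale = FALSE,
                           max_rotation_deg = 6, min_correlation = 0.3) {
  assert_image(ref); assert_image(mov)
  if (!all(dim(ref) == dim(mov))) stopf("ref and mov must have equal size")
  refn <- prep_for_corr(ref)
  movn <- prep_for_corr(mov)

  scales <- if (allow_scale) seq(0.9, 1.1, by = 0.025) else 1
  eval_angle <- function(theta, s) {
    m2 <- if (s == 1 && theta == 0) movn else
      warp_rigid(movn, rigid_transform(theta_deg = theta, scale = s))
    xs <- xcorr_shift(refn, m2)
    list(theta = theta, scale = s, dx = xs$dx, dy = xs$dy, peak = xs$peak)
  }
  best <- NULL
  for (s in scales) {
    coarse <- seq(-max_rotation_deg, max_rotation_deg, by = 1)
    cands <- lapply(coarse, eval_angle, s = s)
    peaks <- vapply(cands, `[[`, numeric(1), "peak")
    b <- cands[[which.max(peaks)]]
    fine <- setdiff(seq(b$theta - 0.8, b$theta + 0.8, by = 0.2), coarse)
    cands2 <- c(list(b), lapply(fine, eval_angle, s = s))
    peaks2 <- vapply(cands2, `[[`, numeric(1), "peak")
    b <- cands2[[which.max(peaks2)]]
    # parabolic refinement of the angle from its two 0.2 deg neighbours
    nb <- lapply(c(b$theta - 0.2, b$theta + 0.2), eval_angle, s = s)
    den <- nb[[1]]$peak - 2 * b$peak + nb[[2]]$peak
    if (den < 0) {
      dth <- 0.5 * (nb[[1]]$peak - nb[[2]]$peak) / den * 0.2
      if (abs(dth) < 0.2) b <- eval_angle(b$theta + dth, s)
    }
    if (is.null(best) || b$peak > best$peak) best <- b
  }

  tf <- rigid_transform(best$dx, best$dy, best$theta, best$scale)
  # robust block polish of the translation
  tf <- block_polish(refn, movn, tf)
  score <- overlap_score(ref, mov, tf)
  if (!is.finite(score) || score < min_correlation)
    stopf("registration failure: overlap correlation %.2f below %.2f (images may show different regions)",
          score, min_correlation)
  w <- apply_transform(mov, tf, fill = NA)
  ok <- is.finite(w)
  attr(tf, "score") <- score
  attr(tf, "residual") <- sqrt(mean((ref[ok] - w[ok])^2))
  tf
}

# translation polish: local correlation per block on the rotation-corrected
# image, trimmed mean over the best 80% of blocks
block_polish <- function(refn, movn, tf, grid = 4L, max_local = 3L) {
  w <- warp_rigid(movn, tf)
  nr <- nrow(refn); ncl <- ncol(refn)
  bs_r <- nr %/% grid; bs_c <- ncl %/% grid
  if (bs_r < 16 || bs_c < 16) return(tf)
  shifts <- list()
  for (i in seq_len(grid)) for (j in seq_len(grid)) {
    rows <- ((i - 1) * bs_r + 1):(i * bs_r)
    cols <- ((j - 1) * bs_c + 1):(j * bs_c)
    a <- refn[rows, cols]; b <- w[rows, cols]
    if (stats::sd(a) < 1e-6 || stats::sd(b) < 1e-6) next
    xs <- xcorr_shift(a, b)
    if (abs(xs$dx) <= max_local && abs(xs$dy) <= max_local)
      shifts[[length(shifts) + 1]] <-
        c(xs$dx, xs$dy, xs$peak / (stats::sd(a) * stats::sd(b) * length(a)))
  }
  if (length(shifts) < 4) return(tf)
  m <- do.call(rbind, shifts)
  keep <- m[, 3] >= stats::quantile(m[, 3], 0.2)  # drop worst 20% of blocks
  dx <- mean(m[keep, 1]); dy <- mean(m[keep, 2])
  rigid_transform(tf$dx_px + dx, tf$dy_px + dy, tf$theta_deg, tf$scale)
}

#' Aligned image pair for the flicker test
#'
#' Bundles a reference image, a moving image and the rigid transform that
#' projects the moving image onto the reference, the prerequisite for
#' flicking between the two.
#'
#' @param reference,moving grayscale matrices.
#' @param transform a [rigid_transform()]; estimated with
#'   [estimate_rigid()] when omitted.
#' @param ... passed on to [estimate_rigid()].
#' @return object of class `flicker_pair` with fields `reference`,
#'   `moving`, `transform`, `residual`.
#' @export
flicker_pair <- function(reference, moving, transform = NULL, ...) {
  if (is.null(transform)) transform <- estimate_rigid(reference, moving, ...)
  residual <- attr(transform, "residual")
  if (is.null(residual)) {
    w <- apply_transform(moving, transform, fill = NA)
    ok <- is.finite(w)
    residual <- sqrt(mean((reference[ok] - w[ok])^2))
  }
  structure(list(reference = reference, moving = moving,
                 transform = transform, residual = residual),
            class = "flicker_pair")
}

#' Build a two-phase flicker animation from an aligned pair
#'
#' Alternating the co-registered images makes structural change visible as
#' apparent motion.  The animation is returned as a list of frames (the
#' reference and the warped moving image, masked to their common overlap)
#' with the flick period in milliseconds; [write_flicker()] serializes it.
#'
#' @param pair a [flicker_pair()].
#' @param period_ms flick period per phase, milliseconds.
#' @return object of class `flicker_animation`: `frames` (list of two
#'   matrices), `period_ms`, `overlap` (logical matrix).
#' @export
make_flicker <- function(pair, period_ms = 500) {
  if (!inherits(pair, "flicker_pair")) stopf("pair must be a flicker_pair")
  w <- apply_transform(pair$moving, pair$transform, fill = NA)
  overlap <- is.finite(w)
  w[!overlap] <- 0
  ref <- pair$reference
  ref[!overlap] <- 0
  structure(list(frames = list(ref, w), period_ms = period_ms,
                 overlap = overlap),
            class = "flicker_animation")
}

#' Write a flicker animation to disk
#'
#' Serializes the two phases as numbered PNG frames plus a JSON manifest
#' carrying the frame delay, ready for assembly by any animation viewer.
#'
#' @param anim a [make_flicker()] result.
#' @param dir output directory, created if needed.
#' @return invisibly, the manifest path.
#' @export
write_flicker <- function(anim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(anim$frames))
  for (i in seq_along(anim$frames)) {
    paths[i] <- file.path(dir, sprintf("phase_%02d.png", i))
    png::writePNG(clamp01(anim$frames[[i]]), paths[i])
  }
  manifest <- file.path(dir, "animation.json")
  jsonlite::write_json(list(frames = basename(paths),
                            period_ms = anim$period_ms,
                            loop = TRUE),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Residual landmark displacements after global alignment
#'
#' After globally aligning a follow-up image to its reference, true tissue
#' change shows up as residual local displacement at landmarks (e.g. small
#' vessels at the edge of the optic cup).  Each landmark is tracked by
#' local block correlation between the reference and the warped moving
#' image; landmarks outside the common overlap are flagged and excluded
#' from the summary.
#'
#' @param pair a [flicker_pair()].
#' @param landmarks n x 2 matrix of (x, y) pixel positions in the reference
#'   image (1-based, col/row order x then y).
#' @param block half-size of the correlation block, px.
#' @param cal optional [scale_calibration()] for mm conversion.
#' @param lens optional [fundus_lens()] for mm conversion.
#' @return list with `vectors` (data.frame x, y, dx_px, dy_px,
#'   magnitude_px, in_overlap, and mm columns when calibrated) and
#'   `summary` (max and mean magnitude over in-overlap landmarks).
#' @export
landmark_displacements <- function(pair, landmarks, block = 16,
                                   cal = NULL, lens = NULL) {
  if (!inherits(pair, "flicker_pair")) stopf("pair must be a flicker_pair")
  landmarks <- rbind(landmarks)
  w <- apply_transform(pair$moving, pair$transform, fill = NA)
  ref <- pair$reference
  nr <- nrow(ref); ncl <- ncol(ref)
  n <- nrow(landmarks)
  dx <- dy <- rep(NA_real_, n)
  inov <- logical(n)
  for (i in seq_len(n)) {
    x <- round(landmarks[i, 1]); y <- round(landmarks[i, 2])
    rows <- (y - block):(y + block); cols <- (x - block):(x + block)
    if (min(rows) < 1 || max(rows) > nr || min(cols) < 1 || max(cols) > ncl)
      next
    b_ref <- ref[rows, cols]; b_mov <- w[rows, cols]
    if (mean(is.finite(b_mov)) < 0.95) next
    inov[i] <- TRUE
    xs <- xcorr_shift(b_ref, ifelse(is.finite(b_mov), b_mov, 0))
    # shift moving->reference; displacement of the structure is the negative
    dx[i] <- -xs$dx; dy[i] <- -xs$dy
  }
  mag <- sqrt(dx^2 + dy^2)
  df <- data.frame(x = landmarks[, 1], y = landmarks[, 2],
                   dx_px = dx, dy_px = dy, magnitude_px = mag,
                   in_overlap = inov)
  if (!is.null(cal) && !is.null(lens))
    df$magnitude_mm <- retinal_length(ifelse(inov, mag, NA), cal, lens)
  list(vectors = df,
       summary = list(max_px = suppressWarnings(max(mag[inov])),
                      mean_px = mean(mag[inov]),
                      n_used = sum(inov), n_excluded = sum(!inov)))
}
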