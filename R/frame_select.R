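#' Focus score of a video frame
#'
#' Mean squared response of the discrete Laplacian (second-derivative)
#' operator over the frame: high when small vessels and other fine fundus
#' structure are in focus, and strictly decreasing as the same frame is
#' blurred.  Frames are scored on the green channel, where fundus contrast
#' is best.
#'
#' @param frame grayscale matrix (green channel extracted upstream) or RGB
#'   array.
#' @return non-negative scalar focus score.
#' @export
sharpness_score <- function(frame) {
  frame <- as_channel(frame)
  assert_image(frame, "frame")
  if (nrow(frame) < 3 || ncol(frame) < 3) stopf("frame too small to score")
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  resp <- EBImage::filter2(frame, lap)
  # exclude the one-pixel border, where the filter wraps
  core <- resp[2:(nrow(resp) - 1), 2:(ncol(resp) - 1)]
  mean(core^2)
}

#' Score every frame of a sequence
#'
#' @param frames list of grayscale matrices (or RGB arrays).
#' @param blink_frac frames with mean intensity below this fraction of the
#'   sequence median are flagged as blinks.
#' @param blink_abs absolute mean-intensity floor: frames darker than this
#'   are blinks regardless of the sequence median (covers sequences that
#'   are all blink).
#' @param saturation_frac frames with more than this fraction of pixels at
#'   the top of the intensity range are flagged saturated.
#' @param sharp_percentile usability requires sharpness at or above this
#'   percentile of the non-blink, non-saturated frames.
#' @return data.frame with columns index, sharpness, brightness, blink,
#'   saturated, usable.
#' @export
frame_scores <- function(frames, blink_frac = 0.3, blink_abs = 0.08,
                         saturation_frac = 0.01, sharp_percentile = 0.5) {
  if (length(frames) == 0) stopf("empty frame sequence")
  frames <- lapply(frames, as_channel)
  brightness <- vapply(frames, mean, numeric(1))
  sharpness <- vapply(frames, sharpness_score, numeric(1))
  sat <- vapply(frames, function(f) mean(f >= 0.995), numeric(1))
  blink <- brightness < blink_frac * stats::median(brightness) |
    brightness < blink_abs
  saturated <- sat > saturation_frac
  candidate <- !blink & !saturated
  thr <- if (any(candidate))
    stats::quantile(sharpness[candidate], sharp_percentile) else Inf
  data.frame(index = seq_along(frames), sharpness = sharpness,
             brightness = brightness, blink = blink, saturated = saturated,
             usable = candidate & sharpness >= thr)
}

#' Select diagnostic still frames from a video sequence
#'
#' Emulates the assistant's task of pulling sufficiently sharp stills out
#' of a fundus video: blink and saturated frames are excluded, the
#' remaining frames are ranked by focus score, and the top k are taken
#' greedily subject to a minimum index separation so the selection spans
#' distinct fixation moments (default ~0.5 s at the 25 frames/s capture
#' timebase).
#'
#' @param frames list of frames (grayscale matrices or RGB arrays).
#' @param k number of stills wanted.
#' @param min_separation_frames minimum index distance between selected
#'   frames.
#' @param ... passed to [frame_scores()].
#' @return data.frame of the selected rows of [frame_scores()] (possibly
#'   empty), ordered by decreasing sharpness, with attribute `diagnostics`
#'   (counts of blink / saturated / blurred rejections).
#' @export
select_frames <- function(frames, k, min_separation_frames = 12, ...) {
  if (k < 1) stopf("k must be >= 1")
  sc <- frame_scores(frames, ...)
  diag <- list(n_frames = nrow(sc), blinks = sum(sc$blink),
               saturated = sum(sc$saturated),
               blurred = sum(!sc$blink & !sc$saturated & !sc$usable))
  pool <- sc[sc$usable, , drop = FALSE]
  pool <- pool[order(-pool$sharpness), , drop = FALSE]
  chosen <- integer(0)
  for (i in seq_len(nrow(pool))) {
    idx <- pool$index[i]
    if (all(abs(idx - chosen) >= min_separation_frames)) {
      chosen <- c(chosen, idx)
      if (length(chosen) == k) break
    }
  }
  out <- sc[match(chosen, sc$index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diag
  out
}

#' Read a directory of numbered frames
#'
#' Loads PNG (and, when the tiff package is available, TIFF) frames in
#' lexicographic order; decoding of video containers into numbered frames
#' is a documented pre-step outside the package.
#'
#' @param dir directory of frame images.
#' @param pattern filename regexp.
#' @return named list of image arrays.
#' @export
read_frames <- function(dir, pattern = "\\.(png|tif|tiff)$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0) stopf("no frames found in %s", dir)
  out <- lapply(files, read_image)
  names(out) <- basename(files)
  out
}

# read a PNG/TIFF image as matrix or RGB array in [0,1]
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stopf("reading TIFF requires the tiff package")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  img
}
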