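# Internal helpers shared across modules.
#
# Image convention used throughout the package: a grayscale image is a
# numeric matrix with values in [0, 1], img[row, col]; row = y increasing
# downward, col = x increasing rightward (the viewed, i.e. inverted, fundus
# frame unless stated otherwise).  RGB images are row x col x 3 arrays.

round_half_up <- function(x, digits = 1) {
  # reported mm values use commercial rounding, not banker's
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_image <- function(x) is.matrix(x) && is.numeric(x)

assert_image <- function(x, what = "image") {
  if (!is_image(x)) stopf("%s must be a numeric matrix (grayscale image)", what)
  if (length(x) == 0L) stopf("%s is empty", what)
  invisible(x)
}

#' Extract a single analysis channel from an image
#'
#' Fundus structures (vessels, small arterioles) show best contrast in the
#' green channel, which is therefore the default analysis channel for all
#' scoring and registration operations.
#'
#' @param img grayscale matrix or RGB array (rows x cols x 3), values in
#'   \[0, 1\].
#' @param channel one of `"green"`, `"red"`, `"blue"`, `"gray"` (luminance).
#' @return numeric matrix.
#' @export
as_channel <- function(img, channel = c("green", "red", "blue", "gray")) {
  channel <- match.arg(channel)
  if (is.matrix(img)) return(img)
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3] >= 3L))
    stopf("img must be a matrix or an RGB array")
  switch(channel,
    red   = img[, , 1],
    green = img[, , 2],
    blue  = img[, , 3],
    gray  = 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
}

# ---- rigid geometry ---------------------------------------------------------

# Pixel-center coordinates relative to the image center, in px.  A pixel at
# [row r, col c] has center (x, y) = (c - (ncol+1)/2, r - (nrow+1)/2).
center_coords <- function(dims) {
  list(x0 = (dims[2] + 1) / 2, y0 = (dims[1] + 1) / 2)
}

# Apply a rigid(+scale) transform to points: x' = s R x + t, angles in
# degrees, positive theta rotates x toward y (clockwise on screen since y
# points down).  pts is an n x 2 matrix of (x, y) center-origin coordinates.
transform_points <- function(pts, tf) {
  th <- tf$theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- tf$scale * (pts %*% t(R))
  out[, 1] <- out[, 1] + tf$dx_px
  out[, 2] <- out[, 2] + tf$dy_px
  out
}

# Bilinear sampling of img at center-origin coordinates (x, y); points
# outside the support return `fill`.
bilinear_sample <- function(img, x, y, fill = 0) {
  cc <- center_coords(dim(img))
  xc <- x + cc$x0
  yc <- y + cc$y0
  x0 <- floor(xc); y0 <- floor(yc)
  fx <- xc - x0;  fy <- yc - y0
  nr <- nrow(img); ncl <- ncol(img)
  inside <- x0 >= 1 & x0 <= ncl - 1 & y0 >= 1 & y0 <= nr - 1
  out <- rep(fill, length(x))
  if (any(inside)) {
    x0i <- x0[inside]; y0i <- y0[inside]
    fxi <- fx[inside]; fyi <- fy[inside]
    i00 <- cbind(y0i,     x0i)
    i01 <- cbind(y0i,     x0i + 1)
    i10 <- cbind(y0i + 1, x0i)
    i11 <- cbind(y0i + 1, x0i + 1)
    out[inside] <-
      img[i00] * (1 - fxi) * (1 - fyi) + img[i01] * fxi * (1 - fyi) +
      img[i10] * (1 - fxi) * fyi       + img[i11] * fxi * fyi
  }
  out
}

# Warp `img` into the reference frame of a rigid transform tf (which maps
# moving-image coordinates to reference coordinates): out(x_ref) =
# img(tf^-1(x_ref)).  Returns a matrix of dims `dims` (default dim(img)).
warp_rigid <- function(img, tf, dims = dim(img), fill = 0) {
  cc <- center_coords(dims)
  grid_x <- rep(seq_len(dims[2]) - cc$x0, each = dims[1])
  grid_y <- rep(seq_len(dims[1]) - cc$y0, times = dims[2])
  inv <- invert_transform(tf)
  src <- transform_points(cbind(grid_x, grid_y), inv)
  matrix(bilinear_sample(img, src[, 1], src[, 2], fill = fill),
         nrow = dims[1], ncol = dims[2])
}

# L1 (least absolute deviations) straight-line fit y ~ a + b*x by
# iteratively reweighted least squares.
l1_line_fit <- function(x, y, n_iter = 30, eps = 1e-6) {
  w <- rep(1, length(x))
  a <- b <- 0
  for (i in seq_len(n_iter)) {
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    a_new <- fit$coefficients[1]; b_new <- fit$coefficients[2]
    r <- abs(y - a_new - b_new * x)
    w <- 1 / pmax(r, eps)
    if (max(abs(c(a_new - a, b_new - b))) < 1e-9) {
      a <- a_new; b <- b_new
      break
    }
    a <- a_new; b <- b_new
  }
  c(intercept = unname(a), slope = unname(b))
}

# Deterministic per-call RNG scope: evaluates expr with the given seed
# without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
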