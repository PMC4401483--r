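#' Fundus image tile
#'
#' One gaze-directed fundus field destined for a mosaic: the image, a gaze
#' label from the structured examination scheme, the nominal angular field
#' diameter for the lens in use, and (for synthetic tiles) the ground-truth
#' placement.
#'
#' @param image grayscale matrix.
#' @param gaze_label e.g. `"center"`, `"up"`, `"up-temporal"`.
#' @param field_diameter_deg nominal angular diameter of the field,
#'   degrees.
#' @param lens a [fundus_lens()] or `NULL`.
#' @param truth optional ground-truth [rigid_transform()] into the source
#'   frame (synthetic tiles only).
#' @export
fundus_tile <- function(image, gaze_label = "center",
                        field_diameter_deg = 45, lens = NULL, truth = NULL) {
  assert_image(image, "tile image")
  if (field_diameter_deg <= 0) stopf("field_diameter_deg must be positive")
  structure(list(image = image, gaze_label = gaze_label,
                 field_diameter_deg = field_diameter_deg, lens = lens,
                 truth = truth),
            class = "fundus_tile")
}

#' Stitch overlapping fundus tiles into a mosaic
#'
#' Estimates pairwise rigid transforms between overlapping tiles
#' ([estimate_rigid()]), keeps pairs whose overlap correlation clears the
#' threshold, and composes placements along a spanning tree rooted at the
#' most-connected tile.  The composite is blended by linear
#' distance-to-edge feathering, which yields a homogeneous composite for
#' posterior-pole mosaics.
#'
#' @param tiles list of [fundus_tile()] objects (or bare matrices), all the
#'   same size.
#' @param min_correlation pairwise acceptance threshold on overlap
#'   correlation.  Tiles of one mosaic come from the same session with the
#'   same settings, so genuine overlaps correlate near 1 after photometric
#'   normalization; the high default rejects coincidental matches between
#'   non-adjacent fields, which score well below it.
#' @param max_rotation_deg rotation search range passed to
#'   [estimate_rigid()].
#' @return object of class `mosaic_layout`: `transforms` (list of
#'   [rigid_transform()] placing each tile on the canvas), `canvas`
#'   (blended composite matrix), `canvas_dim`, `reference` (index of the
#'   root tile), `edges` (data.frame of accepted pairs with scores).
#' @export
stitch <- function(tiles, min_correlation = 0.8, max_rotation_deg = 3) {
  if (length(tiles) == 0) stopf("need at least one tile")
  imgs <- lapply(tiles, function(t)
    if (inherits(t, "fundus_tile")) t$image else t)
  n <- length(imgs)
  dims <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(i) all(dim(i) == dims), logical(1))))
    stopf("all tiles must have equal size")
  if (n == 1L) {
    return(structure(list(transforms = list(rigid_transform()),
                          canvas = imgs[[1]], canvas_dim = dims,
                          reference = 1L,
                          edges = data.frame(from = integer(0),
                                             to = integer(0),
                                             score = numeric(0))),
                     class = "mosaic_layout"))
  }
  # pairwise registration; failures just mean "no usable overlap"
  edges <- list()
  rel <- vector("list", n * n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tf <- tryCatch(estimate_rigid(imgs[[i]], imgs[[j]],
                                  max_rotation_deg = max_rotation_deg,
                                  min_correlation = min_correlation),
                   error = function(e) NULL)
    if (is.null(tf)) next
    edges[[length(edges) + 1]] <- data.frame(from = i, to = j,
                                             score = attr(tf, "score"))
    rel[[(i - 1) * n + j]] <- tf
    rel[[(j - 1) * n + i]] <- invert_transform(tf)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = integer(0), to = integer(0), score = numeric(0))
  deg <- tabulate(c(edges$from, edges$to), nbins = n)
  root <- which.max(deg)
  # BFS spanning tree, best-scoring edges first
  placed <- vector("list", n)
  placed[[root]] <- rigid_transform()
  ord <- edges[order(-edges$score), , drop = FALSE]
  repeat {
    progressed <- FALSE
    for (k in seq_len(nrow(ord))) {
      i <- ord$from[k]; j <- ord$to[k]
      if (!is.null(placed[[i]]) && is.null(placed[[j]])) {
        placed[[j]] <- compose_transforms(placed[[i]], rel[[(i - 1) * n + j]])
        progressed <- TRUE
      } else if (!is.null(placed[[j]]) && is.null(placed[[i]])) {
        placed[[i]] <- compose_transforms(placed[[j]], rel[[(j - 1) * n + i]])
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  unreached <- which(vapply(placed, is.null, logical(1)))
  if (length(unreached))
    stopf("disconnected tile graph: tile(s) %s share no usable overlap with the mosaic",
          paste(unreached, collapse = ", "))
  compose_mosaic(imgs, placed, root)
}

# render the feather-blended composite on a canvas large enough for all
# placed tiles
compose_mosaic <- function(imgs, placed, root) {
  dims <- dim(imgs[[1]])
  half_w <- dims[2] / 2; half_h <- dims[1] / 2
  corners <- cbind(c(-half_w, half_w, half_w, -half_w),
                   c(-half_h, -half_h, half_h, half_h))
  allpts <- do.call(rbind, lapply(placed, transform_points, pts = corners))
  pad <- 2
  xr <- range(allpts[, 1]); yr <- range(allpts[, 2])
  cw <- ceiling(diff(xr)) + 2 * pad
  ch <- ceiling(diff(yr)) + 2 * pad
  # shift so the canvas center maps to the bounding-box center
  cx <- mean(xr); cy <- mean(yr)
  feather <- {
    r <- seq_len(dims[1]); c <- seq_len(dims[2])
    dr <- pmin(r - 1, dims[1] - r) + 1
    dc <- pmin(c - 1, dims[2] - c) + 1
    outer(dr, dc, pmin)
  }
  acc <- matrix(0, ch, cw); wacc <- matrix(0, ch, cw)
  canvas_tfs <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    tf <- placed[[i]]
    tf_canvas <- rigid_transform(tf$dx_px - cx, tf$dy_px - cy,
                                 tf$theta_deg, tf$scale)
    canvas_tfs[[i]] <- tf_canvas
    w <- warp_rigid(imgs[[i]], tf_canvas, dims = c(ch, cw), fill = NA)
    fw <- warp_rigid(feather, tf_canvas, dims = c(ch, cw), fill = 0)
    ok <- is.finite(w) & fw > 0
    acc[ok] <- acc[ok] + w[ok] * fw[ok]
    wacc[ok] <- wacc[ok] + fw[ok]
  }
  canvas <- acc / pmax(wacc, 1e-12)
  canvas[wacc == 0] <- 0
  structure(list(transforms = placed, canvas_transforms = canvas_tfs,
                 canvas = canvas, canvas_dim = c(ch, cw), reference = root,
                 edges = NULL),
            class = "mosaic_layout")
}

#' Gaze directions of the 3x3 panretinal documentation scheme
#'
#' Nine gaze directions tiling the fundus: the posterior pole plus eight
#' neighbours at a fixed polar offset (default one field diameter, i.e.
#' tangent fields).  With a +90 D lens at low magnification each field
#' spans roughly 45 degrees.
#'
#' @param field_diameter_deg angular diameter of one field, degrees, in
#'   (0, 180\].
#' @param spacing_deg polar offset of the eight peripheral directions;
#'   defaults to the field diameter.
#' @param eye a [schematic_eye()].
#' @return object of class `coverage_model`: `directions` (9 x 3 matrix of
#'   unit vectors, first row the optical axis), `field_diameter_deg`,
#'   `eye`.
#' @export
grid3x3_layout <- function(field_diameter_deg = 45,
                           spacing_deg = field_diameter_deg,
                           eye = schematic_eye()) {
  if (field_diameter_deg <= 0 || field_diameter_deg > 180)
    stopf("field_diameter_deg must be in (0, 180]")
  az <- seq(0, 315, by = 45) * pi / 180
  pol <- spacing_deg * pi / 180
  dirs <- rbind(c(0, 0, 1),
                cbind(sin(pol) * cos(az), sin(pol) * sin(az),
                      rep(cos(pol), 8)))
  coverage_model(dirs, field_diameter_deg, eye)
}

#' Coverage model: gaze-directed fields on a spherical retina
#'
#' @param directions n x 3 matrix of gaze direction vectors (normalized
#'   internally); the posterior pole is (0, 0, 1).
#' @param field_diameter_deg angular diameter of each field, degrees.
#' @param eye a [schematic_eye()] providing the retinal half-extent.
#' @export
coverage_model <- function(directions, field_diameter_deg = 45,
                           eye = schematic_eye()) {
  directions <- rbind(directions)
  directions <- directions / sqrt(rowSums(directions^2))
  structure(list(directions = directions,
                 field_diameter_deg = field_diameter_deg, eye = eye),
            class = "coverage_model")
}

#' Analytic fractional area of one spherical cap on the retina
#'
#' Area of a cap of angular radius `cap_halfangle_deg` divided by the area
#' of the retinal sector (half-extent from the [schematic_eye()]), both
#' from the closed-form spherical-cap area 2 pi (1 - cos a).
#'
#' @param cap_halfangle_deg angular radius of the cap, degrees.
#' @param eye a [schematic_eye()].
#' @export
cap_fraction <- function(cap_halfangle_deg, eye = schematic_eye()) {
  (1 - cos(cap_halfangle_deg * pi / 180)) /
    (1 - cos(eye$retina_halfangle_deg * pi / 180))
}

#' Retinal coverage fraction of a set of fields
#'
#' Monte-Carlo estimate of the fraction of the retinal surface (spherical
#' sector up to the eye's retinal half-extent) covered by the union of the
#' model's field caps.  With `assume_disjoint = TRUE` the closed-form sum
#' of individual cap areas is returned instead (capped at 1) — the figure
#' quoted for the 3x3 scheme treats its nine fields as disjoint caps.
#'
#' @param model a `coverage_model`.
#' @param n_samples Monte-Carlo sample count, >= 1e4.
#' @param seed RNG seed (recorded in the result).
#' @param assume_disjoint sum analytic cap fractions instead of sampling
#'   the union.
#' @return list `fraction`, `se` (binomial standard error; 0 for the
#'   analytic path), `n_samples`, `seed`, `method`.
#' @export
coverage_fraction <- function(model, n_samples = 1e5, seed = 1,
                              assume_disjoint = FALSE) {
  if (!inherits(model, "coverage_model")) stopf("model must be a coverage_model")
  cap_r <- model$field_diameter_deg / 2
  if (assume_disjoint) {
    f <- min(1, nrow(model$directions) * cap_fraction(cap_r, model$eye))
    return(list(fraction = f, se = 0, n_samples = 0L, seed = seed,
                method = "analytic-disjoint"))
  }
  if (n_samples < 1e4) stopf("n_samples must be >= 1e4")
  alpha <- model$eye$retina_halfangle_deg * pi / 180
  pts <- with_seed(seed, {
    z <- stats::runif(n_samples, cos(alpha), 1)      # uniform on the sector
    phi <- stats::runif(n_samples, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    cbind(s * cos(phi), s * sin(phi), z)
  })
  cosr <- cos(cap_r * pi / 180)
  covered <- rep(FALSE, n_samples)
  for (i in seq_len(nrow(model$directions)))
    covered <- covered | (pts %*% model$directions[i, ] >= cosr)
  f <- mean(covered)
  list(fraction = f, se = sqrt(f * (1 - f) / n_samples),
       n_samples = n_samples, seed = seed, method = "monte-carlo")
}
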