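# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

fixture_phantom <- function(seed = 3, size_px = 512, ...) {
  cached(sprintf("phantom_%d_%d", seed, size_px),
         generate_phantom(seed = seed, size_px = size_px, ...))
}

# small synthetic slit-band image: Gaussian cross-section band at a known
# subpixel column, independent of the phantom machinery
band_image <- function(center_px = 120.4, nrow = 48, ncol = 200,
                       sigma_px = 6, amplitude = 0.8, background = 0.05,
                       noise_sd = 0, seed = 1) {
  X <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  img <- background + amplitude * exp(-0.5 * ((X - center_px) / sigma_px)^2)
  if (noise_sd > 0) {
    img <- withr::with_seed(seed,
      img + matrix(rnorm(nrow * ncol, 0, noise_sd), nrow, ncol))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

# brute-force integer-shift correlation oracle: exhaustive search over
# integer translations, correlation on the overlapping region only
bruteforce_shift <- function(ref, mov, max_shift = 8) {
  best <- c(NA, NA); best_cor <- -Inf
  for (dx in -max_shift:max_shift) for (dy in -max_shift:max_shift) {
    rr <- max(1, 1 + dy):min(nrow(ref), nrow(ref) + dy)
    cr <- max(1, 1 + dx):min(ncol(ref), ncol(ref) + dx)
    a <- ref[rr, cr]
    b <- mov[rr - dy, cr - dx]
    cc <- suppressWarnings(stats::cor(as.vector(a), as.vector(b)))
    if (is.finite(cc) && cc > best_cor) { best_cor <- cc; best <- c(dx, dy) }
  }
  list(dx = best[1], dy = best[2], cor = best_cor)
}
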