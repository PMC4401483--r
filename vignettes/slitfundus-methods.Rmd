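---
title: "Models and methods behind slitfundus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind slitfundus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slitfundus)
```

`slitfundus` models fundus videography through the slit lamp: the optics
of hand-held converging lenses, the geometry of slit-beam illumination,
and the image processing that turns examination video into measurements,
longitudinal comparisons and panretinal documentation. This vignette
explains each model, its assumptions, the parameters that matter, and
the numerical choices made where the design was genuinely open. It
states no empirical result that the package's tests do not themselves
compute.

## The magnification model

A converging lens of power $P$ held before the eye forms an inverted
aerial image of the fundus. For an emmetropic schematic eye the
manufacturers print a fundus magnification factor $m$ — aerial-image
size equals $m$ times retinal size — of 0.75, 1.15 and 1.67 for the
+90 D, +60 D and +40 D lenses. Two consequences drive everything else:

* an illumination aperture of diameter $a$ projects onto the retina
  with diameter $a/m$ (`projected_aperture_diameter()`), so stronger
  lenses illuminate *more* retina while showing it at *less*
  magnification through the oculars;
* a distance of $p$ pixels on the captured image, calibrated at
  $k$ px/mm against a linear scale held at the slit-lamp objective
  (the aerial image plane), measures $p/k \times m$ millimetres of
  retina (`retinal_length()`); areas scale with $m^2$.

For powers without a printed factor the package fits the
reciprocal-proportionality law $1/m = P/c$ by least squares to the three
catalog points. The fitted constant reproduces every catalog factor
within 3%, and fitted values are flagged (`catalog = FALSE`) so reports
can distinguish printed from modelled numbers. The same proportionality
is why the illuminated-field diameters of the lens collection stand in
the ratio of the powers, 2.25 : 1.5 : 1.0 — the catalog factors
themselves scatter a few percent around that law (the +60 D factor by
about 3%), which the package reports rather than hides: the computed
+60 D projection of the 3.5 mm aperture is 3.04 mm where 3.1 mm is
conventionally quoted, a documented ~2% discrepancy.

Reported millimetre values are rounded to one decimal with half-up
rounding, matching the convention of published ring-diameter figures.

**Drawback distances.** Focusing the aerial image requires pulling the
slit lamp back from the anterior-segment position: 3, 4, 6 and 10 cm for
+90, +60, +40 and +20 D. For intermediate powers the package
interpolates with an affine function of focal length
($f = 1000/P$ mm) fitted by least squares to those four anchors; the fit
reproduces every anchor within 0.4 cm. An affine-in-focal-length form
with fixed coefficients ($d \approx 2f + 9$ mm) was considered but
misses the +20 D anchor by 0.9 cm, so the fitted coefficients
(intercept 11.4 mm, slope 1.80) are used instead.

**Ametropia.** Refractive error changes effective magnification:
hyperopia raises it, myopia lowers it. The package applies a first-order
vergence factor $P/(P-R)$ with $R$ the spherical equivalent. This has
the right sign, is symmetric to first order, and shrinks with stronger
lenses and smaller errors — but its magnitude is an approximation, not a
calibrated per-lens curve, and is documented as such.

## Aperture simulation

The illumination unit combines a rotating plate (circles of 14, 8, 3.5
and 0.3 mm plus a crescent) with a curtain-like second aperture that
sets slit width. Masks are rasterized as the intersection of plate shape
and curtain rectangle on a millimetre grid centred on the optical axis
(pixel centres at half-integer offsets); circle areas are accurate to 2%
at the default 0.01 mm/px.

The crescent's physical dimensions are not published. It is
reconstructed parametrically as an outer disk minus an offset circular
cutout (defaults 4.5 / 4.5 / 3.2 mm), and the *intermediate* plate
position — between the 3.5 mm circle and the crescent — is parameterized
by how far the circle has moved off-axis (2.8 mm) and where the crescent
rim enters (4.2 mm). With the curtain near 3 mm this reproduces the
dual-semicircle "structured" aperture: two opposed near-semicircular
patches, the smaller one usable as a fixation or blind-spot probe, with
a dark comfortable gap between them. These geometric defaults are
explicit reconstructions, chosen to yield that qualitative two-component
configuration, and are fully configurable. Curtains too narrow to admit
both rims degenerate to one component and raise an error naming the
achievable range.

## Surface contour from an oblique slit

A narrow slit projected at angle $\theta$ between illumination and
observation arms is laterally displaced where the surface deviates from
its reference level: height follows $h = \Delta x / \tan\theta$.
Deflection *away* from the illumination arm marks a depression (macular
hole), deflection *toward* it an elevation (tumour, pigment epithelial
detachment, drusen). All analysis runs in the viewed (inverted)
through-the-oculars frame, the orientation clinical video is kept in; an
upright-fundus rectification is available at output only.

The pipeline is:

1. **Centerline detection** — per image row, the intensity-weighted
   centroid of pixels above a contrast threshold (half the dynamic range
   above background by default); subpixel accurate to ≤ 0.3 px on clean
   synthetic bands. No band, or two candidate bands further apart than
   30 px in one row, raise distinct errors.
2. **Centerline smoothing** — a running median over 15 rows. Where a
   vessel crosses the band the local reflectance gradient biases the
   centroid by up to a pixel over roughly ten consecutive rows; the
   median removes these excursions while distorting smooth lesion
   profiles (hundreds of rows wide) negligibly.
3. **Baseline fit** — a least-absolute-deviations straight line (IRLS)
   over rows outside the lesion. The exclusion region is user-supplied,
   or auto-detected as the largest contiguous run of residuals above
   three times their median absolute deviation — the automated stand-in
   for the examiner's delineation. Fewer than 20 support rows is an
   error.
4. **Triangulation** — pixel deflections convert to retinal mm through
   the scale calibration and lens factor, then to height by
   $\Delta x/\tan\theta$, signed by the arm side.

Lesion summaries report depth as the magnitude of the deepest point and
extent as the arc distance between the outermost crossings of a
threshold at 10% of peak depth — a fraction chosen so the extent of a
smooth pit is stable against noise; profiles everywhere shallower than
0.02 mm are reported as lesion-free. Note the "bird's eye" extent seen
from above can undervalue the anatomical extent of a hole with bulging
edges; depth is the more faithful number.

The triangulation deliberately ignores refraction of the probing beam
inside the eye, consistent with how such worked examples are computed at
the instrument; left-arm and right-arm measurements of the same lesion
are each reported, and their average is the recommended estimate.

## Frame selection

Focus is scored as the mean squared response of the discrete Laplacian
on the green channel — green because fundus vessel contrast concentrates
there — which strictly decreases under Gaussian blur of the same frame.
Blink frames (mean intensity under 30% of the sequence median, or under
0.08 absolutely so all-blink sequences are still caught) and saturated
frames (over 1% of pixels at the top of range) are excluded before
ranking; usability additionally requires sharpness at or above the 50th
percentile of the surviving frames. Selection is greedy by sharpness
with a minimum index separation, default 12 frames ≈ 0.5 s at the 25
frames/s capture timebase, so stills span distinct fixation moments. The
blink/saturation thresholds are not physical constants; they are set
from the synthetic generator's regimes and exposed in configuration.

## Rigid registration and the flicker test

Longitudinal comparison requires projecting two sessions' images over
one another; change then shows as apparent motion when flicking between
them. The registration model is rigid (translation + rotation), with
isotropic scale in [0.9, 1.1] only on explicit request — follow-up
sessions use the same lens and magnification, so scale is normally
fixed at 1.

Estimation is coarse-to-fine: photometric normalization (the
documentation enhancement of contrast gain 1.2 about mid-gray and −0.1
brightness, then mean removal), FFT cross-correlation over a 1°-step
rotation grid (±6° default), 0.2°-step refinement with a final parabolic
angle interpolation, subpixel translation by separable parabolic fits
around the correlation peak, and a last translation polish from
per-block local correlations in a 4×4 grid with the worst 20% of blocks
discarded — so changed tissue cannot drag the global alignment. Overlap
correlation below 0.3 is a registration failure (the images likely show
different regions) rather than a silent bad alignment. On synthetic
pairs the recovery is within 0.5 px and 0.2°, and estimating in the
reverse direction gives the inverse transform within the same bounds.

Landmark displacements — e.g. small vessels at the cup margin — are
measured after global alignment by local block correlation (half-size
16 px), with landmarks outside the common overlap flagged and excluded
from summaries. The flicker animation itself is serialized as two PNG
phases plus a JSON manifest carrying the flick period, a format any
animation assembler can consume.

## Mosaics and panretinal coverage

Tiles are stitched by pairwise rigid registration, keeping pairs whose
overlap correlation clears 0.8 — same-session tiles are nearly identical
in their genuine overlap after photometric normalization, while
coincidental matches between non-adjacent fields score well below that —
and composing placements along a spanning tree rooted at the
most-connected tile, best edges first. The composite uses linear
distance-to-edge feathering. Planar rigid placement (no spherical
reprojection) is appropriate because individual slit-lamp fields are
small (≤ 45°); the customary minimum overlap between neighbouring
fields is about 2°.

Coverage uses a spherical model: gaze directions as unit vectors, each
field a spherical cap of half its angular diameter, the retina a
spherical sector from the posterior pole out to the eye's retinal
half-extent. The Monte-Carlo estimator samples the sector uniformly
(area-true in the cosine of the polar angle) and reports the binomial
standard error; it agrees with the closed-form cap area
$2\pi(1-\cos r)$ within sampling error. The default retinal half-extent
of 117° (retina ≈ 73% of the globe) is a documented reconstruction
chosen so that the nine 45° fields of the 3×3 documentation scheme,
counted as disjoint caps, cover ≈ 47% of the retinal surface — the
figure conventionally quoted for that scheme. The caps of the actual
3×3 layout overlap off-axis, so the Monte-Carlo union is smaller
(≈ 39%); both numbers are reported, the disjoint-cap sum flagged as
`analytic-disjoint`.

## The synthetic fundus generator

Every analysis module is tested against phantoms with exact ground
truth. The generator emulates, at a default retinal scale of 0.01 mm/px
on a 512 px (5.12 mm) frame:

* a 1.8 mm optic disc (normal papilla) displaced nasally, a broad
  gentle foveal darkening (Gaussian σ 0.25 mm — the luteal dip of real
  fundus images spans about half a millimetre), and mild vignetting
  plus additive Gaussian noise;
* a vessel tree grown from the disc rim by recursive random branching
  with decreasing caliber, drawn mainly into the green channel (vessel
  contrast in green at least twice that in red, as in real fundus
  photographs);
* signed height maps with Gaussian pit/bump lesions, exactly zero
  outside a 3σ support;
* oblique slit renderings that are the *exact forward model* of the
  contour pipeline: band displacement equals height × tan θ signed by
  arm side, background dimmed to near-invisibility outside the beam;
* tile sets with integer-pixel ground-truth placements, longitudinal
  change pairs (vessel shift, atrophy growth, hemorrhage) that differ
  from baseline only inside a known mask, and video with integer-pixel
  fixation jitter (so resampling adds no blur of its own), scheduled
  defocus, and near-black blink frames.

What the generator does **not** emulate: specular reflexes from the
lens surfaces, media opacities, photoreceptor texture, pulsatile vessel
motion, non-rigid distortion from eye rotation, or photometric
differences between sessions. Passing round-trip tests therefore
demonstrates correctness of the geometry and the estimators under
realistic contrast and noise — not robustness to every clinical
artifact.

## Numerical conventions and problem sizes

Images are numeric matrices in [0, 1], row = y downward, column = x
rightward; transforms act about the image centre; warping is bilinear
with explicit fill values; connected components are 4-connected via
union-find over column runs. Determinism is end-to-end: every
stochastic step takes a seed, generators restore the caller's RNG
state, and each pipeline run writes a manifest from which its artifacts
are byte-reproducible.

The test suite exercises 512 px phantoms for contour and registration
work (the scale at which vessel structure constrains rotation well),
256 px phantoms for video scoring, 160 px tiles for six-tile mosaics,
and 10⁴–10⁵ Monte-Carlo samples for coverage; these sizes were chosen
as the smallest at which the estimators' accuracy targets are
comfortably met.

## Known limitations

* The ametropia correction is directionally correct but uncalibrated in
  magnitude; vertex-distance-dependent magnification curves are out of
  scope.
* Triangulation ignores intraocular refraction of the probing beam and
  cannot see below the surface — intraretinal layers are the domain of
  OCT.
* Registration is rigid: deformable change (edema, traction) corrupts
  the residual landmark field rather than being modelled.
* The crescent geometry and the 3×3 gaze spacing are reconstructions
  with documented defaults, not published specifications.
* Mosaicking assumes stable tissue between tiles; rapidly evolving
  pathology violates the stitching model.
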