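---
title: "Border irregularity assessment: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Border irregularity assessment: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermborder)
```

## The problem

In dermoscopy, the border irregularity of a pigmented lesion — ragged,
notched, abruptly cut-off edges — is among the strongest visual signs of
malignancy, and the ABCD rule quantifies it as B, the number of boundary
octants (0–8) containing an irregularity. Visual B scoring is unreliable
and changes when the image is rotated or reflected. `dermborder`
computes the irregularity count and B automatically, by reducing the
lesion border to a one-dimensional **borderline function** whose local
maxima are the irregularities.

This vignette explains the model and its assumptions, every tunable
parameter, the synthetic phantoms used for validation, numerical
choices, and known limitations. All quantitative statements here are
computed by the test suite (`tests/testthat/`) or the validation script
(`scripts/acceptance.R`); the vignette states no number that those do
not measure.

## Pipeline model and assumptions

**Preprocessing.** Dermatoscopes may add a black frame during
digitization, and dark thick hairs cross many images. A pixel is "black"
when its HSL lightness $(\max(R,G,B)+\min(R,G,B))/2$ is below 15 (scale
0–255). Scanning inward from each side, consecutive rows or columns with
at least 50 % black pixels form the frame band; the band plus 10 extra
rows (the lighter frame rim) is removed. Scanning stops at the first
non-qualifying row, so interior dark rows are never touched, and the
operation is idempotent. Hairs are detected on the NTSC grayscale image
$0.299R+0.587G+0.114B$ with a black top-hat (closing with a disc minus
the image): the response is large precisely on dark structures thinner
than the disc. Because dots and globules also respond, components are
kept as hairs only if elongated (moment-derived major/minor axis ratio
$\ge 4$ and major axis $\ge 30$ px). Hair pixels are replaced by the
mean of clean pixels within a 5 px disc, iterating from the hair
boundary inward so thick hairs fill completely.

**Segmentation** assumes the lesion lies entirely inside the image,
surrounded by roughly homogeneous healthy skin — after inpainting, the
skin is the easy region, so the grower floods *skin*, not lesion, from
an upper-left corner seed. The region admits, at each step, the
4-connected frontier pixel whose intensity is closest to the running
region mean, while that difference stays within the tolerance; what is
never admitted is the lesion. The literal reading "growth continues
until all pixels are allocated" would yield a single region from a
single seed; stopping at the tolerance is the only reading that
produces the stated two-region partition, and is what we implement.
The lesion is the largest 4-connected component of the complement, with
interior holes (4-connected background not reaching the border) filled.
A lesion touching the image edge violates the model and raises a
warning.

**Rotation** makes the analysis orientation-free: the mask's principal
axis angle comes from central second moments, and the raster is
resampled about the lesion centroid onto an enlarged canvas (no
clipping, since the next stage measures distances to the canvas edge).
Bilinear weights are used for continuous rasters; masks use
nearest-neighbour and are re-binarized — resampling can create isolated
interior background pixels, which are filled again. A perfectly
circular mask has no defined axis; the angle is then 0 by convention
(tie tolerance $10^{-6}$ on the moment difference).

**Borderline function.** The exterior boundary is traced
(Moore-neighbour, clockwise, starting at the topmost-then-leftmost
pixel) and cut into four segments at the boundary points lying on the
rays from the centroid to the four bounding-box vertices. When such a
ray crosses the boundary more than once, the outermost crossing is the
split point (deterministic, and consistent with tracing the *exterior*
boundary). Each segment is reduced to one sample per column (top,
bottom) or row (left, right), keeping the outermost pixel, and oriented
so that lesion protrusions are local **maxima** on every side — the
detector looks only for maxima, so a sign convention where bumps on two
sides became minima would make them invisible. The four profiles differ
by constant offsets (their distances to different canvas edges); at
each junction the incoming segment is shifted so the assembled signal
is exactly continuous, cumulatively left to right. The residual closure
gap between the last and first sample is recorded but not corrected:
the borderline function is an open curve, and its endpoints are never
called.

**Smoothing and detection.** The signal is convolved with a sampled,
renormalized Gaussian, size 15, $\sigma = 2.5$ samples, edges
replicated. The size follows the method's reference setting; the
reference compares kernel sizes at $\sigma = 0.5$, but a size-15 kernel
at that $\sigma$ is numerically an identity, so the production default
couples $\sigma$ to the size ($\approx$ size/6). Both are configurable.
An irregularity is a turning point: the discrete derivative changes
sign from + to −; plateaus bounded by a rise and a fall yield one call
at the floor midpoint. A prominence filter (default 2 px) suppresses
rasterization ripples that survive smoothing; setting it to 0 restores
strict sign-change behaviour, which is what the oracle-equivalence test
checks. Concave notches (minima) are not counted by default — the
clinical sign is the protrusion — but `count_minima = TRUE` adds them.
B is the number of occupied octants when the signal domain is divided
into 8 equal parts, and `TDS = 1.3A + 0.1B + 0.5C + 0.5D` with the
benign/suspicious cut at 4.75 and the suspicious/highly-suspicious cut
at 5.45; the gap the published thresholds leave at [4.75, 4.8) is
classified as suspicious, the conservative choice toward follow-up.
A (asymmetry), C (colours) and D (structures) are user inputs; only B
is computed.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `frame_lightness_thresh` | 15 | intensity | "black" pixel cut-off |
| `frame_black_fraction` | 0.5 | ratio | frame row rule |
| `frame_extra_rows` | 10 | px | light frame rim |
| `tophat_radius` | 5 | px | hair thickness ceiling (disc radius) |
| `hair_binarize_thresh` | 20 | intensity | top-hat binarization (`"otsu"` optional) |
| `hair_min_elongation` | 4 | ratio | hair vs dot/globule |
| `hair_min_length` | 30 | px | hair vs small artifact |
| `inpaint_radius` | 5 | px | donor neighbourhood |
| `grow_tolerance` | `"auto"` (0.1 × range) | intensity | region-growing stop; relative default adapts to exposure |
| `smooth_size` | 15 | samples | Gaussian kernel size |
| `smooth_sigma` | 2.5 | samples | Gaussian width |
| `min_prominence` | 2 | px | turning-point salience |
| `radial_samples` | 360 | — | baseline angular resolution |
| `match_tol_frac` | 0.02 | fraction of perimeter | call-to-truth matching |

The matching protocol (greedy one-to-one by increasing circular
arc-length distance, tolerance 2 % of the boundary length) is this
package's choice: the original evaluation compared detections to expert
marks manually, so any automated study needs an explicit protocol, and
all three of its parameters are exposed.

## The synthetic phantoms

No clinical images are distributed, so validation runs on phantoms with
exactly known ground truth. A phantom is a polar contour
$r(t) = r_\mathrm{ellipse}(t; a, b, \varphi) + A\cos(k t - \phi)$ —
semi-axes 80 × 60 px on a 340 × 400 canvas, bump amplitude
$A = 10$ px with $k$ uniformly spaced sinusoidal bumps at a seeded
random phase — rasterized as a dark lesion (intensity 70) on lighter
skin (190), with per-channel Gaussian noise ($\sigma = 8$; contrast is
15 × the noise), optional near-parallel hair strokes (intensity 30,
1–3 px wide), and an optional black frame. The ground-truth bump
positions are the numerically located maxima of $r(t)$, not the nominal
cosine peaks, because the ellipse gradient shifts apexes by a few
degrees at small $k$. Three tiers bundle the artifact settings: clean,
standard (noise + frame), hard (noise + hairs + frame + 30° rotation).

Lesion size, amplitude and contrast are deliberately "easy" in the
photometric sense: the phantoms test the *geometry* of the pipeline
(frame scanning, hair shape discrimination, growing, rotation, the
borderline construction), not low-contrast segmentation. Real
dermoscopic lesions add pigment texture, fuzzy borders, vignetting and
colour variegation that the phantoms do not emulate, so a passing
phantom suite shows correctness of the algorithmic chain, not clinical
performance.

The **lobed phantoms** probe the known failure mode of the radial
distance baseline. Four "canopy" lobes — a 16 px blob held 160 px from
the centre over a boundary bump, connected by a 16 px-wide neck rooted
30° away — make centroid rays cross the boundary three or more times.
The radial curve keeps only the outermost crossing, so the bump beneath
each canopy is invisible to it, while the four side-view profiles still
see the bump because the canopy occupies a different column/row band
(the canopies sit at diagonal positions; a canopy directly above a
cardinal bump would shadow it in both parameterizations). The canopies
are placed symmetrically so the principal axis stays horizontal, the
necks are wider than the hair top-hat's structuring element so hair
removal does not amputate them, and each quadrant's canopy keeps the
shadowed bump inside a left/right segment. On this geometry the
borderline method recovers essentially all true irregularities while
the baseline misses exactly the four shadowed bumps — the package's
operationalization of "many errors when the segmented area is not
round".

## Numerical choices

Determinism is enforced throughout: region growing breaks ties in
row-major scan order; boundary tracing fixes the start pixel and
direction; split points take the outermost crossing; plateau maxima use
the floor midpoint; all phantom randomness derives from the spec seed.
Degenerate inputs raise errors rather than guesses: an all-black image
(frame removal would empty it), a hair mask covering everything (no
inpainting donors), an empty complement (no lesion), masks under 3 px
(no moments), a centroid outside the mask (the quadrant construction
presumes an interior centroid; strongly concave lesions violate it).
Boundary handling is edge replication for open signals and circular
padding for the periodic radial curve, whose detector also wraps by
cutting the signal at its global minimum.

Profile single-valuedness: where a segment is not single-valued per
column/row (overhangs), the outermost pixel wins and the number of
multi-valued columns is reported as the `overhang` attribute, so users
can see how much boundary detail the reduction discarded.

## Validation design and problem sizes

The validation study (mirrored by `tests/testthat/test-acceptance.R`
and recomputed by `scripts/acceptance.R`) uses: exact equivalence of
the turning-point detector with a brute-force sign-pattern scan on
1 000 random length-500 signals; Gaussian smoothing against direct
convolution on 100 signals; segmentation recovery (Jaccard, mean
boundary distance) on 50 standard phantoms; bump-count recovery and
matched sensitivity/precision on 100 phantoms with
$k \in \{4, 8, 12, 16, 20, 24\}$; count stability across lesion
orientations 0°/15°/30°/45° on 20 phantoms ($k = 8$, where count
recovery is stable); the borderline-versus-baseline sensitivity
contrast on 20 lobed phantoms; and the full 540-case TDS sweep against
an independently coded oracle. These sizes keep the whole study at a
few minutes on one CPU while leaving each aggregate rate estimated from
at least hundreds of truth events.

## Known limitations

**Corner blind spot.** The four profiles view the lesion from the top,
right, bottom and left. A boundary feature whose apex points along a
bounding-box corner ray (roughly ±8° around the four diagonal
directions) protrudes in neither view: locally the boundary folds over
in both parameterizations, the outermost-pixel rule keeps the fold's
outer sheet, and the feature vanishes from the signal. For sparse
irregularities ($k \lesssim 10$ on the default phantom) bumps are wide
enough that the count is still recovered within ±1; from
$k \approx 16$ upward, two to three bumps per phantom land in the blind
windows and the detected count systematically undershoots — enlarging
the lesion, changing amplitude within the sensible range, or sharpening
the bumps does not remove the effect, which is intrinsic to
axis-aligned extremal profiles. The per-phantom `overhang` count is the
observable symptom. Arc-length reparameterization of the boundary would
remove the blind spot but is deliberately out of scope: the borderline
function is defined on raw pixel-indexed profiles.

**Other limitations.** Only maxima are counted by default, so concave
notches contribute nothing to B unless `count_minima` is set. The
quadrant construction requires the centroid inside the mask. The
segmentation is a single seeded-region-growing method; images whose
healthy skin is not the brightest homogeneous region (severe vignetting,
very dark skin types) violate its core assumption. Accuracy in the
classification sense is not computed anywhere: without a definable
true-negative event for border irregularities, only sensitivity and
precision are meaningful, and those are what the evaluation module
reports.
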