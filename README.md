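# dermborder

Automatic assessment of skin-lesion **border irregularity** in dermoscopic
colour images.

Border irregularity is the B component of the ABCD rule of dermoscopy: a
ragged, notched lesion edge is one of the strongest dermoscopic warning
signs for melanoma, and the clinical score counts the number of boundary
octants (0–8) that show an abrupt, irregular pigment cut-off. Visual
assessment of this count is known to be unreliable and not invariant to
image rotation. `dermborder` implements a fully automatic pipeline that
produces the irregularity count and the B score from a raw dermoscopic
image, for researchers building or evaluating computer-aided melanoma
screening tools.

## Method

The pipeline runs six stages:

1. **Preprocessing.** The black digitization frame is removed by scanning
   rows/columns inward from each side and dropping those whose fraction of
   black pixels (HSL lightness `L = (max(R,G,B) + min(R,G,B))/2 < 15`) is
   at least 50 %, plus 10 extra rows per side. Dark thick hairs are
   detected with a black top-hat transform `T(I) = (I ∘ b) − I` (closing
   with a disc `b`, radius 5 px) on the NTSC grayscale image
   (`0.299 R + 0.587 G + 0.114 B`), discriminated from dots and globules
   by component elongation, and inpainted from the neighbourhood mean.
2. **Segmentation.** Best-first seeded region growing floods the healthy
   skin from an upper-left corner seed: the frontier pixel minimising
   `δ(x) = |I(x) − mean(region)|` is admitted while `δ ≤ tolerance`,
   partitioning the image into healthy skin and lesion (`S₁ ∪ S₂ = I`,
   `S₁ ∩ S₂ = ∅`); the lesion is the largest connected component of the
   complement, holes filled.
3. **Rotation.** The lesion is rotated about its centroid so the principal
   axis (from central second moments,
   `θ = ½·atan2(2 μ₁₁, μ₂₀ − μ₀₂)`) is horizontal, with bilinear
   interpolation for images and nearest-neighbour for masks, on an
   enlarged canvas.
4. **Borderline function.** The traced exterior boundary is cut into four
   segments at the boundary points nearest the rays from the centroid to
   the bounding-box vertices. Each segment becomes a single-valued profile
   of distance between border and canvas edge (one sample per column or
   row, outermost pixel, oriented so protrusions are maxima), and the four
   profiles are concatenated with the junction gaps subtracted, giving one
   continuous 1-D signal of the whole border.
5. **Smoothing.** Convolution with a sampled normalized Gaussian
   (`f(x) = exp(−x²/2σ²)/√(2π)σ`), kernel size 15, σ = 2.5 samples.
6. **Detection.** Border irregularities are the turning points where the
   derivative changes sign from + to − (`f′(x₀) = 0`, `f′ > 0` before,
   `f′ < 0` after), with a 2 px prominence filter; the B score counts
   occupied octants of the signal, and `TDS = 1.3A + 0.1B + 0.5C + 0.5D`
   classifies the lesion (benign < 4.75, suspicious ≤ 5.45, highly
   suspicious > 5.45) when A/C/D are supplied.

The package also implements the classical **radial distance curve**
baseline (centroid-to-boundary distance per angle, with per-angle crossing
counts exposing its blindness to non-radial structure), detection
evaluation by greedy arc-length matching (sensitivity `TP/(TP+FN)`,
precision `TP/(TP+FP)`), and a **synthetic phantom generator** (elliptical
lesions with a known number of boundary bumps, hairs, frames, noise, and
multi-crossing "canopy" lobes) so the whole pipeline is testable with
exactly known ground truth.

## Worked example

```r
library(dermborder)

# a synthetic dermoscopic image: elliptical lesion, 12 boundary bumps,
# pixel noise and a black digitization frame, ground truth attached
ph <- render_phantom(phantom_spec("standard", k = 12, seed = 7))

res <- run_pipeline(ph$image, abcd = list(A = 1, C = 3, D = 2))
res
#> Border irregularity assessment
#>   lesion area:         15238 px
#>   rotation angle:      0.0572 deg
#>   irregularities:      12
#>   border score (B):    8 / 8
#>   TDS:                 4.6 -> benign

glance(res)        # one-row summary (count, B, area, rotation, TDS, ...)
tidy(res)          # one call per row: signal index, image coordinates,
                   # prominence, boundary segment, octant
autoplot(res)      # smoothed borderline function with detected maxima

# score the detections against the phantom's ground truth
evaluate_detection(tidy(res)[, c("row", "col")],
                   ph$truth[, c("row", "col")], ph$contour)
#> # A tibble: 1 x 7
#>      tp    fp    fn n_truth n_detected sensitivity precision
#>     12     0     0      12         12           1         1
```

The detected count (12) equals the number of bumps built into the
phantom, all 12 calls match a true bump apex within 2 % of the boundary
length, and the B score of 8 says every octant of the border carries at
least one irregularity.

A command-line interface over the same functions is installed at
`inst/cli/dermborder.R` (subcommands `run`, `preprocess`, `segment`,
`borderline`, `detect`, `synth`, `evaluate`), with every threshold in a
YAML config (`inst/extdata/default-config.yaml`) and flag overrides.

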