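---
title: "Methods: texture-based scratch-assay quantification"
author: "scratchquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture-based scratch-assay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

The scratch assay quantifies how fast a cell monolayer closes an
artificial gap. The package's job is the image-analysis half of that
assay: given grayscale frames of a scratched monolayer, produce the
cell-free wound area per frame, subtract cells that migrated into the
wound, combine the frames tiled along each scratch into a per-replicate
total area, and report percent-wound-remaining-open over time,

$$\mathrm{percent\_open}(t) = 100 \cdot \frac{A_\mathrm{total}(t)}{A_\mathrm{total}(0)},$$

with the mean and sample standard deviation across technical
replicates.

The segmentation rests on one assumption about phase-contrast (or
similar) imagery of monolayers: **cells are textured, the cell-free
wound is smooth**. No absolute intensity difference is assumed — a
confluent monolayer and an empty dish can share the same mean gray
level. Each pixel is therefore scored with the standard deviation of
intensity over a square window of side $2r+1$ (default $r = 5$ px),
computed with edge-mirrored padding via integral images. A constant
region scores zero; the monolayer scores near its texture contrast.

## From texture score to wound mask

1. **Binarization.** Low-texture pixels are selected below a threshold
   on the score map, by default chosen with Otsu's method. Otsu
   underperforms when the smooth class occupies few pixels (narrow or
   nearly closed wounds): its low class degenerates into the lower tail
   of the monolayer mode. The pipeline detects this (median of the low
   class above half the median of the high class) and retries once at
   half the global median score. If the low class still is not
   genuinely smooth, the frame is declared closed — the assay's
   terminal state, reported as area 0 with a `closed` flag, never as an
   error.
2. **Closing and labeling.** Morphological closing (disc, default
   radius 5 px) bridges gaps from ragged leading edges; components are
   labeled with 8-connectivity (run-based union-find implemented in the
   package, since the connectivity convention matters for thin
   diagonal structures).
3. **Band selection.** The wound traverses the frame: components
   qualifying as wound must span at least 80 % of the frame extent
   along the scratch axis, and must lie within the dominant (largest)
   spanning component's column range ± `bandMarginPx`. This excludes
   incidental cell-free patches away from the scratch.
4. **Edge restoration.** The windowed score of a wound pixel is
   inflated as soon as its window overlaps the monolayer, so the raw
   low-texture region is eroded by exactly one window radius on every
   side. The final region is rebuilt by dilating the *near-floor core*
   of the selected region — pixels scoring at most
   $\max(1.15\,\hat f,\,10^{-4}\hat p)$, where $\hat f$ is the median
   score inside the candidate (the noise floor) and $\hat p$ the median
   score of the textured class (the plateau) — by a square structuring
   element of radius $r$. On an ideal noiseless edge the core boundary
   sits exactly $r$ pixels inside the true boundary, so this
   restoration is *exact*: noiseless rectangular scratches of any width
   from 20 px to half the frame are recovered with zero pixel error.
   Under noise, stochastic inclusion of transition pixels biases the
   restored boundary slightly outward (about +1 % of area on the
   reference scenes); the 1.15 floor factor was calibrated on the
   synthetic suite to keep that bias small while never leaving interior
   coverage gaps.
5. **Closed-frame rule.** If the candidate is smaller than
   `minWoundFraction` (default 0.5 %) of the frame, the frame is
   reported closed.
6. **Holes and islands.** Interior holes of the restored region are
   enclosed textured structures. All holes are first filled; holes of
   at least `minIslandAreaPx` (default 200 px) are then counted and
   subtracted as migrated-cell islands, while smaller ones stay filled
   as debris (washing leaves small debris in the wound; genuine
   migrated cells form larger patches). Island boundaries are located
   with the same core-coverage rule as the outer wound edge, so the two
   boundaries are consistent; under noise the detected island is
   re-inflated by 1 px to compensate the outward bias of the
   surrounding wound coverage (again calibrated on the synthetic
   suite; no compensation is applied in the noiseless regime, where
   recovery is exact).

The same machinery is exposed as `subtractMigratedCells()` for masks
produced elsewhere (e.g. after a manual edit), and `outlineWound()`
returns outer and inner boundary contours for QC overlays.
`applyManualOverride()` supports the two manual corrections users
actually make — adding to or removing from the mask — with exact area
bookkeeping and a provenance log; the alternative correction style,
overriding the threshold, is available as
`thresholdMethod = "fixed"`.

## Metrics

* **Center-line width** is the wall-to-wall span of the wound on the
  single pixel line through the frame center perpendicular to the
  scratch axis, times the pixel size. It is the span between the
  outermost wound pixels, *not* the count of wound pixels, so a
  subtracted island inside the wound does not shorten the width. A
  closed center line gives width 0.
* **Replicate totals** are exact sums of the per-field pixel areas.
  The set of fields entering a replicate must be identical across its
  timepoints (enforced at manifest validation and again at
  aggregation), otherwise the percent-open ratio would compare
  different stretches of the scratch.
* **Percent open** may exceed 100 (wound widening through cell
  retraction); it is flagged, not clamped, since clamping would hide
  protocol failures. A replicate with zero area at 0 h has no baseline
  and is an error.
* **Summaries** use the arithmetic mean and the sample ($n-1$) SD —
  the conventional choice at $n = 3$ technical replicates; with one
  replicate the SD is reported as 0 with a warning.
* **Coverage planning**: $n_\mathrm{tiled} = \lceil L / \ell \rceil$
  frames of extent $\ell$ tile a scratch of length $L$ (defaulting to
  the 15.6 mm diameter of a 24-well plate well, since a full-well
  scratch spans the well); dropping the two blunt-end frames leaves
  $n_\mathrm{tiled} - 2$, and the plan reports whether the kept frames
  cover at least 76 % of the scratched length. For the standard
  geometry (2.4 mm fields at 4×) this reproduces the 7-tiled /
  5-kept / 77 % design.
* **Seeding density** is cells divided by growth area, reported as
  whole cells per cm² with the fractional part dropped: 10,000 cells
  in a 1.9 cm² well give 5263 cells/cm², 60,000 give 31,578.

# The synthetic scene generator

Validation runs entirely on generated scenes with exact ground truth.
A scene is a 768 × 1024 frame (about what a 4× objective captures of a
well) at 1.6 µm/px containing:

* a monolayer rendered as zero-mean Gaussian texture, blurred with a
  2 px Gaussian (the cell scale) and standardized so its SD equals
  `cellTextureContrast` (default 30 intensity units) — the
  standardization keeps the contrast-to-noise ratio
  CNR = contrast / `noiseSigma` exactly interpretable;
* a vertical smooth band of width `scratchWidthPx` (default 300 px ≈
  480 µm) whose two edges are perturbed per row by a smooth sinusoidal
  roughness (default amplitude 10 px, wavelength 96 px), emulating
  ragged leading edges;
* optional migrated-cell discs rendered with monolayer texture inside
  the band;
* additive Gaussian noise (default SD 7.5, i.e. CNR 4 — a
  conservatively low value for modern cameras).

Ground-truth masks come from the analytic geometry before noise; the
roughness phases are drawn before any texture or noise values, so truth
is bit-identical across noise settings at a fixed seed. Time courses
derive sub-seeds by stable hashing of (well, replicate, fov, timepoint)
identities, so adding a replicate never perturbs existing frames. Each
(replicate, field) draws a fixed width jitter (SD 5 %) and each later
timepoint an additional closure jitter (SD 5 %), reproducing the
field-to-field heterogeneity that motivates total-area aggregation.

What the generator does **not** emulate: phase-contrast halos at the
leading edge, uneven illumination, drift between timepoints, realistic
cell morphology, or proliferation-driven texture changes. Passing the
synthetic suite therefore demonstrates the geometric and statistical
correctness of the pipeline, not robustness to every optical artifact
of real microscopes; on real data the `fixedThreshold` and manual
override hooks exist precisely because such artifacts occur.

The variance-reduction property — percent-open computed from replicate
total areas scatters less across replicates than percent-open from a
single randomly chosen field — is established with the area-level
simulator `simulateClosureAreas()` (100 simulated experiments by
default). The property concerns only the aggregation arithmetic and the
heterogeneity model, so simulating at the area level rather than
re-segmenting thousands of frames changes nothing about what is being
tested and keeps the check fast.

# Numerical choices and degenerate inputs

* Windowed SD uses integral images on a mean-centered copy; centering
  avoids catastrophic cancellation in the squared cumulative sums on
  large frames, and variances are clamped at 0 before the square root.
* The frame center line for width is row $\lfloor (n+1)/2 \rfloor$.
* Otsu runs on the score map rescaled to $[0,1]$ with 256 levels; an
  all-zero score map (blank frame) yields threshold 0 and a closed
  result.
* A `scratchWidthPx` of 0 is a valid specification (fully closed
  scene); rows where roughness makes the two edges cross contribute no
  wound pixels.
* Horizontal scratches are handled by transposing into the vertical
  frame of reference and transposing the mask back, so both axes share
  one code path.
* Manifest file paths are resolved relative to the manifest's own
  directory; intensities are loaded exactly as stored (16-bit TIFF
  round-trips bit-identically), and all normalization is internal to
  segmentation.

# Problem sizes

Unit tests run on compact 256 × 192 scenes; the acceptance suite and
`scripts/acceptance.R` use the full 768 × 1024 reference family — 40
seeded scenes for area recovery, a 3-replicate × 5-field × 3-timepoint
simulated experiment (45 frames) for closure kinetics, and 100
area-level simulated experiments for the variance comparison — sizes
chosen so the whole validation reflects the standardized experimental
design while completing in a few minutes on one CPU.

# Known limitations

* The texture model assumes the wound interior is smoother than the
  monolayer at the chosen window radius; dense debris fields or
  strongly textured backgrounds would need a larger `minIslandAreaPx`
  or a fixed threshold.
* Islands touching the wound edge merge with the monolayer and are not
  separable by any texture criterion; they are treated as monolayer.
* The ~1 % outward area bias under noise is calibrated, not removed;
  at very low CNR (< 2) or for wounds only a few window radii wide the
  relative bias grows.
* Magnification calibration (µm/px) is a required user input — there
  is no reliable default across microscopes.
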