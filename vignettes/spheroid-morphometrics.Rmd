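---
title: "Spheroid morphometrics: models, parameters and design choices"
author: "spheromorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spheroid morphometrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheromorph)
```

## The measurement problem

Tumor spheroids — 3D aggregates of cancer cells grown one per well in
low-attachment plates — are imaged over days of treatment as single-channel
bright-field (or fluorescence) micrographs. Treatment response shows up not
only as a change in projected area but as a change in *structure*: a
compacting spheroid develops a uniform dense core, while a disintegrating one
spreads, sprouts protrusions and loses its core. This package turns one
image per well per timepoint into a vector of morphometric parameters and
summarizes per-well trajectories into interpretable fate calls.

The pipeline is: segmentation → binary-mask parameters (shape, boundary,
skeleton) → grayscale texture (GLCM entropy, gray-value dispersion) → radial
density analysis (Core Threshold, core/edge split) → timecourse statistics
(day-0 normalization, spheroid disruption, death-mode classification,
optional viability correlation).

## Segmentation

The spheroid is separated from the background by a global threshold on
range-normalized intensities, followed by morphological closing (disc radius
2 px), hole filling, and selection of the largest 4-connected component at
least `min_object_fraction` (default 0.1%) of the image. Range normalization
makes the mask invariant to global affine intensity changes for the
automatic methods.

Polarity (dark spheroid on bright field vs. bright on dark) is detected from
the image border: the side of the threshold containing the median border
intensity is background. The border of a single-spheroid well image is
background by experimental design, which makes this test reliable; a mask
that nevertheless touches the border (late, disaggregated spheroids
overflowing the field) is accepted with a warning.

A plain Otsu threshold is unstable on bright-field spheroid frames, which
are *trimodal*: dark core, mid-gray halo, bright background. Depending on
the relative proportions of the three populations, the maximal
between-class variance split can land between core and halo, truncating the
mask to the core. `segment_spheroid()` therefore refines the Otsu threshold
iteratively: the background side is re-split, and while the newly separated
band is still clearly darker (resp. brighter) than the border population —
by more than twice the border's median absolute deviation — the band is
tissue and is absorbed into the foreground. The iteration is deterministic
and stops within a few rounds; on genuinely bimodal images the first
re-split lands inside the background noise and is rejected immediately, so
the behavior reduces to classical Otsu. The triangle method is also
available (`threshold_method = "triangle"`); it anchors on the dominant
background peak but places its threshold close to the peak's foot, within
roughly one noise standard deviation, so on noisy frames a percolating haze
of background pixels can survive; it is provided for images where Otsu's
assumptions fail outright, with Otsu-plus-refinement as the recommended
default.

Externally segmented masks are accepted as-is apart from the
single-component contract (`validate_external_mask()` keeps the largest
4-connected component and optionally fills holes, warning if anything was
removed).

## Binary-mask parameters

**Shape.** Area is the foreground pixel count (times `pixel_size`² for
physical units). Perimeter uses chain-code step weights 0.948 (axial) and
1.343 (diagonal) — the mean-square-error-optimal estimator for digitized
straight edges; raw pixel-edge counting overestimates the perimeter of a
digital circle by ~8%, biasing circularity \(4\pi A/P^2\) low by ~12%, which
would make even a perfect disk look non-circular. Circularity is clamped to
1. Specific surface is defined here as perimeter/area, a boundary-to-mass
ratio in 1/px; perimeter and area are both reported so users preferring
\(P^2/A\) can form it themselves.

**Boundary protrusions.** The outer contour is traced, the centroid
distance \(r(\theta)\) is resampled onto 360 uniform angular bins (the
resampling decouples protrusion counting from contour sampling density),
circularly smoothed with a moving average of 5% of the bins, and local
maxima with topographic prominence of at least `min_prominence` (default
0.05) times the mean radius are counted. Prominence — height above the
higher of the two saddles toward higher ground, computed on the circle — is
what makes the count robust: noise wiggles have height but no prominence. A
constant profile has no maxima, so a disk counts 0. The defaults recover
the lobe count of star-shaped test masks exactly for 3–12 lobes at 30%
amplitude, and are stable to ±1 under arbitrary rotation.

**Skeleton.** Zhang–Suen thinning; endpoints are skeleton pixels with
exactly one 8-connected skeleton neighbor. Invasive protrusions become
skeleton branches, so the endpoint count tracks boundary complexity from
the interior. Parallel thinning can delete small compact blobs entirely (the
classic 2×2 failure); a non-empty mask that thins to nothing is assigned a
single centroid pixel, so a compact disk reports ≤ 1 endpoint rather than
an empty skeleton.

## Texture

Intensities are min–max normalized over mask pixels only and quantized to
`levels` (default 64) gray levels; background pixels are excluded from every
statistic. Co-occurrences are accumulated over pixel pairs with *both*
pixels in the mask, at distance 1 along 0°, 45°, 90° and 135°,
symmetrically; entropy \(-\sum p\log_2 p\) is averaged over the four
directions and reported in bits. These are the common defaults for Haralick
texture; all are configurable, and absolute entropy values are
parameterization-dependent by nature (they scale with the number of levels
and offsets), so comparisons should always be made within one
configuration.

Two practical notes. First, min–max normalization is exact but sensitive to
single outlier pixels. Morphological closing can capture a handful of
background-intensity pixels in deep boundary notches, and one such pixel
stretches the normalization range enough to shift entropy by ~0.6 bits.
The pipeline therefore measures texture on the *thresholded tissue support*
within the final mask — the mask minus pixels added by closing and hole
filling, which are background-intensity field pixels, not tissue. This is
the same reasoning that restricts the GLCM to the mask in the first place.
Shape and density always use the full mask. Second, entropy is also
recomputed separately for the core and edge regions of the density map
(`entropy_core`, `entropy_edge`), because the fate interpretation below is
about where disorder changes: a compacting spheroid grows a uniform
(low-entropy) core, a disintegrating one grows a disordered edge.

## Radial density analysis

Concentric half-open annuli of width `ring_width` (default 2 px) are drawn
from the spheroid centroid. Each ring's *occupancy* is the fraction of its
pixels (clipped to the image) that are mask foreground. The Core Threshold
(CT) is the outer radius of the initial run of rings with occupancy ≥ `tau`
(default 0.95); walking outward, the core ends where density first drops
below the criterion, and a first-ring failure yields CT = 0 (an all-edge,
fully fragmented spheroid). Starting the run at the innermost ring prevents
detached dense fragments from inflating the core. The density map labels
in-mask pixels core (distance ≤ CT) or edge; `percore` is the core
percentage of total area. Core and edge partition the mask exactly, by
construction.

Occupancy of the *binary mask* is the default density metric; a mean-ring-
intensity alternative (`density.metric: mean_intensity`) is available for
workflows that read density from grayscale rather than from segmentation.

One discretization property is worth knowing: when the occupancy profile
crosses `tau` almost exactly at a ring boundary, rasterization noise can
flip the CT by one full ring. For a 60 px spheroid with 30% boundary lobes,
one ring of width 2 px near the core boundary is ~4 points of percore. This
is inherent to any ring-quantized rule; reducing `ring_width` trades it
against noisier per-ring occupancy.

## Timecourse statistics

Per-well area trajectories are normalized to the earliest timepoint (first
value exactly 100). Between a baseline and a later record, spheroid
disruption is

\[ D \;=\; \frac{\mathrm{Area}_t - \mathrm{Area}_0}
               {\mathrm{Percore}_t - \mathrm{Percore}_0}\times\alpha,
   \qquad \alpha = \mathrm{Entropy}_t - \mathrm{Entropy}_0 . \]

When texture entropy is rising (\(\alpha > 0\)), \(D < 0\) flags a death
process in which total area and core percentage move in opposite directions
— the mass spreads while the dense core dissolves. \(D\) is undefined
(`defined = FALSE`, not ±∞) when \(|\Delta \mathrm{Percore}|\) is below an
epsilon guard, which keeps CSV output and downstream plotting finite.

The ratio direction deserves a note. With area change in the numerator,
\(|D|\) *diverges* for a healthy growing spheroid, whose core percentage is
the one quantity that does not change — the statistic is then numerically
dominated by measurement noise in the denominator. The inverted form
\((\Delta\mathrm{Percore}/\Delta\mathrm{Area})\cdot\alpha\)
(`disruption.form: percore_over_area`) is bounded for growth and has the
same sign whenever \(\alpha > 0\); it is the form under which "growth
produces near-zero disruption" holds quantitatively, and the form the
property tests use for that claim. The default remains the
area-over-percore form. Raw pixel areas are used by default; a switch to
day-0-normalized areas rescales \(D\) without changing its sign.

When entropy *falls* (\(\alpha < 0\), the compaction fate), the sign rule
inverts, so the recommended phenotype call is `classify_death_mode()`, not
the raw sign of \(D\): **growth** = area up with entropy stable (within a
band of 5% of baseline entropy — stable entropy indicates a self-consistent
structure); **collapse** = area down, entropy down beyond the band;
**disruption** = area up, entropy up beyond the band; anything else is
indeterminate.

Viability readings, if provided, are matched per (condition, well,
timepoint); the package reports the Pearson correlation and the power-law
calibration \(\mathrm{viability} = a\,x^{3/2} + b\) over normalized area
\(x\), fitted by ordinary least squares in \(x^{3/2}\) (the model is linear
in that regressor, so the fit is closed-form, with standard errors from the
linear model). The 3/2 exponent reflects that viability tracks cell mass
(volume, \(\propto\) area\(^{3/2}\)) while the image measures projected
area. The fit needs ≥ 3 matched pairs; with 2 it is refused and only the
correlation is returned.

## The phantom generator

`make_phantom()` draws a star-cosine spheroid,
\(r(\theta) = R(1 + a\cos k\theta)\), a dark core disk inside a lighter
halo on a bright background (polarity switchable), with additive Gaussian
noise clipped to the bit depth. The star-cosine boundary is used instead of
random-walk boundaries because it gives an *exact* protrusion-count truth.
`fragmentation` emulates disaggregation: a fraction `f` of the halo is
removed; the survivors form radial tendrils that stay 4-connected to the
core (so the generator's own bookkeeping — main-component area equals core
plus the kept halo — holds under 4-connected labeling), and detached
single-cell debris is painted sparsely (≤ 2% of the background, ≥ 6 px from
the spheroid) into the image only, never the truth mask.

The truth core is the *dense* region at the default occupancy criterion:
the full star interior radius \(R(1 + a\cos(0.95\pi))\) when the halo is
solid, or the core disk when fragmentation has made the halo sparser than
`tau`. Defining truth this way keeps it commensurable with the
occupancy-based measurement; the dark *intensity* core drives image
appearance and texture, not the density truth.

Default study conditions, chosen once as representative of bright-field
96-well spheroid assays: 256 px frames, base radius 60 px, 8-bit
intensities (background 220, halo 160, core 60), noise σ = 8 gray levels.
The three timecourse scenarios encode the canonical fates: **growth**
(radius ×1.10/step, constant noise and core fraction), **collapse** (radius
×0.90/step, core fraction rising 0.50 → 0.70, noise 10 → 3 so entropy
falls), **disruption** (radius ×1.25/step, fragmentation 0 → 0.5, core
fraction 0.60 → 0.30, noise 8 → 17 so entropy rises). All truth trends are
monotone by construction.

What the phantoms deliberately do not emulate: optics (point-spread
blur, vignetting, uneven illumination), Poisson/speckle noise, multiple
spheroids or debris touching the spheroid, and 3-D effects. Passing the
phantom suite therefore demonstrates correctness of the measurement chain
on idealized single-spheroid frames, not robustness to every acquisition
artifact; the configuration surface (thresholding method, polarity,
prominence, `tau`, ring width) is how real-data deviations are absorbed.

## Numerical choices and degenerate inputs

* Coordinates are (row, col), 0-based, pixel centers at integers.
* Constant images raise `noSpheroidFound`; a constant in-mask intensity
  normalizes to level 0 and has entropy 0 (not an error).
* Ties in thresholding put boundary-valued pixels on the foreground side
  for dark spheroids (`y ≤ t`) and the background side for bright ones
  (`y > t`); both clean binary inputs re-segment to themselves exactly.
* Peak plateaus count once (strict rise on one side), and shoulder points
  are removed by zero prominence.
* The GLCM probability matrices sum to 1 within 1e−12; entropy uses
  \(0\log 0 = 0\).
* Problem sizes in the test suite — 8×8 rasters for brute-force GLCM
  oracles, 32×32 masks for density oracles, 256–350 px phantoms, 20 seeded
  runs per stochastic claim — were chosen so each property is exercised at
  a scale where its failure modes are visible while the whole suite stays
  interactive.

## Known limitations

* One spheroid per image; multi-spheroid scenes and z-stacks are out of
  scope by design.
* Absolute entropy values are configuration-dependent; only within-study
  comparisons are meaningful.
* The CT rule is isotropic; anisotropic cores are summarized by a single
  radius.
* Very thin (1 px) tendrils can be fragmented by the closing step of
  segmentation; supplying external masks bypasses this.
* The disruption statistic compares exactly two timepoints; it does not
  model the full trajectory shape.
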