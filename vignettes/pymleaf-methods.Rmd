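---
title: "Methods: NIR leaf-area segmentation and rosette growth analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR leaf-area segmentation and rosette growth analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pymleaf)
```

## The imaging model

The pipeline assumes images captured by an NIR-converted camera behind a
blue filter. Storage channels then carry: RED ≈ near-infrared
reflectance (700–1100 nm, high over leaf tissue because internal cell
walls scatter NIR), BLUE ≈ blue visible light (absorbed by
photosynthetic pigments, so low over leaves; high over bright mineral
surfaces). GREEN is carried through but unused — its leakage spectrum is
hardware-specific, and the segmentation needs only the RED/BLUE
contrast.

The vegetation-contrast raster is, per pixel,

$$\mathrm{NC} = \max(0,\ \mathrm{RED} - k\,\mathrm{BLUE}),\qquad k = 0.5 .$$

Negative values arise over non-vegetative, blue-bright material and are
clipped. `k` trades off two failure modes: near 1 the whole raster
darkens and plant pixels drop into the background mode; near 0
NIR-bright backgrounds leak through. Results are insensitive over
roughly `k ∈ [0.4, 0.6]`; the default sits at the midpoint, and no
per-corpus optimization is attempted (the point of the method is one
stationary parameter set for thousands of images).

Numerical choices, fixed so results are bit-reproducible:

* subtraction in real arithmetic, clip, then round — not saturating
  8-bit arithmetic, which would truncate twice;
* rescaling is a global linear min–max stretch of the clipped raster to
  0–255 with half-up rounding. A constant raster maps to all zeros. The
  stretch is the simplest reading of "rescaled"; any monotone
  alternative would leave Otsu's class split unchanged in the noiseless
  limit;
* Otsu's threshold is the exhaustive 256-candidate maximizer of
  between-class variance; ties take the smallest threshold (favouring
  the larger plant mask); foreground is *strictly above* the threshold.
  A constant image has no valid split: its value is returned flagged
  degenerate, and the foreground is empty — this is what makes a
  uniform plant-free frame measure exactly 0 rather than error out
  mid-batch;
* cleanup is erosion → opening → closing, in that order, with a square
  3×3 element (one iteration per stage by default; both configurable).
  The operator sequence is standard for speckle-and-holes cleanup; the
  element size is the smallest symmetric choice. Border pixels count as
  background for erosion, so the frame edge cannot anchor spurious
  objects;
* components are 8-connected (thin tortuous leaf lobes touching at
  corners stay one object); objects are labelled in scan order, which
  also breaks largest-object ties deterministically.

Two area conventions are exposed: `largest_object` (field scenes, where
small weeds are disregarded by taking the biggest object) and
`sum_white` (controlled conditions, or plants whose mask fragments).
Pixel counts convert to cm² by a per-batch calibration factor measured
from a physical standard in the field of view — no auto-detection.

## Growth analytics

Thermal time uses a 3.5 °C base (the accepted minimum for lettuce
growth); daily contributions below base clamp to zero rather than going
negative — in a summer campaign this is nearly moot, but it keeps the
cumulative series monotone in cold snaps.

RER is the discrete log-slope of area against thermal time per imaging
interval, attached to the interval's mean area. The size dependence is
modelled as `RER = exp(α + β A)`. The estimator is nonlinear least
squares on the RER scale (Levenberg–Marquardt, seeded by the log-linear
regression over positive RERs), i.e. maximum likelihood under additive
Gaussian noise. The alternative — linear regression of `log RER` — would
silently discard intervals where measurement noise makes the observed
RER zero or negative, biasing the fit exactly where plants grow
slowest; the nonlinear fit keeps them.

The treatment comparison is a likelihood-ratio test: full model = one
(α, β) per treatment, reduced = shared (α, β), residual variance pooled
in both, so the statistic is `n·log(RSS_red / RSS_full)` on
`2(T − 1)` degrees of freedom. Significance letters come from the same
pairwise statistic at the 1 % level. The test's size is verified by a
500-replicate null simulation in the acceptance suite.

Late in the cycle, neighbouring plants' canopies interpenetrate, and
the projected area overstates a plant's share of ground. The correction
treats the plant as a disk of equivalent area concentric with its
30 × 30 cm planting cell and discards the disk outside the cell. The
closed-form disk∩square expression is only valid while the disk's
radius is between the cell half-width (15 cm) and its circumradius
(15√2 cm); below, the area passes through untouched, above, it caps at
the full 900 cm². The function is continuous at both joints, monotone,
and checked against a grid-quadrature oracle to 0.1 %. Correction is
applied *before* RER and the radiation budget, so every downstream
statistic sees the same area series.

Intercepted radiation follows the trapezoid-in-time rule: mean of the
two bounding areas (cm² → m²) times the radiation cumulated over the
half-open interval `(t_{i-1}, t_i]`, summed over intervals, anchored at
planting with a 10 cm² transplant area. An interval containing no
radiation record raises a coverage error instead of silently
contributing zero. Because the numerator is mol per plant and the
denominator mol m⁻², the literal interception efficiency carries m² per
plant; a normalized variant divides by the 0.09 m² ground cell. Both
are reported, since the ratio's units are a frequent source of
confusion between studies.

## What the synthetic generator emulates — and what it does not

`generate_scene()` renders a rosette (central disk of radius 0.65 r
plus eight radial elliptical lobes of eccentricity 0.7 reaching r) over
dark-soil, clear-sand, mixed or plastic backgrounds. Channel statistics
are invented to reproduce the qualitative spectral contrasts of
blue-filtered NIR imaging — vegetation RED ≈ 200, BLUE ≈ 45; dark soil
flat ≈ 45; clear sand BLUE ≈ 170 above RED ≈ 140 — they are fixtures,
not measurements. The red-leaved class changes only GREEN: pigmentation
alters the visible spectrum, not the internal-structure NIR
reflectance, which is precisely why the method is variety-independent.

Material variation is rendered as a smooth (bilinearly interpolated)
texture field scaled by the material sd, plus iid capture noise
(sd 6). The spatial correlation matters: real leaf and substrate
brightness varies at centimetre scale, not per pixel, and a generator
with iid material noise would pepper the plant with isolated
below-threshold pixels that erosion amplifies — an artefact of the
fixture, not a property of the method.

The default evaluation grid crosses three backgrounds with both leaf
classes and radii of 80/104/128 px — market-stage lettuces of roughly
10/13/16 cm nominal radius imaged at 8 px/cm in a 384 px frame, the
regime in which the reference comparisons with manual contouring were
made. On this grid the pipeline's relative area error stays within 5 %
for every scene; the residual error is dominated by the deterministic
one-pixel boundary ring the cleanup erodes, which is why error shrinks
as plants grow.

What passing these tests does *not* show: robustness to specular
highlights, dew, cast shadows with penumbra, motion blur, lens
vignetting, or sensor-specific NIR leakage into GREEN — none of which
the generator models. A textured plant-free frame is also instructive:
Otsu will always split a unimodal histogram somewhere, so an empty
scene segments its brightest texture patches (a few hundred pixels)
rather than returning zero; only a strictly uniform frame takes the
degenerate all-background path. Field batches should treat
small-area/degenerate records as QC flags, not measurements.

`generate_trajectory()` integrates `dA/dTT = A·exp(α + β A)` (Runge–
Kutta, tolerance 10⁻¹⁰) from the 10 cm² transplant area and applies
multiplicative log-normal observation noise; `generate_radiation()`
produces a midday-centred half-sine at 3-minute steps (14 h daylight,
44 mol m⁻² day⁻¹ clear-sky by default, matching a Mediterranean summer)
with shade windows that transmit a configurable fraction — a schematic
stand-in for panel strips sweeping shade across the ground, with no
ray-traced geometry.

All generators are pure functions of their spec (seed included) and
leave the session RNG untouched.

## Problem sizes and tolerances in the shipped tests

The test suite runs the 18-scene default grid once (≈5 s), checks Otsu
against a 100-histogram exhaustive-search oracle, morphology against a
per-pixel Minkowski oracle on random 32×32 masks, the overlap geometry
against 4000²-point quadrature at 50 radii, exact-arithmetic identities
at 10⁻¹², parameter recovery over 200 noisy replicates (areas uniform
on 10–900 cm², noise sd 10⁻³, within Monte-Carlo CI of the
generators), and the LRT's size over 500 null replicates (3 treatments
× 60 intervals) against the binomial 95 % band at α = 0.01. The whole
suite completes in under a minute on one core.

## Known limitations

* One plant per frame: no instance separation of multiple plants in a
  single image.
* JPEG input is not supported (PNG/TIFF only); JPEG's lossy blocks are
  a poor match for single-pixel-accurate area work anyway.
* The overlap correction models the canopy as a centred disk; strongly
  anisotropic plants or off-centre transplants violate it.
* Areas are horizontal projections: no leaf-angle or vertical-structure
  modelling, so interception is a proxy that degrades as canopies close.
* Radiation at plant level is an *input*; shading geometry of a real
  panel installation must be computed upstream.
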