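---
title: "Methods: retinal phenotyping with retphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retinal phenotyping with retphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retphen)
```

This vignette documents the measurement conventions, model definitions,
and known policy biases behind each module. The synthetic generators are
designed so that every estimator in the package can be checked against an
analytic ground truth.

## Coordinate and unit conventions

Images are numeric matrices indexed `[row, col]`. Continuous pixel
coordinates are 0-based with `x` along columns (rightward) and `y` along
rows (downward), and integer coordinates at pixel centers, so the point
`(x, y)` lives at matrix cell `[y + 1, x + 1]`. Lengths convert through a
scalar `pixel_scale` (µm/px). ERG voltages are µV, times ms, flash
energies log10 cd·s/m²; OCT depths and offsets are µm.

## Vessel caliber

The algorithm composes eight stages, each exported and testable on its
own (`measure_vessel()` is their composition):

1. **Centerline thinning** (`thin_centerline`): the manual trace polyline
   is sampled densely (0.25 px) and rounded to an 8-connected,
   deduplicated pixel chain.
2. **Dilation** (`dilate_centerline`): a Euclidean disc of radius twice
   the nominal vessel radius around the chain defines the measurement
   mask.
3. **Brightness normalization** (`normalize_brightness`): a 64-bin
   histogram of the mask is split by Otsu's criterion; the two modal bins
   (background and vessel) define an affine rescale to 0 and 1. This is
   what makes widths exactly invariant under affine intensity transforms
   of the input image, and it fails loudly ("no vessel contrast") on
   degenerate input.
4. **Tangent estimation** (`estimate_tangents`): central differences of a
   moving-average-smoothed chain (half-window 5). Smoothing trades a
   small angular bias where curvature is high for noise immunity on the
   rasterized chain.
5. **Perpendicular slices** (`extract_perpendicular_slices`): bilinear
   samples every 0.25 px along the normal, out to `half_length_px`.
6. **Reference-circle clipping** (`clip_to_circle`): only chain pixels
   strictly inside a circle of fixed physical diameter centered on the
   optic disc contribute, standardizing retinal eccentricity across
   eyes. Circle diameters are specified in µm so the same protocol spans
   ages with different retinal sizes (e.g. 1720 µm vs 2050 µm).
7. **Ensemble averaging** (`ensemble_average`): the pointwise mean over
   at least 20 slices; isolated contamination (crossings, side branches)
   is diluted proportionally to its share of slices.
8. **Mid-brightness width** (`width_at_midbrightness`): the background
   level is the mean of the outer 20% of ensemble offsets, the level is
   `(background + peak)/2`, and the width is the distance between the
   linearly interpolated crossings of the lobe containing the peak.
   Secondary lobes trigger a warning.

On noiseless synthetic vessels the absolute width error is below 0.13 px
for rectangular profiles of 6–24 px across orientations 0–90°, and the
estimated width of a Gaussian cross-section equals its analytic FWHM
within 0.01 µm.

`tortuosity()` (arc/chord) and `fractal_dimension()` (dyadic box
counting, least-squares slope over at least four octaves) are standard
stand-ins for the proprietary pattern metrics of semi-automated grading
software; values are not interchangeable with such tools' outputs.

## Synthetic vessels

`generate_vessel_image()` rasterizes each vessel at 4× supersampling and
box-downsamples, so a "rectangular" vessel has exact fractional pixel
coverage at its edges and the stated `true_width_um` is the exact
mid-brightness width. Gaussian profiles use
`sigma = FWHM / (2 sqrt(2 log 2))` so the stated width is the FWHM.
Overlaps take the pointwise maximum; optional linear background gradients
and Gaussian noise are applied afterward. All randomness flows through a
seed stored in the spec, and the caller's RNG state is untouched.

## ERG models and generator

The B-wave intensity–response follows the Naka–Rushton function
`V(I) = Vmax I^n / (I^n + K^n)` (fit on linear intensity, `K` reported in
log10 units, exponent fixed at 1 by default). The fit profiles `Vmax` in
closed form at each candidate `K`, multi-starts `K` on a grid, and
polishes with Brent's method, making the noiseless fit exact to
optimizer precision.

The A-wave leading edge follows the phototransduction activation model
`R(t; I) = R_max (1 − exp(−½ I ((t − t_d)/t_c)²))` for `t > t_d`, with
`I` in linear cd·s/m². The fit uses samples from flash onset to 90% of
each trace's A-trough time, shares `(t_c, t_d)` across flash energies,
and fixes `R_max` at the maximum recorded A-wave amplitude.

**R_max policy bias.** Because `R_max` is taken from the data rather than
fitted, the fit is only exactly consistent when the series contains a
flash bright enough to saturate the A-wave. Over a series topping out at
1.0 log cd·s/m² the recorded maximum reaches only ~98% of the true
`R_max`, which biases `t_c` by ~2%. Over the activation-fit range used by
default (−1.1 to 2.2 log cd·s/m²) the top flash saturates and recovery is
exact. This is an honest property of the standard measurement policy, not
a defect of the optimizer.

The synthetic generator builds each clean trace as
`−P3(min(t − onset, 20 ms))` (the activation model frozen at its trough,
so the A-trough location and depth are analytic), plus a lognormal-shaped
B-wave scaled by the Naka–Rushton fraction, plus a Gabor OP packet of
fixed peak-to-peak amplitude (hard-truncated at ±3 envelope widths so the
frozen trough stays exact), plus white noise per sweep. Defaults:
`R_max = 300`, `t_c = 18`, `t_d = 4`, `Vmax = 400`, `K = 0.01` (−2 log),
B-peak 100 ms, OP packet 120 Hz / 10 ms envelope / 40 µV, 2000 Hz
sampling, onset 60 ms.

## ERG features

- **A-wave**: prestimulus baseline (50 ms) minus the trough in the
  5–60 ms post-flash window, floored at 0.
- **B-wave**: A-trough to the following peak (window to 200 ms
  post-flash); for weak flashes without an A-trough it is measured from
  baseline (the documented fallback).
- **OPs** (`extract_ops`): the analysis window (flash onset to B-peak +
  50 ms by default) is mean-removed, tapered with a Tukey window
  (fraction 0.3 — chosen empirically as the smallest taper that keeps
  B-wave spectral leakage below 1 µV while preserving in-band
  peak-to-peak amplitudes), forward-FFT'd, zeroed outside the two-sided
  60–235 Hz band, and inverse transformed. The OP magnitude is the
  peak-to-peak of the filtered waveform.

`build_protocol()` enumerates inclusive arithmetic flash ladders with the
standard interstimulus rules (dark-adapted: 0.7 s up to −2.0 log, 10 s
above; light-adapted: 10 s throughout) and 20 vs 5 averaged flashes for
dim vs bright stimuli. Note that the inclusive ladder from −4.7 to 1.0 in
0.3-log steps has 20 grid points; such series are sometimes loosely
described as having 19 intensities, but the builder reports the exact
count. The light-adapted ladder from −0.2 to 2.2 has 9.

## OCT layer thickness

Boundaries (vitreous to sclera): ILM, RNFGC/IPL, IPL/INL, OPL, ELM, RPE.
The RNFL and ganglion-cell layer are never separated (their reflectance
profiles are too similar), hence the combined RNFGC complex; the ELM is
carried in the data model but no reported layer uses it. Reported layers:
RNFGC, IPL, INL, RNFGC+IPL, inner (ILM→OPL), outer (OPL→RPE), total
(ILM→RPE). Thickness is the difference of linearly interpolated boundary
depths along the A-scan axis at ±100…±400 µm from the disc center —
eight sites per layer per eye. Because all layers difference the same
interpolated depth functions, composite layers are exactly additive, a
property the tests verify on 1000 random non-crossing geometries.

## Study pipeline

`run_study()` consumes a manifest (one row per eye/retina recording),
dispatches on modality, logs and skips failing rows, pre-averages
eyes/retinas within animals, and summarizes per (genotype, age_group,
measure) as mean ± SEM (SEM is `NA` for n = 1). The full configuration is
echoed into `run.log` as YAML for provenance. Inferential statistics
(repeated-measures ANOVA, post hoc tests) are deliberately out of scope;
the per-animal long table is their direct input.

`dioptre_equivalent()` records the refraction-measurement floor implied
by MRI axial resolution: at 80 µm resolution and 6.5 µm of axial length
per dioptre, the smallest detectable change is about 12 D.

## Problem sizes and runtime

All validation problems are small: 200×200 px vessel images (rendered at
4× supersampling), 801-sample ERG traces, 101-point OCT boundary grids.
The full test suite, including Monte Carlo acceptance blocks (500
Naka–Rushton replicates, 200 activation-fit replicates, 1000 OCT
geometries, and an 8-animal end-to-end cohort), runs in a few minutes on
one CPU.
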