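---
title: "Quantifying extracellular traps and cell death from two-channel micrographs: methods and design notes"
author: "trapquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trapquant methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`trapquant` implements an image-cytometry pipeline that quantifies, per
imaged field, the fractions of live cells, cells that have undergone
ETosis (expelled chromatin as an extracellular trap), and non-ETotic
dead or dying cells, from dual Hoechst/SytoxGreen staining. This
vignette explains the model behind each stage, the parameters that
matter, the synthetic data the package validates itself against, and
the design decisions taken where more than one reasonable
implementation exists.

## The measurement model

The object of inference is a per-condition composition: the percentages
of live, ETotic and dead cells in a well. The pipeline treats each
field of view as a set of DNA-positive objects and assigns each object
a class from two features, the mean Hoechst and mean SytoxGreen
intensity, on a log10 scale. The biological justification:

* Hoechst is membrane-permeable and stains all DNA, so every object of
  interest is Hoechst-positive to some degree.
* SytoxGreen only reaches DNA behind a compromised membrane. Dead and
  dying cells are strongly Sytox-positive. Extruded ET chromatin also
  takes up both dyes, but spread over a much larger area, so its
  *per-pixel* (mean) intensity is low in both channels.
* ETotic objects are therefore Hoechst-low/Sytox-low and large; live
  nuclei are Hoechst-high; dead nuclei are Sytox-high across a wide
  range of residual Hoechst staining.

The gate rules encode exactly this, in a fixed order: an object is
**dead** if `log10(sytox_mean + eps) > gate_sytox`, *whatever its
Hoechst level* (the dead population spans all Hoechst levels, so the
Sytox gate must win); otherwise **etotic** if
`log10(hoechst_mean + eps) < gate_hoechst` (optionally also requiring a
minimum area); otherwise **live**. Classes are exhaustive and mutually
exclusive by construction.

`eps` (default `1e-6`, on the [0, 1] dynamic-range intensity scale)
makes the log transform total for zero-intensity objects; it is two or
more orders of magnitude below any gate in practice, which is why
classification is invariant to a global exposure rescaling when gates
are re-derived from the rescaled control (a property the test suite
asserts).

### Gate placement

Manual gates are first-class, mirroring an interactive FlowJo-style
workflow in which the analyst draws the boundaries on the control
sample's bivariate plot. Because manual placement is not reproducible
by a script, `auto_gates()` supplies a deterministic default derived
from an unstimulated control population: the Sytox gate at
`median + 3 * 1.4826 * MAD` of control log10 Sytox, and the Hoechst
gate at `median - 3 * 1.4826 * MAD` of control log10 Hoechst. The
scaled MAD estimates the standard deviation robustly (control objects
are dominated by live cells, but contain outliers in both tails), so
each gate sits three robust standard deviations into the tail of the
live population. Gate provenance (`manual`/`auto`) is recorded in every
run manifest.

## Stage order and the reasoning behind it

`run_pipeline()` executes: focus QC → illumination correction →
threshold/segment/declump → measure → merge and QC exclusion → gate →
aggregate → test. QC exclusion happens before any object can
contribute to statistics; intensities are always measured on corrected
but *unsmoothed* images (smoothing exists only to stabilize
binarization).

### Focus QC

The focus score partitions the image into non-overlapping 20 × 20 px
tiles (partial edge tiles dropped — padding would manufacture
low-variance tiles and bias the score down) and averages the per-tile
normalized variance σ²/μ (population variance; tiles with zero mean
contribute zero). A constant image scores exactly 0; a per-pixel 0/1
checkerboard scores exactly 0.5; defocus strictly lowers the score.
Images scoring below 0.2 (default) are removed.

Two design points deserve note:

* The score deliberately scales linearly with exposure (input is on the
  fixed dynamic-range scale, not min-max normalized). A dim image *is*
  less quantifiable, and the test suite pins this documented behaviour.
* The default removal decision uses the **Hoechst channel only**.
  Every object carries Hoechst signal, so the Hoechst focus score
  measures optics; SytoxGreen content tracks the biology of the field
  (a healthy well is legitimately Sytox-dim) and would conflate focus
  with treatment effect. Both channels are always scored and reported,
  and `qc$channels = c("hoechst", "sytox")` restores the conservative
  both-channels rule.

A two-class Otsu split (`otsu_split()`) is exposed alongside: values
are min-max rescaled, quantized to 256 levels, and the threshold
maximizing the between-class variance w0·w1·(μ1−μ0)² is found by
exhaustive scan, ties broken toward the smallest threshold. The test
suite holds it to exact agreement with a brute-force oracle.

### Illumination correction

The background field is the per-block minimum on a 50 px grid, with the
final partial blocks keeping their own minimum, upsampled
nearest-neighbour (piecewise constant, no smoothing). Two combine modes
exist:

* `subtract` (default): `max(image - field, 0)`. A minimum-based
  background estimate behaves like an additive offset, and subtraction
  leaves object amplitudes interpretable.
* `divide`: `image * mean(field) / field`, the natural inverse of a
  multiplicative shading profile. This mode is used when *measuring*
  gradient suppression, because after subtraction the background mean
  is ~0 and a coefficient of variation is no longer meaningful.

The residual nonuniformity after piecewise-constant correction is the
within-block slope, about `amplitude × block_px / image_width`; a
tenfold suppression of a linear gradient therefore requires the field
to span several hundred pixels at `block_px = 50`, which the test
geometry respects. With heavy noise the block minimum underestimates
the background by a few noise standard deviations; a low-percentile
alternative (`statistic = "percentile"`, default 2nd percentile) is
available for that regime.

### Segmentation

The robust background threshold sorts the pixel sample, discards the
lowest and highest 5% (`floor(f*n)` each side), and sets
`T = (trimmed mean + 2 × trimmed SD) × 0.89`, population-SD convention,
foreground strictly greater than `T`. The worked ten-pixel example
{0×8, 100×2} gives exactly 89. This global rule assumes the image is
background-dominated; `segment_pair()` flags as degenerate any
segmentation whose foreground fraction exceeds 0.5 (a constant image,
where `T = 0.89 × value` marks everything foreground, is the canonical
case).

The printed parameter pair "(0.05–50)" in the recipe this pipeline
follows is read as: 0.05 = the outlier fraction trimmed from each tail,
and 50 px = the upper bound on typical object diameter. Both are
independent configuration keys (`lower/upper_outlier_fraction`,
`diameter_range_px`), so either reading can be reproduced if the
original intent differed. The lower diameter bound (5 px) doubles as
the default declumping seed separation.

Which image to segment is not dictated by the two-channel design:
Hoechst alone would miss nothing in principle (all DNA stains), but
dead nuclei can sit at the dim end of a one-decade Hoechst range while
being Sytox-bright. The default segments the pixelwise maximum of the
two corrected channels, which share the [0, 1] dynamic-range scale;
`segment_channel = "hoechst"` or `"sytox"` override it.

Declumping is shape-based: Euclidean distance transform of the mask,
smoothed with a σ = 1 Gaussian (raw distance maps carry pixel-level
ridges that seed spurious watersheds), then a watershed constrained to
the mask, with maxima closer than the seed separation collapsed. On
two-disc fixtures the operating band is: separation ≥ 1.2 r splits into
two labels with the boundary within 2 px of the perpendicular bisector;
separation < 0.5 r merges. Border-touching objects are removed by
default (their features are truncated), and labels are always
relabelled to contiguous 1..N.

The smoothing scale 1.3488 corresponds to σ = scale/1.3488 = 1 px at
the default, so the scale knob is calibrated in the same units as the
upstream tool this recipe originates from while mapping onto a plain
Gaussian σ internally.

### Measurement and statistics

Per-object features are the minimal cytometry set: area, centroid,
integrated and mean intensity per channel (`integrated = mean × area`
by construction). Percentages are computed per well (animal ×
treatment × replicate), technical replicates are averaged per animal
(unweighted — wells are exchangeable), and treatments are compared per
animal with a two-tailed unpaired Student t test with pooled variance,
following the convention that the animal, not the well, is the unit of
biological replication. `stats$unit = c("animal", "replicate")`
switches to treating every well as a sample, since published analyses
of this assay vary between the two conventions; the run manifest
records which was used. A Welch option exists but is off by default,
matching the stated use of the Student form; no multiple-testing
correction is applied because comparisons are reported per treatment
(a Holm step could be added downstream from the stats CSV). Degenerate
inputs are defined exactly: zero pooled variance with equal means gives
t = 0, p = 1; with unequal means, p = 0 flagged degenerate. The star
mapping (`*` < 0.05, `**` < 0.01, `***` < 0.001, `****` < 0.0001,
strict boundaries) is a pure step function.

The effect summary is the mean percent increase over control,
`(mean_T − mean_C)/mean_C × 100`, which requires a positive control
mean and is reported alongside every test.

## The synthetic data generator

No micrographs from the motivating studies are publicly deposited, so
the package ships a generator whose defaults define the study
conditions used by all simulation-based tests:

* **Field geometry.** 512 × 512 px at ~0.65 µm/px (a 20× plate-imager
  scale), 650 cells per field by default. At this pixel scale an
  invertebrate immune-cell nucleus of 4–5 µm maps to a radius of
  ~3.5 px, and several hundred cells per field matches a dense
  monolayer in a 96-well stimulation assay.
* **Live cells**: Gaussian-envelope nuclei (σ = r/2), Hoechst peak
  0.70 of dynamic range with ±0.15 decade per-cell jitter, faint Sytox
  (0.008, log-uniform over half a decade — membrane integrity varies).
* **Nuclear texture**: each nucleus carries 4 condensed-chromatin foci
  (σ = 1.2 px, 0.7 × envelope amplitude). Real interphase nuclei are
  not smooth Gaussians, and this substructure is what a tile-based
  normalized-variance focus metric keys on: with textured nuclei the
  default fields score ~0.3 when sharp and ~0.03 at 4 px defocus,
  bracketing the 0.2 cutoff with a clear margin in both directions.
* **Dead cells**: like live nuclei but Sytox-bright (0.80) and with
  Hoechst drawn log-uniformly over one full decade below 0.70,
  reproducing the "wide range of Hoechst staining" phenotype.
* **ETotic cells**: a diffuse chromatin cloud (Gaussian envelope,
  radius 10 ± 1.5 px, ~8× the nuclear area) with 6 radiating wiggly
  filaments of small bright bumps, rendered with identical geometry in
  both channels at low amplitude (Hoechst 0.18, Sytox 0.003). The
  amplitudes keep the three populations linearly separable in log10
  mean-intensity space after background correction; the `overlap` knob
  (0..1) geometrically collapses them toward the live population for
  stress tests.
* **Nuisance processes**: flat autofluorescence baseline (0.02),
  optional bacterial specks bright in both channels, multiplicative
  linear or radial illumination with exact range [1, 1+amplitude],
  Gaussian defocus, scaled-Poisson shot noise (5000 counts full scale)
  plus additive Gaussian read noise (0.002), clipping to [0, 1].

Everything is driven by a single integer seed: the first RNG draw is
the multinomial class split, and identical config + seed reproduces
bit-identical images. Centroids are placed by dart throwing with a
minimum separation (11 px default) and a border margin; an
over-packed request fails loudly, naming the count achieved. Ground
truth is a cell table plus an integer label mask in which the
later-placed cell wins where extents overlap — with the separation
constraint, overlap is minor, and a fully-overwritten cell simply has
no mask pixels.

What the generator does **not** emulate: optics-accurate point-spread
functions (blur is Gaussian), spatially correlated noise, z-stacks or
time lapse, phagocytosed material, autofluorescent debris
heterogeneity, and chromatin clouds that overlap into connected
carpets at very high ETotic fractions (clouds are placed by the same
centroid process as nuclei). Passing the simulation-based tests
therefore demonstrates that the pipeline's logic is correct and
well-calibrated on scenes with these statistics — not that any given
microscope's data will separate as cleanly; on real data the gates
should be inspected on the control scatter plot before batch use.

## Numerical choices and degenerate inputs

* Gaussian blurs (defocus, threshold smoothing, distance-map
  smoothing) are implemented in the Fourier domain with the analytic
  Gaussian transfer function: mass is conserved exactly, σ = 0 is the
  identity, and blurring by a then b equals one blur by √(a²+b²) to
  machine precision. The boundary is periodic; cells are kept away
  from borders by the placement margin, and border-touching objects
  are excluded downstream.
* Population (divide-by-n) SD in the robust threshold; strict `>` at
  every binarization; smallest-threshold tie-break in the Otsu scan;
  first-appearance relabelling — all fixed for bit-reproducibility.
* 16-bit TIFF I/O quantizes as `round(clip(x, 0, 1) * 65535) / 65535`
  explicitly, so a written dataset reads back exactly equal to the
  quantized in-memory image.
* Empty inputs: an empty mask measures to a zero-row table with the
  full header; an empty metadata CSV reads to an empty list with a
  warning; an empty treatment comparison (fewer than two biological
  units per arm) yields no stats table rather than an error mid-run.

## Problem sizes used by the automated checks

The simulation-based checks run at the package's default field size:
20 fields × 200 sparse nuclei for count recovery; three datasets of
~2,600 truth-labelled objects each (ETotic/dead fractions 5/5, 20/10
and 40/20 percent) for gating recovery against control-derived gates;
and a 4-animal × 2-treatment × 3-replicate experiment (~15,000
objects) for the end-to-end comparison, rerun twice to confirm
byte-identical outputs. Gating recovery is evaluated on
ground-truth-labelled objects so that it measures the gates, not the
segmenter; the end-to-end check exercises both together.

## Known limitations

* The global robust-background threshold assumes background-dominated
  fields; above roughly 25% foreground coverage it rises enough to
  erode faint ET clouds, and very dense stimulated wells will
  undercount ETotic objects (consistently across arms, so relative
  comparisons remain directional).
* Heavily overlapping ET clouds merge into single objects; the
  per-object percentage then undercounts the ETotic fraction at high
  effect sizes.
* Auto gates inherit any contamination of the control: a control well
  with substantial spontaneous ETosis widens the live MAD and relaxes
  both gates.
* The watershed declumper is tuned for convex nucleus-scale objects;
  filamentous ET arms are intentionally *not* split off (they fall
  below the minimum diameter or stay attached to the cloud), but
  exotic shapes outside the 5–50 px diameter band are dropped, not
  split.
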