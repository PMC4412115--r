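---
title: "Classifying cyanobacterial pigmentation phenotypes from fluorescence micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cyanobacterial pigmentation phenotypes from fluorescence micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscope)
```

## The biological problem

Cyanobacteria engineered to secrete ethanol (a pyruvate-decarboxylase /
alcohol-dehydrogenase cassette in *Synechocystis* sp. PCC6803 or
*Synechococcus* sp. PCC7002) down-regulate phycocyanin, the blue antenna
pigment absorbing near 620 nm. Under a fluorescence microscope with a
chlorophyll/phycocyanin filter set this shifts single-cell appearance in a
diagnostic way:

* **wild type / revertant** cells keep the full pigment complement and appear
  **red**;
* **producing** cells, with less phycocyanin, show red and green signals of
  roughly equal intensity and appear **orange**, noticeably dimmer;
* **dead** cells lose their photopigments and show only an unspecific
  **green** fluorescence.

Production cultures slowly accumulate revertants — mutants that lost the
cassette, regained wild-type pigmentation and outgrow producers — so a fast
per-cell census of these three classes is a practical process-monitoring
tool. Bulk absorption spectroscopy sees only the culture average (the
PC/Chl ratio, `pc_chl_ratio()`); the pipeline in this package counts single
cells.

## The pipeline

### Flat-field correction

Microscope illumination is never uniform. `correct_illumination()` divides
each channel by a blank (no-sample) image and rescales by the blank channel's
mean, so corrected brightness stays comparable across sessions:

\[ I'(x, y) = I(x, y) \cdot \frac{\overline{B}}{B(x, y)} \]

The blank is median-smoothed (5×5 by default) first; raw division would
inject the blank's shot noise into every corrected image. Arithmetic is done
in floating point and the result is rounded half-up to 8-bit at the end.
A blank pixel that is still ≤ 0 after smoothing is a hard error naming the
channel and pixel, since division there is meaningless.

### Segmentation

`segment_cells()` thresholds the red and green channels independently with
the maximum-entropy criterion of `kapur_threshold()`: the threshold
maximizes the sum of Shannon entropies of the intensity distributions below
(background, levels ≤ t) and above (foreground) the candidate level.
Candidates that leave either class empty are skipped rather than scored
zero, and exact ties resolve to the smallest threshold. Thresholding only
red and green is deliberate: chlorophyll autofluorescence puts live cells in
the red channel, dead cells appear only in green, and the blue channel
carries no signal of interest. The two binary masks are combined by
pixelwise union — this is what lets a purely green (dead) cell be registered
at all — and connected components are labeled with 8-connectivity, the
particle-analyzer default (4-connectivity is available via the
`connectivity` argument). Two artifact filters follow: particles smaller
than 10 px ("smaller than" read strictly, so area ≥ 10 survives) and
particles touching the image edge are excluded, each tallied separately.
The filters commute, so their order is immaterial.

Touching cells merge into one particle: there is no watershed splitting.
This is a documented limitation; the protocol fixes cells in a sparse
monolayer where contacts are rare.

### Features

For every surviving particle `particle_features()` records a normalized hue
histogram plus the mean brightness. Hue and value come from the standard
hexcone RGB→HSV transform (red ≈ 0, yellow ≈ 1/6, green ≈ 1/3 on a 0–1
scale; value = max channel / 255). Choices worth stating:

* **32 hue bins** by default. The bin count is a resolution/sample-size
  trade-off: 256 bins would give ~3 px per bin for a typical 100-px cell and
  mostly-empty histograms. 32 bins put the three phenotype hues about 3–9
  bins apart while keeping histograms well populated; the count is
  configurable (`bins`) and recorded in the model fingerprint, so training
  and prediction can never silently disagree.
* **Achromatic pixels** (max = min, hue undefined) take hue 0 by convention.
  They are rare inside segmented cells; any fixed convention works as long
  as it is the same at training and prediction time.
* **Brightness is appended** as one extra input (length `bins + 1`), not
  normalized jointly with the histogram. It is what separates the dim orange
  producers from bright red wild types when their hues are close.
* Features are extracted from the **same corrected image** that was
  segmented.

Note that hue is circular: under noise, red pixels (hue ≈ 0.03) can wrap to
values near 1. The classifier consumes the whole histogram and is
indifferent to the wrap; anything that summarizes particle hue as a single
number (as one of the test suites does) must use a circular mean.

### The classifier

`phenonet()` fits a feed-forward network with one hidden layer (default 10
units), sigmoid activations throughout, one-hot targets and sum-of-squares
loss — the classic compact architecture for a 33-input, 3-class problem.
Training alternates two optimizers:

1. **Resilient propagation** (the iRPROP⁻ variant, no weight backtracking)
   on the full batch, with the standard literature constants η⁺ = 1.2,
   η⁻ = 0.5, Δ₀ = 0.1, Δmax = 50. RPROP uses only gradient signs, which
   makes it robust to the badly scaled gradients sigmoid saturation
   produces.
2. A **genetic algorithm** that engages when RPROP stalls — when the
   relative change of the training misclassification rate over a 20-epoch
   window drops below 1% while the rate is still above target. The
   population (30) is seeded from the current weights plus Gaussian
   perturbations (σ = 0.2); fitness is the training error with
   sum-of-squares loss as tie-breaker; two elites survive unchanged, so the
   best individual can never get worse; parents are picked by tournament of
   three with uniform crossover and Gaussian mutation, for 25 generations.
   RPROP then resumes from the GA's best individual with fresh step sizes.

Training stops when the training misclassification rate reaches the target
— **0% by default**, i.e. the schedule keeps alternating until every
training particle is classified correctly — or when the epoch (2000) or GA
round (10) budget runs out, in which case the model is returned flagged as
non-converged. Whether the 1% stall criterion is relative or in absolute
percentage points is a genuinely open reading; this implementation uses the
relative change (an absolute rule would fire constantly once the error is
small, e.g. a 2% → 1.5% improvement), and both the threshold and window are
exposed in `phenonet_control()`.

Stopping at exactly 0% training error invites overfitting on noisy training
sets. `phenonet_control(validation_fraction = )` provides an optional
held-out monitor that returns the weights with the best validation error,
but it is off by default: the reference protocol trains to zero.

Determinism: a fixed `seed` fixes initialization, the GA and hence the whole
trajectory. Models serialize to versioned JSON (`save_phenonet()`) with
17 significant digits, so a reloaded model predicts bit-for-bit identically.

### Sample reports and the mixing experiment

`analyze_sample()` runs correction → segmentation → features → prediction
over a batch of micrographs sharing one blank (the blank is smoothed once
for the batch), aggregates counts, and enforces the accounting identity
*registered = excluded + classified* per image and overall. Fractions are
reported both over all classified particles and over viable (non-dead)
particles, because culture mixtures are usually quoted among live cells
while dead-cell percentages are quoted over everything. A warning is issued
below 500 classified cells, the lower end of the 500–1000 cells per sample
the microscopy protocol aims for (20 stage positions per sample).

`mixing_experiment()` is the in-silico reconstruction of the validation
experiment in which wild-type and producer cultures are mixed at known
ratios: for each requested wild-type fraction and replicate it renders
synthetic micrographs, analyzes them with a trained network, and tabulates
estimated against true fractions. Defaults: 1000 cells per sample over 20
images, ratios {0, 5, 10, 25, 50, 100}% wild type, three replicates.

### Spectra

`normalize_spectrum()` rescales an absorption spectrum so A(680 nm) — the
chlorophyll *a* peak — equals 0.45, the plotting convention that makes
phycocyanin differences between cultures visible at a glance. The reading is
taken at exactly 680 nm by linear interpolation rather than by local peak
finding: the fixed wavelength is the reproducible choice and is immune to
noise-induced peak shifts. `pc_chl_ratio()` returns A(620)/A(680), which is
scale-invariant and therefore commutes with normalization; normalization is
idempotent.

## The synthetic micrograph generator

No annotated micrographs of these strains are publicly deposited, so the
package carries its own scene generator (`render_scene()`, `render_blank()`)
and every downstream claim is validated against its ground truth.

What it emulates, and the defaults chosen:

* **Cells** are axis-aligned ellipses with radii drawn uniformly from
  3–8 px — round-to-elliptical cocci as they appear at 40× magnification,
  where no pixel-size calibration is published; the range is a judgment call
  exposed in `phenotype_spec()`.
* **Colors**: WT_RED (200, 40, 10), PRODUCER_ORANGE (150, 130, 10),
  DEAD_GREEN (30, 180, 20), each with per-pixel Gaussian spread σ = 15.
  These place the three phenotypes at hues ≈ 0.03, 0.14 and 0.32 — separated
  the way the real phenotypes are — and make producers dimmer than wild
  type, matching the observation that the producer's red and green signals
  are approximately equal and less bright.
* **Illumination**: a radial quadratic vignette, multiplicative, with
  center-to-corner ratio 1/(1 − strength) and default strength 0.25 — the
  simplest smooth field with the right character. The field is normalized to
  unit mean: the blank is this field at mid-gray (mean 128), and with the
  mean-rescaling division convention a unit-mean field is exactly what
  flat-field correction inverts, which keeps the round-trip property exact
  rather than true only up to a brightness factor.
* **Noise**: additive Gaussian read-out noise (default σ = 5) on a dark
  background (level 10), applied after the field.
* **Placement**: rejection sampling on a minimum center distance (default
  19 px, keeping default-size cells from touching); a scene that cannot be
  placed errors out rather than silently overlapping. Ground truth records
  the pre-noise pixel membership of every cell.

Images are held in memory as double arrays on the 8-bit scale \[0, 255\];
quantization to integer levels happens at file I/O and at the end of
illumination correction. This keeps the generator↔correction round trip
exact to well under one intensity level and costs nothing downstream, since
histograms bin by rounding anyway.

What it deliberately does **not** model: point-spread blur, photobleaching,
cell clumping and division, focus drift, and intermediate ("dying")
phenotypes. Passing the in-silico validation therefore shows that the
algorithmic chain — correction, thresholding, registration, features,
classifier — is implemented correctly and recovers known mixtures under
realistic noise and shading; it does not certify performance on real
micrographs, where debris, clumps and partially induced cells exist. On the
real data the original protocol reported, for example, ~90% of wild-type
culture cells recognized as wild type with a few percent spilling into the
producer class; such numbers depend on biology (not-fully-induced cells,
revertants, dying cells) that the generator intentionally leaves out.

## Numerical and degenerate-input choices

* Kapur thresholding requires histogram mass in at least two bins; a flat
  channel is a hard error naming the channel (a blank micrograph is not a
  sample).
* The ±1-level round-trip guarantee of flat-field correction holds in the
  unclipped regime; where field × intensity exceeds 255 the clip is, by
  construction, not invertible. Default scene settings keep cell interiors
  below the clip.
* Ties: Kapur threshold → smallest level; prediction argmax → earliest
  class in `cell_classes()` order (WT_RED, PRODUCER_ORANGE, DEAD_GREEN).
* Particle labels are assigned in row-major scan order, consecutively from
  1, before and after filtering.
* Empty scenes, empty particle sets and single-particle masks are all legal
  and covered by tests.

## Problem sizes used for validation

The shipped test-suite and the acceptance script validate at the scales the
protocol itself describes: training sets of 300 particles (100 per class),
samples of ~1000 cells over 20 micrographs of 1024×768 px, mixing ratios
{0, 5, 10, 25, 50, 100}% wild type with three replicates, and held-out
accuracy measured over ten independent seeds. Smaller scenes (≈ 256×340 px,
20–50 cells) are used where a property does not depend on scale.

## Known limitations

* No splitting of touching cells; dense fields undercount.
* One blank per batch; sessions with drifting illumination need re-blanking.
* The classifier is a color model: phenotypes that differ only in
  morphology are out of reach by design.
* Training to 0% error memorizes label noise if the training scenes are
  mislabeled; use `validation_fraction` when training on hand-curated real
  data.
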