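---
title: "Quantifying light-induced nuclear condensates: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying light-induced nuclear condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photobodykit)
```

## The measurement problem

Blue-light photoreceptors such as CRY2 form sub-nuclear condensates
("photobodies") with partner transcription factors within seconds to minutes
of illumination. The quantities of interest are simple but must be computed
consistently: how enriched a condensate is over its surroundings (partition
ratio), how round it is (circularity), how big and how numerous condensates
are per nucleus, how mobile the protein inside a condensate is (FRAP), how
completely condensates dissolve when the light goes off, how strongly a
transcription factor occupies a promoter element (ChIP-qPCR), and how a
downstream promoter-luciferase reporter oscillates. This vignette records
the models behind each statistic, the conventions the package fixes where
common practice is ambiguous, and what the synthetic-data tests do and do
not demonstrate.

## Segmentation

Nuclei are segmented by a global Otsu threshold on the frame, keeping the
largest 8-connected component and filling holes. One refinement matters:
intensities are winsorized at the 90th percentile before the histogram is
formed (`clip_quantile`). Bright condensates can contribute most of the
intensity variance of a frame even at a few percent area, in which case
plain Otsu splits nucleoplasm from condensate rather than background from
nucleus, and "the largest bright component" becomes a condensate. Clipping
the top decile removes that failure mode while leaving the
background/nucleus split untouched; since quantiles scale linearly with
intensity, the mask remains exactly invariant under multiplying the frame by
a positive constant. The cost is an assumption that the nucleus occupies
more than 10% of the frame — true for images cropped around a nucleus, the
intended input.

Condensates are within-nucleus pixels brighter than the within-nucleus mean
plus `k_sigma` (default 3) within-nucleus standard deviations. This replaces
the manual, unrecorded intensity threshold of interactive ImageJ analysis
with a reproducible, scale-equivariant rule. Pixels are grouped 8-connected
— two regions touching only diagonally are one object — and regions smaller
than `min_area` (default 4 px) are discarded, a concrete reading of the
field's convention that tiny, indistinct puncta are not counted. Both
defaults are declared choices, not values inherited from any particular
study, and are configurable.

Perimeters use a Crofton (integral-geometry) estimator built from the
2 x 2 pixel-configuration histogram with four projection directions. On
rasterized disks it carries a small positive bias — about 4% at radius
10 px, under 1% at radius 50 px — so circularities of genuinely round
objects come out slightly below 1 (0.94-0.99 over that radius range), and
tests of shape statistics use tolerances, never equality. The implementation
is checked in the test suite against reference perimeter values for
rasterized disks computed with an independent implementation.

## Condensate statistics

**Circularity** is `4 * pi * area / perimeter^2`, dimensionless, 1 for a
circle; elongation at fixed area strictly decreases it.

**Partition ratio** is condensate intensity over background intensity. Two
background conventions coexist in practice and both are supported,
selected by the `context` flag at detection time: the mean of the full
image for in-vitro droplet fields, and the mean of the whole nucleus for
in-vivo nuclear images. "Photobody intensity" is read as the region's mean
pixel intensity, consistent with the per-time-point form below; an
integrated-intensity variant is available via `intensity_mode = "sum"`.
A sample in which no particles are detected is assigned the value 1 —
the no-enrichment baseline — rather than NA, so failed-assembly conditions
enter group statistics at their biologically meaningful value. Both ratio
forms inherit this rule.

**Per-time-point partition ratio** (the form used for split-fluorophore
interaction assays) is `sum(P_i) / (n * N)` with `P_i` the per-photobody
intensity, `n` the count and `N` the nucleus mean. Algebraically this equals
`mean(P_i / N)`; the identity is enforced in the property tests. Both ratios
are invariant under rescaling all raw intensities by a positive constant,
because numerator and denominator scale together.

**Size fraction** is `count(area > threshold) / count(total)` with a
strictly-greater comparison. The conventional cutoff 0.75 is kept as the
default, but its units are whatever units the supplied areas are in: the
pipeline's `stats.csv` applies it to areas expressed as percent of nucleus
area, a declared choice (`size_units = "pixels"` applies it to raw pixel
counts instead).

**Normalized size series**: per nucleus, mean condensate area divided by
nucleus area; averaged over nuclei per time point; the series is then
divided by its first value so time point one is 1. The normalization basis
(per-nucleus relative area, anchored at the first time point) is a package
convention; other anchors (e.g. per-image area in vitro) can be built from
the raw columns.

## FRAP

The four-step double normalization is applied exactly in order:
background subtraction of both channels (`I - B`, `R - B`), division by
the reference to cancel acquisition photofading, then division by the
pre-bleach value so `I_c3(p) = 1` to machine precision. `B` is a scalar
collected pre-bleach; no per-frame background drift is modelled. The
pre-bleach state is a single time point, index 1 by default, and the first
post-bleach frame is `p + 1` unless configured. Traces whose reference
falls to or below background are rejected with the offending index, since
the division is then meaningless.

The optional recovery model is the single-exponential
`f(t) = f0 + (plateau - f0) * (1 - exp(-k t))` fitted by
Levenberg-Marquardt least squares on the post-bleach points, with the
mobile fraction `A = (plateau - f0) / (1 - f0)` and half-time `ln(2)/k`.
Initial values are taken from the data (first post-bleach point, tail mean,
quarter-span rate); `k` is bounded below by a tiny positive constant. A flat
post-bleach curve (sd below 1e-10) short-circuits to `A = 0` with an
undefined rate instead of a degenerate fit. Diffusion-regime FRAP models are
deliberately out of scope; for condensates with reaction-dominant exchange
the single exponential is the standard first-order summary. Each nucleus is
normalized first and averaged afterwards when multiple traces are combined.

## Light cycles

Assembly/disassembly experiments follow a programmed schedule (the default
mirrors the common 10 min on / 10 min off design). Every frame is
segmented and measured independently — no tracking of individual
condensates — and tagged with its cycle and phase. End-of-phase values are
means of the last 3 frames of the phase, a noise-robustness choice. The
reversibility index `(PR_end_off - 1) / (PR_end_on - 1)` maps complete
disassembly to 0 and none to 1. Frames where segmentation or detection
finds nothing take partition ratio 1, the same failed-sample convention as
above; a cycle whose end-of-light ratio does not exceed 1 has no defined
index and errors rather than returning 0/0.

## ChIP-qPCR

The enrichment arithmetic is
`Adjusted input = Raw Ct(input) - log2(fraction of total input)` and
`IP/Input = 2^(Ct(adjusted) - Ct(sample))`, with amplification efficiency
fixed at 2. The default `convention = "paper"` takes the fraction in the
printed percent figure — a 1.25% aliquot subtracts `log2(1.25) = 0.32`
cycles. This differs from the widespread percent-input protocol, which
subtracts the dilution factor `log2(100/1.25) = 6.32`; that form is exposed
as `convention = "standard"`. The two differ by the constant factor
`100/fraction^2` in the final enrichment, so within-experiment comparisons
are unaffected but absolute values are not interchangeable. Both
conventions appear in published protocols and neither can be inferred from
a Ct table after the fact, so both are implemented, the percent-figure
form is the default, and the choice is an explicit argument rather than a
silent "correction" of one to the other.

## Bioluminescence

Two normalizations, applied per replicate: division by the first time point
(induction kinetics start at 1), optionally followed by division by the
series maximum (rhythm traces peak at 1). Both are idempotent and invariant
to rescaling the raw counts. The windowed amplitude operator, `(max -
min)/2` inside a time window, is the minimal statistic for comparing
pulse-perturbed and free-running rhythms; for a pure cosine sampled over a
full period it equals the cosine amplitude up to discretization. Rhythm
*fitting* (period, phase, relative amplitude error) is intentionally not
implemented — established spectral services do that — beyond an unexported
periodogram helper used for QC.

## The synthetic-data generator

The generator exists so every downstream stage can be tested against known
truth. It emulates: nuclei as uniform bright disks on a dark background;
condensates as hard-edged disks at `nucleoplasm x fold` intensity
(optionally Gaussian-blurred; blur is off by default so pixel-sum identities
are exact); additive Gaussian read noise clipped at zero (no Poisson
component — shot-noise modelling would add a parameter no downstream
statistic is sensitive to at the SNRs tested); FRAP traces in which ROI and
reference fade at a common rate, so the double normalization removes fading
exactly and the ideal normalized curve is `(1-d) + dA(1 - exp(-kt))`;
first-order condensate assembly toward a plateau in the light and
first-order decay toward `1 + residual x (assembled - 1)` in the dark;
damped-cosine luminescence rhythms; and Ct tables constructed by inverting
the enrichment equations. Illumination power is not mapped to assembly
rate — no such calibration exists — so kinetic rates are free parameters.

Default study conditions: 128 x 128 px scenes, nucleus radius 0.35 x the
frame, condensates of radius 4 px at fold-enrichment 5, nucleoplasm 2000
and background 200 intensity units with read-noise sd 100 (SNR 20 relative
to the nucleoplasm level); FRAP traces of 100 frames at 1 s with bleach
depth 0.9, mobile fraction 0.8, rate 0.1 s^-1, on an order-1 intensity
scale so a noise sd of 0.01 is 1% of the bleach dynamic range; two
10-min/10-min light cycles sampled every 60 s; luminescence sampled every
20 min over 96 h. These sizes keep the full test suite under a minute on
one core while leaving every recovery tolerance comfortably resolvable.

What passing tests show — and what they do not. Recovery of truth from
these scenes demonstrates the *arithmetic and the segmentation contract*:
counts, areas and ratios are recovered within stated tolerances (partition
ratio within 5% at SNR >= 10; FRAP A and k within 5% at 1% noise; ChIP
enrichment exactly when noiseless; every disjoint fold-5 disk found). Real
micrographs violate the generator's assumptions in known ways: textured
nucleoplasm, out-of-focus light, anisotropic PSF, condensate fusion and
movement, bleaching during acquisition beyond a single common fade rate.
The tests therefore validate the pipeline's correctness, not its
performance on adversarial real data; threshold parameters (`k_sigma`,
`min_area`) should be checked against a few hand-annotated nuclei in any
new imaging configuration.

## Numerical and interface conventions

Coordinates are R-native 1-based (row, col); areas are pixel counts unless
a `pixel_size` converts them to physical units. Images travel as grayscale
uint16 multi-page TIFF (page = time); tables as comma-separated CSV with a
mandatory header, '.' decimal separator and UTF-8; FRAP CSVs carry
`background` and `prebleach_index` as `#`-comment header fields; configs
are `key: value` text with an explicit `seed`. Every generator takes a
seed and restores the caller's RNG state, so identical parameters and seed
give bit-identical outputs without disturbing the session. Readers reject
missing, negative and non-finite values with errors naming the file,
column and line. Component labeling is deterministic (first-encounter,
column-major), which makes the label-matrix comparison against the
exhaustive flood-fill oracle in the tests exact rather than
up-to-relabeling.

## Known limitations

No 3D segmentation, PSF deconvolution or condensate tracking; no
diffusion-model FRAP; no qPCR efficiency correction or melt-curve QC; no
rhythm-parameter estimation; no reading of proprietary microscope formats.
The Crofton perimeter's bias means absolute circularities near 1 saturate
slightly low; comparisons *between* conditions measured at similar
condensate sizes are unaffected.
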