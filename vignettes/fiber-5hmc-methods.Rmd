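---
title: "Methods: single-molecule 5hmC quantification on stretched DNA fibers"
author: "fiberHMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule 5hmC quantification on stretched DNA fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberHMC)
```

## The measurement

5-hydroxymethylcytosine (5hmC) is an oxidized cytosine modification whose
global level varies strongly between tissues and drops in many cancers.
In the single-molecule assay this package analyzes, each genomic 5hmC
residue is enzymatically glucosylated with an azide sugar and click-labelled
with a fluorophore; the DNA is then stretched into near-linear fibers on an
activated glass surface and imaged in two channels: an intercalating dye
shows every molecule's backbone, and the label channel shows one
diffraction-limited spot per (resolvable) 5hmC site.

The statistic is simple by design:

$$D = \frac{N}{L}$$

where $N$ is the number of label-channel spots collocalized with a traced
backbone and $L$ is the total traced DNA length in pixels, summed over all
molecules of a sample. Pooling always sums numerators and denominators —
the density of the concatenated data — never averages per-image densities.

$D$ is converted into an absolute fraction of nucleotides:

$$\%5hmC/dNTPs = 100 \cdot \frac{D \cdot C / \varepsilon}{\text{bp/px}},
\qquad \text{bp/px} = \frac{\text{pixel size (nm)}}{0.34\,\text{nm/bp} \cdot s}$$

with $\varepsilon$ the labelling efficiency (probability a 5hmC site
carries a fluorophore), $s$ the DNA stretch factor (realized extension
relative to the 0.34 nm/bp B-form rise), and $C$ the cluster correction —
the mean number of fluorophores per resolvable site, estimated from
photobleaching step counting (below). When a well-characterized reference
sample is imaged side by side, the result is additionally rescaled by
(known % of the reference) / (measured % of the reference), which absorbs
day-to-day variation of $\varepsilon$ and $s$.

With 160 nm pixels and $s = 0.85$ one pixel of backbone represents
$160 / (0.34 \cdot 0.85) \approx 554$ bp, so tissue-level densities of
$2\text{–}6\times10^{-5}$ marks per base correspond to roughly one spot
per 30–90 px of DNA — sparse dots on long fibers, which is what makes
counting tractable.

## Pipeline stages and their tunable parameters

### Backbone tracing (`segmentBackbones`)

1. Background estimation by grayscale morphological opening (disc radius
   `bgRadiusPx = 10` px), subtracted from the channel.
2. Light Gaussian smoothing (`smoothSigmaPx = 0.7` px) to suppress
   single-pixel noise before thresholding.
3. Robust threshold at `median + thresholdK × MAD` (`thresholdK = 6`).
   Otsu's method is available (`threshold = "otsu"`) but is not the
   default: DNA occupies only ~1% of a field's pixels, and with so small
   a foreground class Otsu bisects the background noise mode and floods
   the mask. A noise-relative threshold has no such failure mode and is
   invariant to exposure rescaling. A fixed numeric threshold is also
   accepted.
4. Connected components; objects smaller than `minAreaPx = 15` px are
   debris.
5. Guo–Hall thinning to one-pixel skeletons. Guo–Hall was chosen over
   Zhang–Suen because the latter leaves two-pixel staircase artifacts on
   diagonal strokes, and combed molecules sit at arbitrary small angles.
6. Spur pruning (branches shorter than `spurLengthPx = 5` px ending at a
   branch point).
7. Discards, logged with reasons: objects that still contain branch
   points (`branched`: crossing or overlapping molecules — splitting
   them would require resolving junction ambiguity and could bias the
   length denominator, so they are dropped entirely), objects touching
   the image border (`border`: truncated length), mean width above
   `maxWidthPx = 6` (`wide`: aggregates), and paths shorter than
   `minLengthPx = 20` px ≈ 11 kb (`short`: debris). Because a discarded
   molecule loses its spots *and* its length, discards do not bias the
   density ratio.
8. Remaining skeletons are ordered endpoint to endpoint; length is the
   sum of per-step costs, 1 for axial and $\sqrt2$ for diagonal moves.

The digital length estimator has a known small-angle property: an
8-connected path for a line at angle $\theta$ measures
$\cos\theta + (\sqrt2-1)\sin\theta$ per unit length, up to ~3% above the
Euclidean length at the few-degree angles typical of combing. This is
partly offset by slight end erosion of the thresholded mask. Both effects
are stable across samples and cancel in group comparisons; in absolute
terms they are part of what the side-by-side reference normalization is
for.

### Spot detection (`detectSpots`)

Difference-of-Gaussians band-pass at the PSF scale (`psfSigmaPx`,
default 130 nm / 160 nm ≈ 0.81 px, and 1.6× that), local maxima,
threshold at `thresholdK × MAD` of the filter response (default 6 —
chosen so that a blank 128×128 noise frame yields a false spot in under
1% of frames, while spots at signal-to-noise ≥ 10 score far above
threshold), merging of maxima closer than `minSeparationPx = 2` px
keeping the brighter, and subpixel refinement by intensity-weighted
centroid in a 5×5 window after local-median background subtraction.
Thresholding on noise units makes detections invariant to positive
rescaling of the image. Weighted centroids localize well within 0.5 px
here, sufficient for colocalization at ~2 px tolerance; Gaussian fitting
would only matter for super-resolution uses out of scope.

Two fluorophores closer than roughly the diffraction limit (200–300 nm,
i.e. 300–1000 bp on a stretched fiber) merge into one detected spot.
That loss is not a detection defect to fix but a physical property of
the assay; it is exactly what the photobleaching cluster correction
accounts for.

### Colocalization (`assignSpots`)

Each spot is assigned to the molecule whose path minimizes the Euclidean
distance, if that distance is ≤ `maxDistPx = 2` px (~320 nm at 160
nm/px: localization error plus label linker length). Ties go to the
lower molecule id so the assignment is deterministic; everything else is
an orphan, reported separately and never counted into the density. An
optional constant channel offset in the run configuration compensates
fixed two-filter registration shifts.

### Photobleaching step counting (`fitSteps`)

Traces of single sites bleach in discrete downward steps, one per
fluorophore. The fit is an exact dynamic program over all change-point
positions minimizing

$$\mathrm{RSS} + \lambda \, m \log n$$

with $m$ change points; $\lambda$ defaults to $3\hat\sigma^2$ with
$\hat\sigma = \mathrm{mad}(\Delta x)/\sqrt2$, a BIC-flavored penalty that
scales with the noise variance, making the fitted step count invariant
to affine intensity transforms. Exactness (no heuristic sliding tests)
is what allows the fit to be verified against brute-force enumeration in
the test suite. Only downward change points count as bleaching steps;
upward jumps (blinking) are fitted but not counted, a conservative
choice. At signal-to-noise 5 the fit recovers 1–3 fluorophores correctly
in ≥ 90% of simulated traces. Step counts across many spots give the
cluster-size distribution $p_k$ ($k \le K_{\max} = 5$; zero-step traces
carry no site and are excluded) and $C = \sum_k k\,p_k \ge 1$.

### Sample-level QC (`convergenceCurve`, `splitHalfSD`)

The convergence curve plots running density against cumulative DNA as
molecules accumulate in acquisition order; the sample is declared
converged when the trailing 20% of cumulative length stays within 5%
(relative) of the final density. These two numbers operationalize
"reaching a plateau" and are configurable; the endpoint itself is
order-invariant.

The split-half statistic shuffles molecules with the run seed, assigns
them longest-first to whichever half has less total DNA (halves land
within a few percent of each other), and reports
$|d_1-d_2|/\sqrt2 / \bar d \times 100$ — the two-value sample SD over
the mean. Well-sampled runs sit far below the 10% QC ceiling; the
statistic shrinks toward 0 as molecule count grows.

### Group comparison (`compareGroups`)

Welch's *t* (default) or Mann–Whitney on per-sample %5hmC, reporting
group means, fold change and the two-sided p-value. Welch is the default
because cohort groups are small, unequal in size and not
variance-matched.

## The synthetic-scene simulator

Every stage above is validated against `renderScene`, which draws:

* molecule lengths — lognormal with 30 kbp mean (the fragment scale of
  the assay's typical preparations) and sdlog 0.35;
* straight segments with Gaussian angular jitter (SD 5°) about the
  stretching axis — combed DNA is near-linear, so curvature is not
  modelled;
* per-base Bernoulli 5hmC marks at `markDensity`, thinned to
  fluorophores with probability `labellingEfficiency`;
* an analytic Gaussian-PSF rendering (error-function profile for finite
  segments; 85 nm backbone / 130 nm label PSF sigma at the default
  wavelengths and NA);
* EMCCD-like noise: Poisson on signal + background photons, multiplied
  by the EM gain, plus Gaussian read noise, clamped to 16 bits. The
  excess-noise factor of real EM registers is omitted; it would inflate
  shot noise by ~√2 without changing any tested mechanism, and the
  detection thresholds are noise-relative anyway.

Molecules that would leave the field are re-placed up to 100 times, then
clipped with the ground truth recording the clipped length, keeping
totals exact. Identical spec + seed gives bit-identical images, which the
determinism tests rely on. Default intensities put single fluorophores at
signal-to-noise ≈ 18, comfortably above the regime where detection, not
optics, would limit the assay — matching long-exposure acquisition of
bright dyes.

Absolute-recovery validation mirrors the assay's full calibration path:
`simulateClusterCorrection` matches ground-truth fluorophores to the
spots they merged into, simulates a photobleaching trace per spot,
counts steps with the change-point fit and returns the resulting $C$.
Applying that $C$ (with matched $\varepsilon$, $s$ and pixel size)
closes most of the diffraction-merging deficit: recovery lands within a
few percent of the generating density across the tissue presets, versus
a 4–8% shortfall if clustering were ignored — which is the point of the
correction.

Preset specs named after tissue groups span mark densities from
$1.9\times10^{-5}$ to $5.9\times10^{-5}$ per base (0.0019–0.0059
%5hmC/dNTPs), the range this assay observes between blood cancers and
healthy colon.

What the simulator does **not** emulate — molecule curvature, optical
aberrations and field-dependent PSFs, stage drift, surface
autofluorescence structure, fragment-length correlations with 5hmC
content — bounds what passing tests prove: they validate the estimator
and its statistics under the stated image-formation model, not the
microscope itself. On real data the absolute scale additionally leans on
the calibration constants and the reference standard.

## Numerical and design choices

* Coordinates are 1-based (row, col) with pixel centres at integers,
  the native R convention, used consistently across images, traces,
  truth records and serialized tables.
* The B-form rise is fixed at 0.34 nm/bp; the stretch factor is the
  single knob relating physical to rendered length.
* Change-point ties in the step fit resolve toward fewer change points,
  then earlier positions — fits are reproducible to the bit.
* `splitHalfSD` uses the $n-1$ two-value SD ($|d_1-d_2|/\sqrt2$), stated
  explicitly because "SD of two values" is ambiguous in the field.
* Degenerate inputs are contracts, not crashes: zero-length paths warn
  and return 0; empty samples produce files with flagged null density;
  an all-flat image segments to nothing; all-zero-step trace sets raise
  "no analyzable sites".
* Validation scales: property and acceptance tests use 14 fields of
  1024×1024 px with 90 molecules each (~1,260 molecules, ~34 Mb of DNA
  per sample) — enough DNA that sampling error of the density sits near
  2–3%, well inside the bounds being checked, while a full sample
  analyzes in well under a minute.

## Known limitations

* Absolute accuracy at the highest densities carries a few-percent
  negative bias from diffraction-limit merging of nearby marks (partially
  recoverable via $C$) and a few-percent length-estimator bias at shallow
  angles; both are stable and shared across samples.
* Crossing molecules are discarded, not split; in extremely dense fields
  this reduces usable DNA per image (it does not bias the ratio).
* $\varepsilon$ and $s$ are configuration inputs, not estimated from the
  images; absolute results inherit their uncertainty unless the
  reference-standard normalization is used.
* Bleach traces are expected as extracted intensity series; photometry
  from raw movies is out of scope.
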