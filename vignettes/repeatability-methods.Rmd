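---
title: "Methods: lesion-level test-retest repeatability of PET radiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion-level test-retest repeatability of PET radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrep)
```

## The problem

Quantitative PET biomarkers — SUV metrics, lesion volume, and radiomics
texture descriptors — are only usable for response assessment if their
intrinsic test-retest measurement variability is known: an observed change
smaller than the repeatability limits cannot be attributed to biology. In
metastatic prostate cancer imaged with PSMA-targeting tracers this question
arises twice: repeating a scan with the *same* tracer (intratracer), and
repeating it with a *different* tracer (intertracer), as both gallium- and
fluorine-labelled PSMA ligands are in clinical use and have different
biodistributions.

`petrep` implements the full lesion-level analysis chain for this question:
paired image ingestion, SUV-threshold segmentation support, conventional
metrics, an IBSI-aligned radiomics catalogue with an image-filter bank, and
the repeatability statistics. Because clinical test-retest scans cannot be
redistributed, the package ships a synthetic paired-phantom generator whose
injected variability is known exactly, so every stage is testable end to
end and estimator calibration can be demonstrated rather than assumed.

## Repeatability statistics

For each biomarker, paired lesion-level values $(y^{test}_i, y^{retest}_i)$,
$i = 1..n$ (lesions pooled across subjects, the lesion being the unit of
replication), are reduced to relative differences with the pair mean as
denominator (the Bland-Altman convention):

$$d_i = 100\cdot\frac{y^{retest}_i - y^{test}_i}{(y^{test}_i + y^{retest}_i)/2}.$$

From these:

* **wCV** (within-subject coefficient of variation):
  $\mathrm{wCV} = \sqrt{\sum_i d_i^2 / (2n)}$, the paired-replicate
  estimator of the within-subject CV.
* **RC** (repeatability coefficient): $\mathrm{RC} = 1.96\sqrt{2}\,
  \mathrm{wCV} \approx 2.77\,\mathrm{wCV}$, the symmetric threshold
  containing 95% of test-retest variability.
* **LOA** (95% limits of agreement): $[B - \mathrm{RC},\ B + \mathrm{RC}]$
  where $B = \bar d$ is the mean relative difference (non-zero under a
  systematic intertracer shift).
* **ICC(A,1)**: intraclass correlation from a two-way mixed-effects model
  with absolute agreement on single measurements,
  $$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + MS_E + \tfrac{2}{n}(MS_C - MS_E)},$$
  with the exact F-based 95% confidence interval (McGraw-Wong, with the
  Satterthwaite denominator degrees of freedom). Absolute agreement
  penalises systematic offsets; the consistency-type coefficient
  $(MS_R - MS_E)/(MS_R + MS_E)$ is available for contrast.
* **Reliability class** (Koo-Li), applied to the **lower bound** of the ICC
  confidence interval: $\ge 0.9$ excellent, $[0.75, 0.9)$ good,
  $[0.5, 0.75)$ moderate, $< 0.5$ poor.

Two identities are constructional and asserted on every record:
$\mathrm{RC} = 2.7719\,\mathrm{wCV}$ and LOA width $= 2\,\mathrm{RC}$.

### Choices where the literature is ambiguous

* **Denominator of the relative difference.** The methodology chain the
  analysis follows does not restate the formula; the package defaults to
  the pair-mean denominator and exposes `denominator = "test_value"` as a
  config switch. This is the single most consequential formula choice: with
  a pure multiplicative shift $1+\beta$ and pair-mean denominator,
  $B = 200\beta/(2+\beta)$ (18.2 points at $\beta = 0.2$), not
  $100\beta$.
* **Sign convention**: $d$ is retest minus test; scan order is preserved in
  the feature table.
* **Pooling**: lesions are pooled across subjects with no within-patient
  correlation correction, matching the lesion-level published analysis.
* **Degenerate ICC**: zero between-subject variance yields a flagged `NA`,
  never a silent 0; perfect agreement on non-constant data yields ICC 1
  with interval [1, 1].
* **Wilcoxon for filter effects**: exact null distribution for $\le 25$
  untied non-zero differences, otherwise a normal approximation with tie
  correction and Pratt handling of zeros (zeros ranked, then discarded);
  Bonferroni over the 16 filters. Each filter's 93-feature ICC vector is
  compared against the original image's, the reading supported by how the
  filter analysis is framed.

## Image processing chain

* **SUV conversion**: SUV$_{bw}$ = concentration (kBq/mL) x body weight (g)
  / injected activity (kBq); decay correction is assumed upstream.
* **Segmentation support**: global threshold at SUV $\ge$ 3 (inclusive —
  the clinical description does not state strictness, and inclusive matches
  common tooling), 26-connected components, exclusion of candidates
  $< 1.5\ \mathrm{cm}^3$ (voxel count x voxel volume), with exclusions
  logged. Lesions present on only one scan are excluded and reported by the
  matcher (`by_id` for shared delineations, mutual-nearest-centroid within
  a distance cap otherwise; equidistant candidates are an error naming the
  lesions).
* **Conventional metrics** (SUVmax, SUVmean, SUVtotal = SUVmean x volume,
  volume) are computed on the **original** grid, avoiding resampling error.
* **Radiomics** are computed on a **2 mm isotropic** grid: images via cubic
  B-spline interpolation (with the exact interpolation prefilter,
  mirror-symmetric boundaries; an aligned identity resample is exact and
  linear ramps are reproduced away from borders), masks via nearest
  neighbour (strictly binary). Output grids share the input origin with a
  corner-anchored half-open voxel convention, axis order x, y, z.

## The feature catalogue

107 features from the unfiltered image: 14 shape, 18 first-order, 24 GLCM,
14 GLDM, 16 GLRLM, 16 GLSZM, 5 NGTDM. The catalogue and counts follow the
established open-source radiomics tooling whose definitions closely align
with the IBSI reference, including that tooling's documented divergences —
kurtosis is reported without the $-3$ offset, first-order energy is the
plain sum of squares with total energy scaled by voxel volume — because the
107/1488 structure comes from that catalogue. Divergences and degenerate
values are pinned by unit tests.

* **Discretisation**: fixed bin width (default 0.2 SUV) with edges anchored
  at multiples of the bin width — absolute SUV bins, not region-relative,
  appropriate for a calibrated scale. Levels are contiguous from 1;
  shifting a region by an exact bin multiple leaves the level map
  unchanged.
* **Texture aggregation**: all five matrix families use the 3-D
  26-neighbourhood at distance 1 and are **direction-merged** (counts
  accumulated over the 13 unique directions before feature computation, the
  IBSI "merged" strategy). Merging makes direction-dependent features
  exactly invariant under 90-degree rotations, which is tested. GLDM uses
  $\alpha = 0$ with dependence defined as 1 + the number of agreeing
  neighbours.
* **Degenerate regions**: uniform regions return 0 for contrast-like
  features and 1 for uniformity/correlation-like features (e.g. GLCM
  correlation, MCC); NGTDM coarseness, an inverse-contrast quantity for
  which neither convention is meaningful, is capped at the reference value
  $10^6$. Single-voxel regions produce defined matrices (an empty GLCM, 13
  unit runs, dependence 1, an empty NGTDM neighbourhood). Every choice is
  unit-tested.
* **Shape** is computed once per lesion on the unfiltered mask geometry and
  is bitwise identical across filters. The surface mesh is built by
  marching tetrahedra on the 0.5 iso-surface of the mask indicator after a
  separable (1/4, 1/2, 1/4) smoothing, with linearly interpolated edge
  crossings; this relaxes the binary staircase towards the underlying
  smooth boundary, so mesh volume and surface area of digitised ellipsoids
  converge to the analytic values and the sphericity of a digital ball
  approaches 1 from below (raw-binary meshing overestimates a ball's area
  by roughly a quarter and is used only as a fallback for masks too small
  to survive smoothing). Axis lengths derive from PCA of the physical
  voxel-centre coordinates.

## The 16-filter bank

Exactly 16 filters: exponential, logarithm, square, square root; Laplacian
of Gaussian at $\sigma$ = 2, 3, 4, 5 mm; and the 8 subbands of a one-level
undecimated separable 3-D wavelet transform. Each filter contributes the 93
intensity-based features (shape excluded), hence 1488 additional features.

* **Intensity transforms** are monotone and normalised so the output
  maximum magnitude equals the input's (with $m = \max |x|$): square
  $(x/\sqrt m)^2$, square root $\mathrm{sign}(x)\sqrt{m|x|}$, logarithm
  $\mathrm{sign}(x)\, m \log(|x|+1)/\log(m+1)$, exponential
  $e^{x \log m / m}$. The constants are documented here and in the code and
  pinned by regression tests on fixtures.
* **LoG** operates in physical units: Gaussian smoothing with $\sigma$ in
  mm (per-axis voxel widths) followed by a finite-difference Laplacian
  scaled by the squared spacings. A $\sigma$ below the voxel spacing warns
  but still computes. The centre response to a Gaussian blob matches the
  closed form $-3a^3/(a^2+\sigma^2)^{5/2}$ within 2% in tests.
* **Wavelets** use Coiflet-1 decomposition filters scaled by $1/\sqrt 2$
  per axis (so the LLL subband preserves constants and detail subbands of a
  constant image are exactly zero), replicate boundary extension, subband
  letters selecting low/high pass along x, y, z in that order. The basis is
  a default; no basis is prescribed by the clinical analysis description.

## The synthetic paired phantom

`generate_subject()` emulates the *structure* of a clinical whole-body
acquisition: a 4.07 x 4.07 x 2 mm grid, uniform background (default SUV 1),
non-overlapping ellipsoidal lesions (semi-axes drawn from 8-16 mm, mean SUV
5-12 — above the segmentation threshold and the 1.5 cm^3 exclusion by
construction, validated at config time), an isotropic Gaussian point-spread
function of 6 mm FWHM (the standard reading of a post-reconstruction filter
width), and additive Gaussian noise (default SD 0.1 SUV) clamped at zero.
Intra-lesion heterogeneity is a log-normal texture field — an exponentiated
Gaussian random field with Gaussian-kernel correlation (default length 8 mm,
log-SD 0.3) — keeping uptake positive. Masks are the pre-blur ellipsoid
supports. Lesion placement rejection-samples centroids with a cap of 1000
attempts, then errors. Everything is deterministic given the seed.

`generate_retest()` re-renders the same subject with each lesion's uptake
multiplied by $(1 + \mathrm{bias}/100)$ times a unit-mean log-normal factor
whose CV is $\sqrt 2\, w/100$, so the theoretical wCV of paired relative
differences equals the injected $w$. Noise is redrawn or reused per config.
The magnitudes of lesion noise and heterogeneity are not published for real
lesions; the defaults were chosen once for testability and plausibility,
not fitted to data.

What the phantom does **not** emulate — and hence what passing tests do not
show about real data:

* no reconstruction physics (sinograms, iterative updates, scatter/randoms);
  resolution is a single stationary Gaussian;
* no respiratory motion, no CT, no uptake-time or activity variation;
* a *shared* delineation is applied to both registered scans, so the volume
  biomarker is identical between test and retest by construction (its wCV
  is 0 in phantom runs); the clinical analysis had independent per-scan
  delineations whose variability dominates volume repeatability;
* within-subject error is a single multiplicative factor per lesion (the
  lesion-level unit of analysis), not voxel-wise.

### Calibration experiments and the spill-in effect

The recovery experiments (injected wCV in {2, 10, 25}% at 200 lesion pairs,
and the +20% bias shift) use **zero-background** phantoms. With a warm
background, PSF spill-in makes the measured SUVmean
$c_{bg} + f \cdot c_{lesion}$, attenuating the recovered wCV by roughly the
background's share of the in-mask signal (about 10% under the default
contrast) — a partial-volume-like property of the measurement, not of the
estimator. Removing the background makes the measurement proportional to
lesion uptake and isolates the estimator property being calibrated; the
attenuation mechanism itself is a known limitation of warm-background
phantom measurements (and of clinical SUV metrics). At these settings the
estimator recovers the injected wCV within a few percent (sampling SD at
$n = 200$ is about $w/20$), the ICC decreases monotonically in the injected
wCV, and a 20% bias shifts $B$ by $200\cdot 0.2/2.2 = 18.2$ points while
degrading ICC(A,1) but not the consistency-type ICC.

## Problem sizes and numerical tolerances

Test and calibration runs use deliberately small problems: 32 x 32 x 24 to
48 x 48 x 32 phantom grids, cohorts of 3-5 subjects for end-to-end runs, 200
lesion pairs for estimator recovery, 50 random lesions of at most 100
voxels for the brute-force texture-matrix oracles (tolerance 1e-9), 100
random datasets for the ICC ANOVA oracle (tolerance 1e-10). Texture
matrices are integer count matrices, so oracle agreement is exact up to
floating-point bookkeeping. The B-spline prefilter uses the exact
mirror-boundary initialisation (pole $\sqrt 3 - 2$); boundary effects on
interpolated values decay geometrically with that pole, which is why "away
from borders" in the ramp-reproduction test means a dozen samples.

## Known limitations

* Radiomics feature values are validated structurally (counts, identities,
  invariances, brute-force matrix oracles, closed-form filter responses)
  and against hand-computed cases, not against an external radiomics binary
  at run time; numerical conventions documented above (aggregation
  strategy, bin anchoring, degenerate values) must be matched when
  comparing with other tools.
* The ICC confidence interval is the exact F-based two-sided 95% interval;
  no small-sample correction beyond it.
* Lesions are pooled across subjects; clustered data would need a
  correction the published analysis also did not apply.
* The phantom's realism caveats above.
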