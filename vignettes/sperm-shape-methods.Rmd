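---
title: "Methods: Fourier harmonic shape analysis of sperm nuclei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Fourier harmonic shape analysis of sperm nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermshape)
```

## The problem

Ram fertility varies widely between males that all pass a conventional
semen examination. One candidate predictor is the shape of the sperm
nucleus: subtle differences in head elongation and tapering track
chromatin organization and have been associated with field fertility in
several species. `spermshape` implements the complete computational
pipeline for testing that association: fluorescence nuclei are segmented,
their outlines are converted to rotation-invariant Fourier harmonic
amplitudes (FHA) and ImageJ-style morphometrics, per-animal summaries are
assembled, and a two-group linear discriminant model with stepwise
variable selection and leave-one-out cross-validation classifies males
into adequate-fertility (AF) and low-fertility (LF) groups.

Because the original image data are not public, the package includes a
first-class synthetic generator that emulates the study design — 47 AF
and 9 LF rams, 100 nuclei per ram, group-level amplitude and intensity
statistics matching the published per-group summaries — so that every
stage can be tested against known ground truth.

## The shape model

A nuclear outline is represented by its polar radius profile about the
center of mass,

$$ r(\theta) = c_0 + \sum_{k=1}^{K} a_k \cos k\theta + b_k \sin k\theta,
\qquad K = 5, $$

and described by the harmonic amplitudes $HA_0 = c_0$ (mean radius, μm)
and $HA_k = \sqrt{a_k^2 + b_k^2}$. Amplitudes are rotation-invariant
because rotation only moves phase between $a_k$ and $b_k$. $HA_2$
captures elongation, $HA_1$ anterior asymmetry, $HA_3$–$HA_5$ posterior
tapering. Multiplying all coordinates by $s$ multiplies every amplitude
by $s$ exactly.

Fitting is ordinary least squares of the resampled radii on the
trigonometric basis (`fit_fourier()`). The outline is resampled at
`M = 128` equally spaced angles by exact ray–polygon intersection
(`to_polar()`); with equal-angle sampling the least-squares solution
coincides with the discrete Fourier transform, which the tests verify to
`1e-9`. `M = 128` is far above the minimum `2K + 1 = 11`, so aliasing of
smooth head outlines is negligible.

### Why the generator anchors outlines at their center of mass

The measurement frame is the area centroid (the average-shape figure's
axes intersect at the center of mass). For a truncated series the first
harmonic mostly encodes displacement of the pole: to first order the
centroid of $r(\theta) = c_0 + a_1\cos\theta + \dots$ sits at $(a_1,
b_1)$. Consequently a $K \le 5$ outline measured about its own centroid
cannot carry an arbitrary $HA_1$; anchoring slaves $(a_1, b_1)$ to the
other coefficients (roughly $(a_2 a_3 + a_3 a_4 + a_4 a_5)/c_0 \approx$
0.01–0.03 μm for realistic heads). `draw_nucleus()` therefore draws
$HA_0$ and $HA_2$–$HA_5$ freely and solves $(a_1, b_1)$ so the centroid
coincides with the pole, using a finite-difference Newton iteration on an
exact spectral centroid ($r^2$ and $r^3$ are trigonometric polynomials,
so their equal-angle sums are exact). Ground truth stored for each
nucleus is exactly recoverable by the measurement chain (< 1e-6 μm with
densely sampled outlines), which is the property that makes end-to-end
pipeline validation meaningful. The published first-harmonic mean
(0.085 μm) is not reproducible as a free parameter inside this family;
real outlines have energy above $K = 5$ that the truncated family cannot
represent.

## The synthetic cohort

Defaults are the study conditions:

* **Design**: 47 AF + 9 LF rams, 100 sperm per ram.
* **Group amplitude means** (μm): the published per-group values
  (AF $HA_2$ 0.905, LF 0.872; $HA_0$ 2.851/2.838; …).
* **Between-ram spread**: group SEM × $\sqrt{n_\text{rams}}$, so the
  printed group SEMs are reproduced at the ram level. For $HA_2$ this
  gives 0.041 (AF) and 0.072 (LF) μm; the resulting group comparison
  reproduces the published "trend" ($t \approx 1.9$, $p \approx 0.06$).
* **Within-ram spread**: overall-cohort SEM × $\sqrt{100}$, a common
  sperm-to-sperm process for both groups. Using per-group SEMs here
  instead would give LF rams ~16× the AF within-ram variance — an
  artifact of the SEMs differing mostly through group size (9 vs 47) —
  and would make the cohort separable through dispersion features rather
  than mean $HA_2$.
* **Conception rates** (percent): AF 95.1 (SEM 0.6, n = 41), LF 79.7
  (SEM 2.5, n = 27), drawn with SEM × $\sqrt{n}$ spread and clamped to
  [0, 100].
* **Intensity** (8-bit gray levels): per-ram means around 99.2 (AF) and
  110.7 (LF); within-nucleus pixel SD around 17.8/20.5 with between-ram
  spread from the printed SEMs. The injected chromatin texture SD is
  0.68 × the published within-nucleus SD: the published value is a
  *measured* SD that already includes the PSF-dimmed edge band and
  shot/read noise, and the 0.68 factor was calibrated once so rendered
  nuclei measure at the published scale (17.9 measured vs 17.754 at AF
  defaults).
* **Canonical phases**: tapering harmonics in phase with the elongation
  axis, which keeps heads convex (outline solidity ≈ 0.9996, as for real
  paddle-shaped ram heads); phase jitter SD 0.15 rad; uniform random
  rotation per nucleus.

Rendering (`render_nucleus()`, `generate_field()`): pixel-center
rasterization of the outline interior, Gaussian PSF with σ = 0.15 μm
(typical widefield), Poisson shot noise, Gaussian read noise (SD 2 gray
levels), 8-bit quantization (the published intensities, ~99–111 gray
levels, sit on an 8-bit-like scale; bit depth is configurable). The
default pixel size is 0.11 μm/px (≈ 40× objective with a 1.25×
magnifier); no μm-per-pixel calibration is published for this workflow,
so the default is an assumption, not a reported value. Fields place nuclei without mask
overlap except for a requested overlap fraction used to exercise
quality-control rejection; the phase-contrast-like companion image is a
contrast-inverted, halo-blurred rendering.

What the generator does *not* emulate: optical aberrations,
photobleaching, debris and non-sperm objects, true chromatin
substructure, tails/midpieces, and above-$K$ shape detail. Passing tests
therefore demonstrate correctness of the measurement chain, not
performance on real slides.

## Segmentation

`log_threshold()` implements Laplacian-of-Gaussian thresholding: the
image is smoothed (σ = 0.3 μm, about the edge scale), the negated
Laplacian response is thresholded (Otsu by default; the response is
insensitive to constant offsets), small gaps in the edge-response
annulus are closed, holes filled, specks removed, and the mask is grown
to the response zero-crossing — which marks the blurred edge position —
then smoothed morphologically. The original macro is unpublished, so all
segmentation constants here are the package's own, validated against
synthetic truth (single-nucleus IoU ≈ 0.97).

`extract_objects()` labels 8-connected components and rejects objects
touching the border, outside a 10–80 μm² area gate (around the ~28 μm²
nominal nucleus), or with the fused-pair signature — solidity < 0.92
*and* area > 1.6 × the cohort median (both conditions required; with no
usable median, low solidity alone decides). Requiring both avoids
rejecting genuine nuclei whose noisy masks dip slightly below the
solidity cutoff while still catching fused pairs (two touching disks
have solidity $2\pi/(\pi + 4) \approx 0.88$).

`trace_perimeter()` follows the outer boundary with Moore-neighbour
tracing (Jacob's stopping criterion), yielding a closed counterclockwise
polygon of pixel centers in μm with y up. Chain-code step parities are
kept: the perimeter estimate is 1/√2-weighted by default, or
Vossepoel–Smeulders weighted (0.980 axial, 1.406 diagonal) with
`corner_correction = TRUE`, which removes the ~5% staircase overestimate
on smooth outlines while remaining near-exact on axis-aligned edges. (A
single global 0.948 factor would shrink a square's perimeter by 5%, so
per-step weights are used instead.)

Boundary-pixel centers sit on average ~0.46 px inside the region they
delimit; left uncorrected this biases the mean radius by ~0.05 μm at the
default pixel size. The segmentation workflow therefore applies a
half-pixel outward radial pad to traces (`radial_pad_px = 0.5` in
`segment_field()`), a pixel-support convention measured on rasterized
disks. With it, end-to-end recovery of $HA_0$ and $HA_2$ through
render → segment → fit has mean absolute error ≈ 0.014–0.018 μm at
0.11 μm/px — the residual being mostly the curvature-dependent offset of
the LoG zero-crossing, which scales with σ²κ.

## Morphometrics

`measure_nucleus()` follows the ImageJ definitions: area = pixel count ×
pixel size²; the fitted ellipse comes from central second-order moments
of member pixels (+1/12 px² pixel-support term), with semi-axes
$2\sqrt{\lambda}$; aspect ratio = major/minor; roundness = $4A/(\pi\,
\text{major}^2)$; solidity = outline area / convex-hull area; intensity
mean, SD, median, population skewness and excess kurtosis over member
pixels. Perimeter and circularity ($4\pi A/P^2$, clamped at 1) are
evaluated on the equal-angle resampled outline with a width-3 circular
moving average: the raw staircase makes a digital disk's circularity
0.88–0.94 under any single chain weighting, whereas the smoothed outline
measures a disk at ≈ 1 and a square at ≈ π/4, matching the continuous
definitions the features are named for.

## Per-animal summaries and the average shape

`summarize_ram()` reports, per animal, the mean, unbiased variance,
adjusted Fisher–Pearson skewness, and bias-corrected excess kurtosis of
each amplitude (the SAS conventions), joined with mean morphometrics —
the candidate pool for classification (6 amplitudes × 4 statistics + 11
morphometric means = 35 variables). Zero-variance amplitudes report
skewness/kurtosis 0 with a degenerate flag.

`average_shape()` aligns each outline (centroid at origin, moment-ellipse
major axis horizontal, the boundary-heavier end toward +x, optional
reflection making the signed third moment along the minor axis
nonnegative — near-circular outlines warn that orientation is arbitrary),
resamples at common angles and averages radii, giving the cohort mean
outline with per-angle SD.

## Fertility grouping and classification

`threshold_groups()` labels animals LF when their conception rate falls
below mean − 1 SD of the population, using the population SD (divisor
n), which reproduces the published arithmetic 89.0 − 6.6 = 82.4; a ram
exactly at the cutoff is AF. `group_ttest()` wraps the pooled-variance
Student's t-test (Welch by flag).

`stepwise_select()` is stepwise discriminant selection in the SAS
STEPDISC style: at each round the candidate with the largest partial
Wilks'-lambda F joins if its p-value is below `entry_p` (default 0.15),
then included variables whose F-to-remove p exceeds `stay_p` are
dropped. Near-collinear candidates (R² > 1 − 1e-4 on the selected set)
are skipped, and entry stops when residual df (n − 2 − p) would fall
below 5, a numerical guard that keeps every leave-one-out fold's pooled
covariance nonsingular. Note a property inherent to the procedure: with
~35 candidates, the round's best p-value on pure noise is the minimum of
~35 uniforms (≈ 0.03), far below the 0.15 entry level, so greedy
selection admits several noise variables by design; the entry level
governs admission but does not control family-wise error.

`fit_lda()` fits the two-group linear discriminant: pooled within-group
covariance (solved on the correlation scale, since features mix μm²
variances with gray levels across ~12 orders of magnitude), per-group
linear classification functions with priors (equal by default,
proportional available), the Fisher direction, and the canonical
correlation $\sqrt{1 - \Lambda}$ with its Wilks'-lambda F-test.
Posterior ties classify as AF (the majority class).
`loo_crossvalidate()` refits on each leave-one-out fold and reports the
confusion counts, sensitivity (AF correct), specificity (LF correct) and
overall error, raw and as integer percent.

On default synthetic cohorts the pipeline's LOO error (~11%) clearly
beats permuted-label baselines (~36% with equal priors; ~16%, the
majority-class rate, with proportional priors). Mean $HA_2$ itself
enters the stepwise model in only a minority of seeds: its group signal
is the published $p \approx 0.06$ trend, which rarely wins a greedy
best-of-35 race — mirroring the original analysis, whose stepwise model
contained roundness, circularity, intensity SD and dispersion terms,
with mean $HA_2$ included only in a manually specified final model.
`run_pipeline()` accepts a fixed `features` list for exactly that kind
of manual specification.

## Numerical choices and degenerate inputs

* Polar resampling uses exact ray–segment intersection; non-star
  outlines (a centroid ray crossing more than once) take the farthest
  intersection and are flagged; a centroid outside the outline is an
  error. The point-in-polygon parity test jitters the query point to
  avoid ties when rays pass exactly through vertices of symmetric
  outlines.
* `fit_fourier()` requires M ≥ 2K + 1 and errors on rank-deficient
  designs.
* Boundaries with fewer than 8 pixels raise an interrupted-perimeter
  error; traces store first vertex = last vertex.
* All generators are pure functions of their seed (`rng_seed`); the
  caller's RNG state is saved and restored.
* Problem sizes in the test suite are scaled down (e.g. 8 rams × 20
  sperm for pipeline recovery, 20 seeds × 25 sperm for selection
  behaviour) — chosen as the smallest sizes at which each property is
  stable; the acceptance script runs the full 47 + 9 × 100 design.

## Known limitations

* Image-based validation is against the package's own synthetic
  renderer; segmentation constants are untested on real micrographs.
* The K ≤ 5 outline family constrains the first harmonic (see above), so
  anterior asymmetry is under-represented relative to real heads.
* Greedy stepwise selection overfits by construction at `entry_p =
  0.15`; cross-validated error, not the selected variable list, is the
  meaningful output.
* The published per-ram measurements are not available, so fitted
  coefficients and the published canonical correlation cannot be
  reproduced, only the procedure and its printed classification
  arithmetic.
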