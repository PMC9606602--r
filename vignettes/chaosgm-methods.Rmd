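---
title: "Chaos analysis of gray-matter topology: models and choices"
author: "chaosgm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaos analysis of gray-matter topology: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement

`chaosgm` quantifies the geometric complexity of a gray-matter (GM)
segmentation by treating the image as a *spatial series* and analysing it
with tools from nonlinear dynamics.

1. **Weighted distances.** For a modulated, spatially normalised GM volume,
   the intensity-weighted centre of mass is computed, and each voxel is
   assigned the product of its Euclidean distance (in mm, through the image
   affine) from that centre and its GM intensity. A voxel of intensity 1 at
   3 mm and a voxel of intensity 3 at 1 mm are equivalent under this
   measure; the highest values belong to voxels that are either far out on
   the cortical surface or unusually dense.
2. **The spatial series.** The top `K` weighted distances (default
   `K = 5000`, roughly 1% of nonzero GM voxels at full resolution) are
   sorted in decreasing order. The resulting sequence \(x_1 \ge x_2 \ge
   \dots \ge x_K\), with the originating voxel of every rank retained, is
   treated like a time series whose "time" axis is rank.
3. **Largest Lyapunov exponent (lambda).** The series is delay-embedded
   (Takens reconstruction) into \(X_k = (x_k, x_{k+\tau}, \dots,
   x_{k+(m-1)\tau})\), and the Rosenstein nearest-neighbour procedure
   estimates the average exponential divergence rate of nearby state-space
   trajectories: each reference point is paired with its nearest neighbour
   outside a Theiler window, the mean log-distance \(\langle \ln d(s)
   \rangle\) is tracked over steps \(s\), and lambda is the least-squares
   slope of its linear region. Per-point lambda values are mapped back to
   the selected voxels, giving a 3D lambda map that is smoothed with an
   8 mm FWHM Gaussian kernel for group analysis.
4. **Scalograms.** The per-point lambda series is decomposed with a
   continuous wavelet transform (complex Morlet mother wavelet), giving a
   points-by-scales matrix of signed correlations — a scalogram — per
   subject.
5. **Group inference.** Smoothed lambda maps are compared voxel-wise with a
   covariate-adjusted linear model; family-wise error is controlled by a
   permutation maxT scheme with Freedman–Lane covariate handling, with
   clusters formed at an uncorrected threshold (default p < 0.001) and an
   extent filter (default 10 voxels, 26-connectivity). Scalograms are
   compared cell-wise with two-sample t-tests under Benjamini–Hochberg FDR
   over the whole point-by-scale grid.

## Embedding parameters

The embedding dimension and delay are method parameters with no single
correct value; the Rosenstein estimator is known to be robust to moderate
changes in both. Defaults: `tau = 1`, `m = 5`, Theiler window
`tau * (m - 1)` (one embedding-window separation, preventing trivially
correlated neighbours), divergence horizon 50 steps, linear-region fit over
steps 1–20, and state-space sampling interval `tStep = 1` so lambda is in
units of inverse rank steps. `lambdaGrid()` reports the estimate across an
(m, tau) grid as a robustness diagnostic. For strongly chaotic benchmark
maps the divergence curve saturates early, and the fit range must sit inside
the linear region — the package's own benchmark uses steps 1–7 for the
logistic map at series length 5000, where saturation begins near step 10.

All voxel indices in the package are 1-based R indices; the NIfTI affine
(which addresses 0-based voxel offsets) is applied to `index - 1`, so world
coordinates agree exactly with the NIfTI convention.

## Localizing lambda

The divergence relation \(d(s) = d(0)e^{\lambda_1 s}\) defines a *global*
exponent via the slope of the mean log-divergence. To write one lambda per
selected voxel, a per-reference quantity is needed. Two rules are
implemented:

* **Per-reference slope (default).** \(\lambda_1(k)\) is the least-squares
  slope of the reference's own log-divergence \(\ln d_k(s)\) over the same
  fit range used globally. The global estimate fits the *mean* curve, so on
  curves that are linear in the fit range the mean of per-reference slopes
  equals the global slope — the local rule is the exact disaggregation of
  the global one.
* **One-step finite difference** (`lambdaLocal(method = "difference")`):
  \((\ln d_k(1) - \ln d_k(0))/T\), the minimal localization using only the
  first step.

The default was chosen after measuring both on synthetic cohorts: the
one-step difference uses two log-distances only and inherits the full
variance of nearest-neighbour micro-spacings, producing per-point values
that are essentially uncorrelated between subjects; the fit-range slope
averages ~20 steps and is the stabler spatial signal, while agreeing with
the global estimator by construction. Positions past the end of the embedded
trajectory, references with no admissible neighbour, and zero-distance pairs
(exact ties in the sorted series, excluded rather than jittered so no
randomness enters) are flagged missing; they are written as zeros in the 3D
map with a logged count.

## Wavelet choices

The Morlet centre frequency is \(\omega_0 = 6\), the standard admissible
choice. Scales default to integers 1–100; the cosine-of-period-P peak scale
follows the Fourier factor \(s^\ast = P(\omega_0 + \sqrt{2 +
\omega_0^2})/(4\pi)\). Coefficients store the real part — a signed
correlation with positive and negative matches — with the modulus available
via `waveletConfig(output = "modulus")`. Support is truncated at
\(|t/s| > 8\), where the Gaussian envelope is below 1e-14; the transform is
computed by FFT convolution on a shared padded length, which is exact to
rounding. Boundaries are zero-padded (consistent with imputing missing
lambda values as zero), and every cell within one truncated support radius
of either series end is flagged in a boundary mask. At scale 1 the unit
sampling grid itself limits how well discrete sums approximate continuum
integrals (Poisson-summation error ~\(2e^{-\pi^2 s^2}\)); from scale 2 up
only the truncation matters.

## Group statistics

The voxel-wise model is ordinary least squares on
`[intercept, group, covariates]`, reducing exactly to the pooled-variance
two-sample t-test when no covariates are given. Covariates are adjusted
jointly by passing several names at once, or separately by calling the
function per covariate. Random-field-theory FWE is *not* implemented;
instead `permutationFWE()` permutes residuals under the nuisance-only model
(Freedman–Lane) and uses the max-|t| null distribution, which is exact under
exchangeability and testable by enumeration (an `exact = TRUE` mode
enumerates all row permutations for n ≤ 8).

Smoothed lambda maps are zero wherever a subject's smoothing kernel reaches
no selected voxel, which makes edge voxels zero-inflated mixtures across
subjects and badly calibrates t-tests there. As in voxel-based morphometry
practice (implicit/absolute-threshold masking), `runGroup()` therefore
restricts the analysis to voxels with minimum smoothed selection coverage
above a small cutoff (`minCoverage = 0.001`) in *every* subject;
`glmContrast()` without a mask retains the plain nonzero-variance mask.

BH-FDR rejects a cell iff its adjusted p-value is ≤ q (the literal step-up
rule); over the full grid by default, per scale column with
`perScale = TRUE` — the field is genuinely split on which family is the
right correction unit for scalograms, so both are provided. Note that FDR
control still admits a ~q share of false cells anywhere on the grid: planted
scale bands are recovered as the *bulk* of the discoveries, not as a strict
superset-free set.

## The synthetic cohort generator

Clinical GM maps cannot ship with the package, so the generator emulates
them as corrugated shells: intensity
\(I(v) = \exp\{-(r_v - R(u_v))^2/2w^2\}\) with angular radius
\(R(u) = r_0(1 + a\,B(u))\), where \(B\) is a band-limited, unit-variance
angular field (a seeded mixture of low-order directional cosines, band
limit 6 by default) and \(a\) is the corrugation amplitude — the
surface-complexity handle that differs between synthetic groups
(default group effect: +0.1 amplitude). Because the method consumes
*spatially normalised* maps, anatomy is shared within a cohort:
\(B = \sqrt{1-w^2}B_{\text{tmpl}} + wB_{\text{subj}}\) with a cohort-level
template field and a subject fraction `subject_frac = 0.3`; subject fields,
intensity noise (truncated Gaussian, SD 0.02) and per-subject seeds derive
deterministically from the master seed. Defaults: 1.5 mm voxels, shell
radius 22% of the grid extent (leaving room for strong corrugation), shell
width 3 mm (about cortical thickness; pass 2 mm for grids below ~48³ so a
corrugated shell still fits). Variance of \(R\) over angle grows as
\((r_0a)^2\), so roughness is strictly monotone in the amplitude.

**What passing tests do and do not show.** The phantom reproduces the
pipeline's *mechanics* (selection, embedding, divergence, mapping,
transformation, inference) and the distributional consequences of a
complexity shift: the weighted-distance distribution widens reliably with
amplitude, and the null inference layers are calibrated. It does not
reproduce the rank-locked anatomical structure of real cohorts: because the
series is indexed by rank, inter-subject value perturbations larger than
the inter-rank spacing scramble which voxel occupies which rank, so
per-rank lambda values decorrelate between subjects even when anatomy is
70–98% shared. Detecting a group difference in scalogram *cells* at small n
therefore demands far larger samples than detecting it in the
weighted-distance series itself; results on real data, where the effect
sizes and coherence structure are unknown, cannot be inferred from phantom
power alone.

## Numerical choices

* Sorting ties are broken by ascending linearised (column-major) voxel
  index — the output is deterministic and storage-order invariant.
* Nearest-neighbour ties take the smaller index; the search is blockwise
  vectorised and matches the O(M²) definition exactly.
* Gaussian smoothing uses per-axis sigma
  `fwhm / (voxel_size * sqrt(8 log 2))` (FWHM in mm), kernels truncated at
  4 sigma and renormalised, zero-padded boundaries; the map total is
  preserved up to boundary loss.
* Negative intensities on input are clipped to zero with a logged count
  (segmentation outputs are nominally non-negative; ringing artefacts are
  small).
* All randomness (phantoms, covariates, permutations) flows from explicit
  integer seeds; identical configuration and seed reproduce manifests and
  arrays bit-for-bit. Manifests contain no timestamps.

## Problem sizes in the test-suite

The packaged tests exercise the full pipeline at reduced scale — 48³
phantom grids, K = 1000, 50 wavelet scales, cohorts of 8 + 8 across 50
(null) and 20 (planted-effect) seeds; brute-force oracles run on instances
of a few dozen points — sizes chosen so the whole suite completes in
minutes while every code path is covered. Production use on 121×145×121 GM
maps with K = 5000 and 100 scales uses the same code paths unchanged.

## Known limitations

* The sorted series makes the attractor interpretation unconventional; the
  package implements the measure as defined and leaves the interpretation
  to the analyst. An unsorted series can be explored by embedding
  `seriesValues()` in a custom order.
* Lambda is invariant to uniform scaling of the series, so it does not
  register pure widening of the weighted-distance distribution — only
  changes in its shape.
* Permutation inference assumes exchangeability of subjects under the
  null within the covariate model.
* Scalogram group power at small n is limited by the rank-locking issue
  discussed above.
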