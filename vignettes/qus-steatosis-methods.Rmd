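---
title: "Quantitative ultrasound assessment of liver steatosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ultrasound assessment of liver steatosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qusliver)
```

## The problem

Nonalcoholic fatty liver disease progresses through accumulating fat
vacuoles in hepatocytes.  Two acoustic consequences are measurable in
backscattered radiofrequency (RF) ultrasound: the backscatter coefficient
(BSC) rises as fat droplets change the spatial organisation of scatterers,
and the attenuation coefficient (AC) rises with fat load.  `qusliver`
implements a pipeline that estimates *relative* backscatter and attenuation
maps against a calibrated reference phantom, summarizes them into
per-subject features, and regresses histology-derived fat fraction on those
features, grading steatosis by the Brunt intervals (grade 0 below 5% fat
area, grade 1 from 5 to 33%, grade 2 above 33 to 66%, grade 3 above 66%).

Because the rat RF and histology data behind this kind of study are not
publicly deposited, the package ships a synthetic-data module that plays
the role of the acquisition hardware and the microscope: every downstream
stage is exercised against inputs with known ground truth.

## The spectral model

Block-wise power spectra of the tissue, `S_s(f, z)`, are divided by
reference-phantom spectra `S_r(f, z)` acquired with identical settings, so
that transducer, diffraction and system effects cancel; `T_m(f)`
compensates the phantom membrane's transmission.  With a power-law
backscatter model `b f^n` and frequency-proportional attenuation, the log
spectral ratio follows the linear model

    Y(f, z) = ln(Δb(z)) + Δn(z) · ln(f) − 4 f · Δa(z)

where `Δb = b_s / b_r` (dimensionless ratio), `Δn = n_s − n_r`, and
`Δa(z)` is the *cumulative* attenuation difference in Np/MHz, whose axial
derivative is the attenuation-slope difference `Δα` in Np cm⁻¹ MHz⁻¹.
Natural logarithms and frequency in MHz are used internally everywhere;
decibel views (`10·log10` for `Δb`, the 8.686 dB/Np factor for `Δα`) are
reporting conversions only, so the model stays exactly linear in the
parameters.  The relative backscatter coefficient at any frequency is
`ΔBSC(f) = Δb · f^Δn`, reported at 11 MHz.

Blocks are 20λ × 20λ (λ = 0.14 mm, the wavelength at 11 MHz for
c = 1540 m/s) with 80% overlap.  Sides are rounded to pixels and the step
is `floor(0.2 · side)` — overlap is rarely integral, and the floor keeps
blocks inside the frame.  Each block's spectrum is the average of its
lateral lines' Tukey(0.25)-windowed, zero-padded periodograms; there is no
axial sub-segmentation.  Analysis is restricted to 4–18 MHz, further
trimmed by `usable_bandwidth()` to the largest contiguous band within
20 dB of the spectral peak.

## Region-of-interest selection by envelope SNR

The envelope SNR — mean over population standard deviation of the
analytic-signal envelope — equals `sqrt(π / (4 − π)) ≈ 1.913` for fully
developed (Rayleigh) speckle and falls when vessels or other coherent
structure contaminate a block.  `select_roi()` scans all candidate
sub-windows of a fixed parenchyma region and keeps the one whose mean SNR
is closest to the Rayleigh value, breaking ties toward the smallest axial,
then lateral, origin.  Blocks with undefined SNR (constant envelope) are
excluded from the means rather than raising, so edge artifacts cannot kill
a run; if every window sits below the target a warning is emitted and the
closest window is still returned.  The sub-window defaults to half the
fixed region per axis, a choice we document because the source protocol
does not state its subsection size.

## The TV-regularized inversion

`fit_rpl_tv()` estimates, per frame, the three maps jointly by minimizing

    Σ_blocks Σ_f ( Y − [β + n·ln f − 4 f a] )²
      + μ_b TV(β) + μ_n TV(n) + μ_a TV(a),      β = ln Δb

with isotropic two-dimensional total variation on each map and the fixed
weights `μ_b = 1, μ_n = 10³, μ_a = 10³`.  Optimizing `β` rather than `Δb`
keeps the data term linear and makes positivity of `Δb` automatic.

The solver is a majorize–minimize (lagged diffusivity) iteration: the
smoothed TV terms `Σ sqrt(|∇x|² + ε²)` (ε = 10⁻³ on the natural-log map
scale) are majorized at the current iterate by weighted quadratics, and
each iteration solves one sparse symmetric positive-definite system in the
`3 N` stacked unknowns, in which the 3 × 3 per-block least-squares term
couples the maps and the weighted Laplacians couple neighbours within each
map.  The MM construction guarantees a monotonically non-increasing
objective — an invariant the test suite asserts.  Iterations stop when the
relative objective change falls below 10⁻⁶ or after 500 iterations,
whichever comes first; non-convergence is flagged, not raised.  With all
weights zero the first iteration solves the block-diagonal system exactly,
so the unregularized limit coincides with per-block ordinary least squares
(`per_block_ols()`), which doubles as the test oracle.  `Δα` is obtained
from `Δa` by forward finite differences over the axial block step with the
last row replicated, so all maps share the grid shape.

Two properties of this construction deserve emphasis.  First, the TV
weights are dimensionless and act relative to the scale of the data term,
which here is a sum over the frequency grid (30 points by default): a
different grid density rebalances regularization against data fidelity,
just as a different block count does.  Second, the cumulative attenuation
map of even a homogeneous attenuating medium is a *ramp*, whose total
variation is positive; at `μ_a = 10³` the fit therefore shades attenuation
slopes toward zero on small, weakly-informative grids.  On piecewise
targets with realistic noise this bias is far smaller than the variance it
removes — the regularized fit beats the OLS oracle on every map in the
recovery tests — but users reading `Δα` quantitatively on tiny grids
should compare against `per_block_ols()`.

## What the synthetic generators emulate

`simulate_spectra()` evaluates the model above exactly and adds i.i.d.
Gaussian noise to `Y` — the idealized regime in which the inversion's
statistical behaviour can be verified against analytic expectations.
`simulate_rf()` produces the regime upstream of that: a white Gaussian
scatterer field scaled by `sqrt(Δb)`, filtered per depth segment by a
Gaussian-modulated pulse (15 MHz center, 120 MHz sampling, i.e. 8× the
center frequency), a band-limited `f^(Δn/2)` backscatter filter and
two-way amplitude attenuation `exp(−2 ᾱ f z)`.  Its envelope statistics
are Rayleigh by construction, so the SNR machinery can be validated
end-to-end.  Neither simulator models diffraction, focusing, elevational
geometry or nonlinear propagation; passing tests demonstrate correctness
of the estimation chain under the stated model, not robustness to beam
physics absent from it.

`make_histology_image()` lays non-overlapping bright discs (vacuole radii
6–16 px) on a noisy stained background until the disc area reaches the
target fraction within ±0.5 percentage points, plus elongated bright
distractors (aspect ≥ 4) that emulate vessels, sinusoids and cracks and
are excluded from the returned truth mask.  Gray levels (background 120,
structures 235) straddle the segmentation threshold of 180 with margins
far exceeding the texture noise, mimicking well-stained, well-exposed
slides; stain variation and out-of-focus blur are not modeled.

`make_cohort()` generates per-subject feature tables for the study's
group sizes (24/15/16 subjects in grades 0/1/2).  Each subject draws a
fat fraction from its grade's normal distribution (means 1.28/20.36/45.23%,
sds 1.26/7.36/9.74%) truncated to the grade's Brunt interval; features are
then drawn around a piecewise-linear trend linking the grade anchor points
(grade fat-fraction mean, grade feature median), because acoustic
parameters of a continuously fat-infiltrating tissue vary continuously
with fat load rather than jumping between grade plateaus.  The per-grade
interquartile range of each feature is an *observed* spread, so the
generator decomposes it: the part explained by the trend carried across
the grade's fat-fraction spread is removed, and only the residual standard
deviation (floored at 30% of the total so no feature is ever noiseless) is
drawn as noise.  The marginal per-grade medians and IQRs therefore match
the requested table while the joint feature–fat-fraction distribution
carries the within-grade signal a regression can exploit.  The relative
BSC is generated lognormally (it is positive and spans orders of
magnitude); the backscatter frequency dependence `Δn` is generated
independently of grade, emulating sub-wavelength Rayleigh scattering whose
frequency dependence shows no steatosis trend.

## Histology quantification

`segment_fat_vacuoles()` follows a six-step recipe: luminance grayscale
conversion; global binarization at 180 (an Otsu option exists for images
whose exposure drifts); binary erosion then dilation with a radius-5 disc
(the classical non-flat ball element degenerates to its footprint on
binary data, so a flat disc is equivalent and is what we use);
8-connected component labeling; removal of components whose circularity
`4πA/P²` falls below 0.4 or whose axis aspect ratio exceeds 3 — a
deterministic stand-in for the expert's manual removal of vessels, bile
ducts and tissue cracks, which no reproducible pipeline can contain; and
the area-ratio fat fraction.  Per-subject fat fraction averages several
images (`subject_fat_fraction()`) to reduce sectioning sampling error.
Grades follow `brunt_grade()`, with 5 and 33 belonging to grade 1 and 66
to grade 2, matching the printed interval notation.

## The regression model

`fit_predict_loo()` predicts fat fraction from four features — median
`Δb` (dB), median `Δα`, median `ΔBSC` at 11 MHz and median envelope SNR
(each the across-frame mean of per-frame ROI medians; `Δn` is excluded
from the model because it carries no steatosis trend, but stays in the
summary table).  The learner is a Gaussian process with the exponential
kernel `k(x, x′) = σ_f² exp(−‖x − x′‖/ℓ)` over the standardized feature
space, one shared length scale, zero prior mean (no basis function) and
Gaussian observation noise; hyperparameters maximize the log marginal
likelihood with five-restart L-BFGS.  Under leave-one-out
cross-validation, standardization statistics — for the features and for
the response — are computed on each training fold only, so no information
about the held-out subject leaks into its own prediction; predictions are
transformed back and clamped at zero (a fat fraction cannot be negative).
Two preprocessing choices are the package's own and deserve a note: the
relative BSC enters through its logarithm, because a feature spanning two
orders of magnitude otherwise dominates every kernel distance through its
tail; and the response is z-scored fold-locally so that the zero-mean
prior is centered on the training level.  A shared-length-scale kernel was
retained after evaluating a per-feature (ARD) variant, which was noisier
on cohorts of this size without being systematically better.

Classification derives grades from the predicted fat fractions and scores
the binary task (grade 0 versus grades ≥ 1) and the multiclass task over
pooled held-out predictions; train-side accuracies averaged over the LOO
fold models are reported separately.  Group statistics use the
Kruskal-Wallis rank test with tie correction (significance declared below
0.01), and cohort tables report median (IQR) under the type-7
linear-interpolation quartile convention, with fat fraction as mean ± sd.

## Numerical choices and degenerate inputs

* TV smoothing ε = 10⁻³, stopping at relative objective change < 10⁻⁶ or
  500 iterations; the sparse systems are solved exactly each iteration.
* Cumulative attenuation integrates from zero at the transducer-proximal
  edge of the analysis grid by the midpoint rule, so a constant slope α
  yields exactly `α · depth` at each block center.
* Coordinates are 0-based half-open pixel intervals; the axial index
  grows with depth.  Block sides round to the nearest pixel, steps floor.
* Constant envelope blocks give `NA` SNR and are skipped in ROI search;
  ROI ties break toward the smallest origin; an all-subthreshold SNR map
  warns but still returns the argmin window.
* Rank-deficient spectral designs (fewer than three distinct frequencies)
  raise immediately; non-convergence of the TV solver is flagged on the
  result rather than raised.
* Every stochastic routine takes an explicit seed; the pipeline derives
  per-stage seeds deterministically from the global seed and stage name,
  and its artifacts are bitwise reproducible for a fixed configuration.

## Problem sizes used by the test-suite

The recovery and property tests run on deliberately small instances: TV
versus OLS comparisons use 16×16 to 20×20 block grids with 30-point
frequency grids over 10 noise realizations; envelope-SNR limits use one
to three million speckle samples; the end-to-end cohort study uses the
full 55-subject design with leave-one-out refits; the null calibration of
the Kruskal-Wallis test uses 2,000 replicates.  These sizes were chosen
so the whole suite completes in well under a minute per module while
keeping Monte-Carlo error far below every asserted tolerance.

## Known limitations

* The TV weights are tied to the data-term scale; transferring them to a
  much denser frequency grid or much larger ROIs shifts the
  regularization balance and should be revalidated.
* Heavy `μ_a` regularization shades attenuation ramps toward zero on
  small grids (see above); absolute `Δα` on few-row grids is better read
  from the OLS oracle.
* The RF simulator's speckle is fully developed by construction; the SNR
  map's ability to *reject* structured tissue is exercised only through
  synthetic structured inputs, not through physical heterogeneity.
* The synthetic cohort reproduces marginal grade summaries and a
  plausible feature–fat-fraction coupling, not the unknown joint
  distribution of real livers: regression metrics on it are property
  checks of the pipeline, not claims about in vivo performance.
* Grade-3 steatosis is absent from the emulated design (as it was from
  the source cohort); predictions above 66% rely on the regressor's
  extrapolation.
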