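# qusliver

Quantitative ultrasound (QUS) assessment of liver steatosis in R.

Fatty infiltration of the liver changes two acoustic properties that can
be measured from backscattered radiofrequency (RF) ultrasound: the
backscatter coefficient (BSC) and the attenuation coefficient (AC).
`qusliver` implements a pipeline for staging steatosis from these
measurements:

1. **Spectral processing** — block-wise power spectra (20λ × 20λ blocks,
   80% overlap, Tukey 0.25 window, 4–18 MHz band), envelope computation,
   envelope-SNR maps, and log spectral ratios against a reference phantom.
2. **Simultaneous coefficient estimation** — the relative power-law model

       Y(f, z) = ln Δb(z) + Δn(z)·ln f − 4 f·Δa(z)

   is inverted jointly for the relative backscatter amplitude `Δb`, the
   frequency-dependence difference `Δn` and the cumulative attenuation
   `Δa` (whose axial derivative is the attenuation-slope difference `Δα`,
   Np cm⁻¹ MHz⁻¹) with isotropic total-variation regularization
   (weights μ_b = 1, μ_n = 10³, μ_a = 10³), solved by monotone
   majorize–minimize iterations over sparse linear systems.  The relative
   BSC is `ΔBSC(f) = Δb·f^Δn`, reported at 11 MHz.
3. **Region-of-interest selection** — the analysis window is the
   sub-region whose mean envelope SNR is closest to the fully developed
   speckle (Rayleigh) value `sqrt(π/(4−π)) ≈ 1.913`.
4. **Histology ground truth** — fat-vacuole segmentation of H&E images
   (grayscale, threshold 180, radius-5 disc opening, 8-connected
   components, circularity/aspect shape filter) yields the fat-area
   fraction, graded by the Brunt intervals (<5%, 5–33%, >33–66%, >66%).
5. **Regression and grading** — a Gaussian process with exponential
   kernel, no basis function and fold-local standardization predicts fat
   fraction from the median `Δb` (dB), `Δα`, `ΔBSC` at 11 MHz and SNR
   under leave-one-out cross-validation, with negative predictions
   clamped to zero; predicted fractions are graded and scored, and
   Kruskal–Wallis tests summarize per-feature grade separation.

A synthetic-data module (`make_ground_truth`, `simulate_spectra`,
`simulate_rf`, `make_histology_image`, `make_cohort`) generates RF
volumes, block spectra, histology images and whole 55-subject cohorts
with known ground truth, so the entire pipeline is testable without any
proprietary data.

## Worked example

```r
library(qusliver)

# --- invert a noisy two-layer phantom ------------------------------------
truth <- make_ground_truth(c(12, 12), "piecewise",
                           levels = list(delta_b = c(1, 100),
                                         delta_alpha = c(0.1, 0.5)))
vol  <- simulate_spectra(truth, noise_sd = 0.5, seed = 1)
maps <- fit_rpl_tv(vol, solver_config())
median(10 * log10(maps$delta_b[7:12, , 1]))   # bottom half, true 20 dB
#> 19.17
median(maps$delta_alpha[7:12, , 1])           # bottom half, true 0.5
#> 0.36

# --- a full synthetic cohort study ---------------------------------------
coh <- make_cohort(cohort_spec(seed = 1))     # 24/15/16 subjects, grades 0-2
res <- fit_predict_loo(coh, config = gpr_config(), grades = coh$grade_true)
cls <- classify_from_predictions(res, coh$grade_true)
round(c(r2 = res$r_squared, rmse = res$rmse), 3)
#>    r2  rmse
#> 0.933 5.330
cls$confusion_multiclass
#>     predicted
#> true  0  1  2
#>    0 20  4  0
#>    1  0 13  2
#>    2  0  0 16

# --- histology quantification --------------------------------------------
him <- make_histology_image(histology_spec(target_fat_fraction_pct = 45,
                                           n_distractors = 4, seed = 9))
seg <- segment_fat_vacuoles(him$image)
c(fraction = seg$fat_fraction_pct, grade = brunt_grade(seg$fat_fraction_pct))
#> fraction    grade
#>    42.87        2
```

The inversion recovers the backscatter contrast of the lower layer to
within a decibel and separates the two attenuation levels; heavy
attenuation regularization biases slope ramps toward zero on small grids
(see the methods vignette), which is why the lower-layer `Δα` reads 0.36
rather than 0.50 here.  On the synthetic cohort the leave-one-out
regression explains 93% of the fat-fraction variance and grades 49 of 55
subjects correctly; the histology pipeline measures the 45%-fat image to
within about two percentage points and grades it correctly.

`run_qus_pipeline(pipeline_config("out"))` chains all stages (cohort →
imaging demo → histology → regression → summary) into CSV/JSON artifacts
with a reproducibility manifest.

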