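# nirquant

Deep-learning chemometrics for quantifying solid adulterants in coconut
milk from near-infrared (NIR) spectra.

## The problem

Coconut milk is routinely adulterated with cheap solid fillers — corn
flour and tapioca starch — to pad volume and apparent carbohydrate
content. Reference laboratory assays (oven drying, total-fat
determination) take hours per sample; NIR spectroscopy is fast and
non-destructive but needs a calibration model mapping a spectrum to the
adulteration level. `nirquant` implements such calibrations with
one-dimensional deep convolutional regressors and everything around them:
a spectral data model for two instrument classes (benchtop FT-NIR, 1102
wavenumbers over 12,500–4000 cm⁻¹; portable Micro-NIR, 125 wavelengths
over 908–1676 nm), a Gaussian-band mixture simulator reproducing the
15-level × 10-sample × 3-scan study design (450 spectra per
instrument–adulterant pair, 1800 in total), standard normal variate (SNV)
preprocessing, four 1D network architectures with their training
protocol, an evaluation suite, and a perturbation-based interpretation
method that flags the wavelengths driving each model.

The package is aimed at chemometricians and food-authentication
researchers who want a self-contained, dependency-light reference
implementation of this modeling pipeline in R: the network engine
(convolution, max-pooling, batch normalization, residual and inception
blocks, Adam, early stopping) is implemented in-package in double
precision on BLAS-backed matrix operations, so results are exactly
reproducible under a seed with no external deep-learning runtime.

## The method

Spectra are measured in absorbance (log 1/R). Each spectrum `x` is first
standardized per spectrum (SNV): `x ← (x − mean(x)) / sd(x)`, which
removes multiplicative scatter and baseline offsets exactly. A 70/30
train/test split (random state 42) and a 10% validation block carved from
the shuffled training rows (315 → 32) follow the study protocol. Four 1D
regressors are provided — a simple CNN, an AlexNet-style stack, a residual
network and an inception network — all trained with Adam on mean squared
error with early stopping and best-weights restoration, optionally over
11 independent repeats keeping the repeat with the lowest validation
loss.

Model quality is reported as

- `R² = 1 − Σ(Eᵢ−Pᵢ)²/Σ(Eᵢ−Ē)²`
- `RMSE = √(Σ(Eᵢ−Pᵢ)²/N)` (percent units)
- `Bias = Σ(Eᵢ−Pᵢ)/N`
- `RPD = 1/√(1−R²)`, banded as <3.0 poor, 3.1–4.9 fair, 5.0–6.4 good,
  6.5–8.0 very good, >8.1 excellent,

where `E` are the existing (reference) levels and `P` the predictions.

For interpretation, the trained network `f` is probed by forward finite
differences, one wavelength at a time:
`wⱼ = [f(x + ε·eⱼ) − f(x)]/ε` (default `ε = 1e-6`), averaged over all
training spectra to give a per-wavelength "regression coefficient"
profile `w̄`. Wavelengths with `w̄ⱼ ≥ 0.5·max(w̄)` or `w̄ⱼ ≤ 0.5·min(w̄)`
are reported as important, merged into contiguous ranges labeled in both
nm and cm⁻¹.

Because no public spectra exist for this design, the package ships a
simulator: pure components are sums of Gaussian bands at standard NIR
assignments (water OH combination at 1932 nm / 5176 cm⁻¹ and first
overtone at 1452 nm / 6889 cm⁻¹, fat CH overtones at 1728/1764 nm, starch
OH near 1540 nm, glucose region near 1400 nm, CH second overtone near
1212 nm), mixed as
`A = g·[(1−c)(1−γc)·A_milk + c·A_adulterant] + b₀ + ε(λ)` with
per-sample gain `g`, offset `b₀`, per-scan noise, and a moisture
attenuation `γ` that makes peak absorbance fall as the solid fraction
rises.

## Worked example

```r
library(nirquant)

ds  <- generate_design(design_spec(instrument = "Micro-NIR",
                                   adulterant = "corn_flour", seed = 42))
pp  <- snv_dataset(ds)
sp  <- split_train_test(pp, 0.70, 42)
cfg <- training_config("simple_cnn", max_epochs = 200, n_repeats = 1,
                       seed = 42)
fit <- train_regressor(pp$absorbance[sp$train_idx, ],
                       pp$level_percent[sp$train_idx], cfg)
evaluate_regressor(fit, pp, sp$test_idx)
#> <regression_metrics> n=135  R2=0.9998  RMSE=0.187%  Bias=0.008  RPD=68.741 (excellent)

prof <- mean_coefficients(fit, pp$absorbance[sp$train_idx, ], axis = pp$axis)
select_important(prof)
#> <important_features> 24 features beyond cutoffs (-0.3861, 1.668) at fraction 0.50
#>   10053-9991 cm-1 (995-1001 nm), 8699-8652 cm-1 (1150-1156 nm), ...
```

The metrics line reads: on the 135 held-out spectra the network explains
99.98% of the variance in adulteration level, errs by 0.19 percentage
points RMS with negligible signed bias, and its RPD of 68.7 sits far
inside the "excellent" band (> 8.1) — consistent with the strong,
low-noise signal the simulator provides. The selection output lists the
wavelength ranges whose averaged perturbation coefficient exceeds half
the profile's extreme peaks, i.e. the regions the network leans on.

The full pipeline (simulate → SNV → split → train → evaluate → interpret
→ report, with CSV tables and a JSON manifest) is one call:

```r
run_study(study_config(architectures = c("simple_cnn", "googlenet"),
                       quick = TRUE), outdir = "out")
```

A thin command-line wrapper lives at `inst/cli/nirquant.R`
(`Rscript nirquant.R run-all --arch simple_cnn --quick --outdir out`).

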