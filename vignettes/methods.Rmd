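---
title: "Models and methods in nirquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in nirquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nirquant)
```

`nirquant` quantifies solid adulterants (corn flour, tapioca starch) in
coconut milk from NIR spectra with one-dimensional deep regressors. This
vignette records the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open — in enough
detail that a maintainer can judge every default.

## Data model and study design

A spectrum is a vector of absorbance values (log 1/R) on a strictly
monotone axis in nm or cm⁻¹ (reciprocal units, ν[cm⁻¹] = 10⁷/λ[nm]).
Two canonical grids are built in: the benchtop FT-NIR grid with exactly
1102 evenly spaced wavenumbers over 4000–12,500 cm⁻¹, and the portable
Micro-NIR grid with exactly 125 evenly spaced wavelengths over 908–1676
nm. The nominal FT-NIR resolution of 8 cm⁻¹ does not arithmetically
yield 1102 points over that span; the feature count is the authoritative
quantity, so the grid is defined as 1102 evenly spaced points (spacing
8500/1101 ≈ 7.72 cm⁻¹). Likewise the Micro-NIR grid pins both endpoints
on-grid (spacing 768/124 ≈ 6.19 nm, consistent with the instrument's
6.2 nm nominal resolution).

The emulated study design is 15 adulteration levels (1–10, 15, 20, 30,
40, 50% w/w — stored as exact integers so targets are deterministic),
10 physical samples per level, 3 replicate scans per sample: 450 spectra
per instrument–adulterant dataset, 1800 across the four datasets. Splits
are a plain uniform random permutation under a seed (default 42), 70/30,
sized by `floor`: 450 → 315/135. The split is deliberately *not*
stratified by level, and a sample's three replicate scans may straddle
train and test; both follow the original protocol's plain "random
splitting", and the replicate-leakage implication is noted rather than
"fixed" — on real data this inflates test metrics slightly, and the same
caveat applies here.

Target summaries use the sample (n−1) standard deviation, the usual
chemometrics table convention.

## The synthetic-data generator

No spectra are publicly deposited for this design, so the simulator is a
first-class module rather than a test fixture. Pure components are sums
of Gaussian bands. Band *centers* follow standard NIR assignments: water
OH combination at 1932 nm (5176 cm⁻¹) and OH first overtone at 1452 nm
(6889 cm⁻¹) dominating coconut milk; fat CH first overtones at 1728 and
1764 nm; CH second overtone near 1210–1212 nm; starch OH near 1540 nm,
a glucose-related band near 1400 nm and a starch combination band near
2100 nm for the two flours. Band *widths* (σ 16–40 nm) and *amplitudes*
(water ≈ 1.0 AU, others 0.18–0.65 AU) are synthetic defaults — there is
no public reference to calibrate them against — chosen so the water
bands dominate the milk spectrum as observed in practice; they are
plain configuration and overridable.

A mixture at adulterant mass fraction *c* has noise-free expectation

```
A(λ) = (1 − c) · (1 − γc) · A_milk(λ) + c · A_adulterant(λ)
```

The attenuation γ (default 0.3) models moisture equilibration: free
water migrating from the milk into the dry filler lowers the water-band
absorbance faster than dilution alone, reproducing the observed
monotone decrease of peak absorbance with adulterant level. The
expectation is affine in *c* when γ = 0 and quadratic otherwise; both
facts are asserted in tests against the closed form.

Measurement effects: per-sample multiplicative gain U(0.9, 1.1) and
baseline offset U(−0.02, 0.02) shared across that sample's three scans,
plus i.i.d. per-point Gaussian scan noise (σ 0.003 AU). The gain/offset
sizes are chosen so SNV visibly matters (they are removed exactly by
SNV); the scan-noise σ is about 0.3% of the water-band amplitude, a
realistic signal-to-noise for averaged NIR scans. One master seed drives
everything; each (instrument, adulterant) dataset derives its own
31-multiplier string-hash stream seed, so any one dataset is
reproducible in isolation.

What the simulator does **not** emulate: temperature and humidity drift,
scattering physics (Kubelka–Munk), instrument line-shape differences,
batch-to-batch composition variation of real coconut milk, and
nonlinear detector effects. Passing tests on synthetic data therefore
demonstrate that the pipeline recovers a recoverable signal under the
stated noise model — not that the printed performance would transfer to
real spectra.

## Preprocessing

SNV standardizes each spectrum to mean 0 and sample SD 1 (n−1
denominator; the population form differs only by a constant factor that
scale-free downstream models absorb). SNV is per-row and fit-free, so it
is applied before splitting without leakage. Constant spectra are a
degenerate-input error, not silently zeroed.

## Architectures and training protocol

The exact layer parameterizations of the original networks are not
recoverable from text, so `nirquant` fixes canonical 1D adaptations that
preserve each architecture's defining mechanism at a size trainable on
315 spectra:

- **simple_cnn** — Conv(32,k7) → MaxPool2 → Conv(64,k5) → MaxPool2 →
  Flatten → Dense(64) → Dense(1);
- **s_alexnet** — Conv(48,k11,s4) / Conv(128,k5) / Conv(192,k3) /
  Conv(192,k3) / Conv(128,k3), max-pools after layers 1, 2, 5, then
  Dense(256) → Dense(128) → Dense(1);
- **resnet** — Conv(32,k7,s2) stem + four residual blocks (two k3
  convolutions with batch norm each, identity shortcut, 1×1 projection on
  channel change; 32, 32, 64, 64) + global average pool + Dense(1);
- **googlenet** — Conv(32,k7,s2) stem + max-pool + two inception modules
  (parallel k1/k3/k5/pool-k1 branches, splits 16-32-8-8 and 32-48-12-12)
  + global average pool + Dense(1).

ReLU throughout, single linear output, no target normalization (targets
are trained in raw percent). The engine is written in R on BLAS matrix
products (convolution via im2col) in double precision; backpropagation
is verified against central-difference numerical gradients to ~1e-8
relative error in the test suite.

Training: Adam (β₁ 0.9, β₂ 0.999, ε 1e-8) on MSE — the protocol reports
RMSE, which implies a squared-error loss. Hyperparameter defaults per
architecture: simple_cnn (batch 128, 1000 epochs, lr 5e-3, patience
200); s_alexnet (16, 300, 1e-5, 300); resnet and googlenet (160, 1000,
1e-5, 200); 10% validation everywhere. The validation block is the
*trailing* fraction of a single seeded shuffle, sized
`n − floor(0.9·n)`, which reproduces the protocol's 315 → 32 rounding.
"Total running time is 11 times" is read as 11 independent training
repetitions with fresh initialization, keeping the repeat with the
lowest best validation loss; the cumulative epoch counts reported
alongside published results (e.g. ~8000 for a 1000-epoch budget) support
this reading, and `epochs_run` mirrors it by accumulating across
repeats. Early stopping restores best weights. Weight initialization is
a uniform fan-in scheme keyed to the run seed; determinism holds for a
fixed seed on a fixed BLAS, but bit-exact cross-platform equality is not
promised.

## Evaluation statistics

R², RMSE and Bias follow their usual definitions, with Bias defined as
mean(existing − predicted) — so a positive bias means under-prediction.
RPD is computed as `1/√(1−R²)`. The equation as typeset in the source
literature ("RPD = 11 − R2") is ambiguous; the reciprocal-square-root
reading is adopted because it reproduces the published pairing of
R² = 0.886 with RPD 2.958 (the alternative reading `1/(1−R²)` gives
8.77). RPD is always computed from the *unrounded* R². The quality-band
boundaries are poor < 3.0, fair 3.1–4.9, good 5.0–6.4, very good
6.5–8.0, excellent > 8.1; the gaps between published ranges (e.g. an
RPD of 3.05) are assigned to the lower band, and the boundary table
lives in one function. Training-set metrics are computed over all
training rows including the validation block, matching how a single
"Training" column is conventionally reported; callers wanting
fit-rows-only metrics can pass those indices explicitly.

## Interpretation

Per-spectrum weights are forward finite differences
`w_j = [f(x + ε·e_j) − f(x)]/ε`, perturbing **one coordinate at a
time**. The source equation as typeset appears to perturb every
coordinate simultaneously, which would make all components equal; the
one-at-a-time form is the only reading consistent with per-wavelength
importance profiles and with the Cui & Fearn approach it adapts, so it
is implemented as a typo resolution. The per-spectrum vectors are
averaged element-wise over all training spectra (the index in the
averaging equation runs over spectra, not features). The intercept of
the locally-affine surrogate cancels in the difference and is never
estimated.

ε defaults to 1e-6. Because the engine evaluates in 64-bit precision
this is comfortably above numeric resolution (the linear-oracle test
recovers slopes to ≤ 1e-4 relative error); a network evaluated in
single precision would need ε ≥ ~1e-3, so the implementation emits a
precision warning whenever all finite differences are exactly zero
rather than silently returning a zero profile.

Important-feature selection uses *signed* cutoffs — 50% of the maximum
peak and 50% of the minimum peak separately, not 50% of |w̄| — matching
the "maximum and minimum peaks" phrasing. Selection is monotone in the
threshold fraction, and contiguous selected indices are merged into
ranges labeled in both nm and cm⁻¹. Published important-wavelength
lists depend on the original trained weights and real spectra; they are
format templates here, not reproduction targets.

## Pipeline, determinism and problem sizes

`run_study()` orchestrates simulate → SNV → split → train → evaluate →
interpret → report, persisting CSV tables (metrics with the standard
columns, predictions with recomputable scatter slope/intercept, training
history, coefficient profiles, merged important ranges, best-regressor
summary) and a JSON manifest with per-stage seeds, durations and file
checksums. Determinism classes: data generation and splitting are exact
under fixed seeds; training is stochastic-but-seeded; all reported
metrics are recomputable exactly from the persisted predictions. Best
regressors are chosen by test RPD with ties broken by lower test RMSE,
then architecture name.

Problem sizes used in the shipped tests and acceptance script are the
package's own desk-scale choices: unit tests train on 32–125-feature
inputs with tens of rows and capped epochs; the parameter-recovery check
trains the Simple CNN on the full 450-spectrum Micro-NIR design under
the protocol defaults with a single repeat, which converges in a few
minutes on one CPU. The architecture capacity check uses a learning
rate of 1e-3 for the three larger networks: their protocol rate of
1e-5 bounds each Adam update to ~1e-5 per parameter and cannot close a
±14-percent output gap in a desk-scale epoch budget (the cumulative
epoch counts reported for the original training — thousands across 11
repeats — indicate the same slow convergence), while capacity, the
property under test, is rate-independent. The `quick` profile of `study_config()` (epochs ≤
200, one repeat) exists for the same reason and is the default in
examples.

## Known limitations

- The four architectures are canonical adaptations, not reconstructions
  of the originals; published per-table metrics on real spectra are not
  reproducible and are used only as qualitative references.
- The simulator's band widths/amplitudes and noise sizes are synthetic
  defaults; conclusions about real coconut-milk matrices require real
  spectra.
- Replicate scans can straddle the train/test split (by design, matching
  the emulated protocol), which optimistically biases test metrics.
- The engine is CPU-only and single-threaded beyond BLAS; it is sized
  for hundreds of spectra and ~1000 features, not for large-scale
  hyperparameter searches.
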