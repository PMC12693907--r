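---
title: "Models and methods in ripecast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ripecast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ripecast` predicts tomato fruit quality on the plant from two cheap data
streams: a greenhouse sensor logger (temperature, relative humidity, solar
radiation) and RGB images of the fruit surface with a pixel-level fruit
mask. This vignette documents the models, their assumptions, the tunable
parameters, the synthetic data generator used throughout the tests, and
the design decisions taken where the problem was genuinely open.

## The pipeline

The system is a sequential coupling of three learned stages:

* an LSTM forecaster per environment variable (next-step prediction from a
  24-step, 3-channel window);
* a GRU encoder with query–key–value attention predicting the next-step
  red/yellow/green surface fractions from a 24-step, 6-channel window
  (environment plus lagged fractions);
* a feed-forward multi-task regressor from the normalized CIELAB a\*
  feature to six quality traits — FI (firmness, kg/cm²), SSC (soluble
  solids, °Brix), SS (soluble sugars, mg/g), TA (titratable acidity, %),
  VC (vitamin C, mg/g), LYC (lycopene, mg/g).

At inference the stages chain: the environment forecast rolls forward
recursively, drives the color model (whose own predictions are also fed
back), each predicted red fraction is converted to an a\* value through a
calibrated monotone proxy, and the quality network maps that scalar to the
six traits. `predict_integrated()` implements the chain;
`experiment_integrated()` runs it end to end on simulated plants.

## Sensor preprocessing

Quality control runs per variable over the full series, before any
splitting: values outside the Tukey fences `Q1 − 1.5·IQR` /
`Q3 + 1.5·IQR` become missing. Quartiles use the sorted-order
linear-interpolation convention (R's default type 7), which the test suite
pins against a brute-force oracle.

Gap filling distinguishes run length. Runs of at most five consecutive
missing points bracketed by observations are filled linearly between the
bracketing points, reproducing the endpoints exactly. Longer runs (and
edge runs with no bracket) are copied, hour for hour, from the nearest
prior day whose daily mean of the same variable lies within one standard
deviation (of all daily means) of the gap day's mean, ties resolved to the
most recent day. This "matched weather day" rule is deliberately
deterministic and seedless so refilling the same series always gives the
same answer. A series whose gap cannot be matched (for example, a fully
missing series) raises an `unfillable gap` error rather than guessing.

Scaling is per-variable min–max to [0, 1], fitted on the training portion
only; out-of-range values at transform time are *not* clipped, which keeps
the transform invertible (round-trip error below 1e−9 is asserted).

Splitting is plant-wise in a 7:2:1 ratio with largest-remainder rounding
(80 plants → 56/16/8). The plants whose records start latest form the test
set, and train/validation records at or after the earliest test record are
flagged for exclusion, so the test period strictly postdates every kept
training record. The remaining plants are shuffled under the caller's
seed.

Windowing is stride-1 with a one-step horizon: a series of length `n`
yields `S = n − T` windows of shape `T × X` (T = 24 by default, so a
window spans one day at the simulator's hourly step — the logging interval
is a package choice, exposed in `sim_scenario()`).

## Image color pipeline

White balance follows the gray-world assumption: channel gains
`s_c = a_gray / a_c` with `a_gray` the mean of the three channel means.
After scaling, channel means are exactly equal; the stored image is
clipped to [0, 255] and rounded half-to-even to stay 8-bit, so a second
pass changes means only at rounding magnitude.

The a\* feature uses the standard sRGB → XYZ path: inverse companding with
the 0.04045/12.92 threshold pair, the classic RGB→XYZ matrix, and the CIE
`f(t)` with cube-root branch above `δ³`, `δ = 6/29`. The reference white
is the matrix's own row sums (D65, 2° observer), which makes the gray axis
map to a\* = 0 exactly. Pure sRGB red gives a\* ≈ 80.1; the tests compare
a sample of colors against `grDevices::convertColor()` as an independent
oracle. The fruit-level feature is the arithmetic mean of per-pixel a\*
over the mask, normalized as `a_n = (a* + 128)/255`.

Surface color ratios are not derivable from a\* alone, so masked pixels
are classified by HSV hue: red `[0°, 25°) ∪ [330°, 360°)`, yellow
`[25°, 70°)`, green `[70°, 170°)`; pixels below saturation 0.15 or outside
the bands are left unclassified and redistributed proportionally. The hue
bands are a package decision (the classification rule is not otherwise
pinned down); they match common horticultural color ranges and are
exposed as arguments. Whether ratios are measured before or after white
balance is configurable; the default is after.

Maturity grading is total on [0, 1] via contiguous half-open bins on red
coverage — level 1 below 1% red+yellow, level 2 below 10% red, level 3
below 40%, level 4 below 70%, level 5 at or above 70%. The published
five-level standard leaves 30–40% and 60–70% unassigned; closing the bins
at 40 and 70 keeps grading monotone and total.

Polygon annotations (LabelMe dialect, `shapes[[i]]$points`) rasterize over
zero-based pixel centers with inclusive boundaries, so a square from
(0,0) to (10,10) covers 11 × 11 = 121 pixels; multiple shapes union.

## The recurrent models

The LSTM cell implements the four-gate equations with weights acting on
the concatenation `[H_{t−1}, X_t]`; the GRU cell the reset/update pair
with candidate `tanh(w_xh x + w_hh (r·h_prev) + b_h)`. Attention projects
every hidden state to a key and value and the *final* state to the query
(the query construction is a package decision — last-step query is the
standard choice for sequence regression), scores by dot product, and
normalizes with softmax; the context vector feeds a ReLU fully connected
layer and a linear 3-output head. Raw head outputs are clipped to [0, 1]
and renormalized so predictions live on the 3-simplex (surface fractions).

Everything trains with Adam (learning rate 0.001) under mean squared
error; batch sizes are 32 (environment), 64 (color) and 16 (quality), for
150/150/100 epochs in the full-size configurations. Weight initialization
is uniform in ±1/√(fan-in) from the model seed; batch shuffling uses the
seed + 1, so identical seeds give bitwise-identical loss histories. There
is no early stopping. Training rejects non-finite losses with the epoch
index (`divergence` error).

**Rollout robustness.** Both recurrent stages are consumed recursively at
inference: each prediction is appended to the window that produces the
next one. A model trained purely on observed windows can be excellent one
step ahead yet drift over a multi-day rollout, because its own small
errors are inputs it has never seen. Two training devices address this:

* *Jitter augmentation* — the trainers add Gaussian jitter
  (SD `input_noise`, default 0.02 in scaled units) to training windows.
  The environment trainer additionally draws a per-window, per-channel
  offset of the same SD: element-wise noise averages out over a 24-step
  window, but a rollout's feedback error is a *correlated* level shift,
  and the offset term is what teaches the map to contract such shifts
  back toward the diurnal attractor. The color model deliberately gets no
  offset term: a shifted color level is a legitimate plant state (plants
  differ in ripening midpoint), and the model should continue from it,
  not regress toward the average trajectory. Set `input_noise = 0` for
  pure teacher-forced fits.
* *Learning-rate annealing* — with a constant Adam step the parameters
  keep orbiting the loss minimum at a radius set by the learning rate; a
  one-step bias that is negligible for next-step metrics is amplified
  several-hundred-fold by a season-long rollout. Setting `lr_final`
  decays the rate geometrically over the epochs and settles the one-step
  map far closer to its minimum; in the integrated experiment this cuts
  the season-long red-fraction rollout error by an order of magnitude.

## The quality network

Architecture 1–256–128–64–6 with ReLU hidden layers and a linear output;
dropout 0.4 (inverted scaling) after each hidden layer during training.
The single input is the scalar `a_n`; with one feature already mapped to
[0, 1] by construction, no input batch normalization is applied (batch
statistics of a scalar at batch size 16 are ill-conditioned). Targets are
standardized per trait on the training set and de-standardized at
prediction, then clamped at zero — the traits are physical quantities.

The multi-task loss is `Σ_k λ_k · MSE_k` over the six standardized
traits. After each epoch the weights are recomputed as
`λ_k = 6 · m_k^γ / Σ_j m_j^γ` with `m` an exponential moving average
(factor 0.7) of per-task MSE and `γ = 0.5`; harder tasks are upweighted,
weights stay positive and always sum to 6. The exponent tempers the
update so one noisy task cannot monopolize the loss; both `γ` and the
smoothing factor are config fields.

## The synthetic greenhouse

The simulator emulates the statistical structure the pipeline assumes:

* **Microclimate** — temperature is a diurnal sinusoid (mean 22 °C,
  amplitude 5 °C, peak at 14:00) plus AR(1) noise (ρ = 0.8, SD 0.5 °C);
  humidity is anti-phase (mean 75%, amplitude 15%, SD 2%), clamped to
  [0, 100]; radiation is a half-sine over a 12 h daylight window (peak
  600 W/m²) with noise truncated at zero and exact zeros at night.
  Missingness is injected in runs (rate 3%, max run 4 by default; a run
  longer than 5 is planted when the configuration allows it, so both fill
  branches are exercised).
* **Color kinetics** — ripening is driven by thermal time,
  `GDD(t) = Σ max(T − 10 °C, 0)·Δt/24`. The red fraction is a logistic in
  GDD (midpoint 130 degree-days, steepness 0.04, between-plant midpoint SD
  6), the yellow fraction a transient Gaussian bump (amplitude 0.35, width
  40 GDD) capped so red + yellow ≤ 1, green the remainder. Red is
  non-decreasing whenever temperature stays above base.
* **Campaign structure** — 80 plants by default, monitored 21 days each,
  with start dates staggered over 7 days; the stagger is what makes a
  temporally gapped plant split possible, mirroring how later-planted
  individuals provide genuinely future test data.
* **Images** — fruit are rendered as discs on a gray background with
  angular sectors in the target proportions and ±12 per-channel jitter;
  sector base colors are chosen so jittered hues stay inside the
  classifier's bands. Measured ratios recover the inputs to within the
  pixel-discretization error (±0.02 is asserted). `a_n` for simulated
  fruit is measured from the rendered image through the full pipeline, not
  computed analytically, so the image path gets integration coverage.
* **Traits** — smooth responses to `a_n`: rising saturating logistics for
  SSC, SS, LYC; falling for FI and TA; a concave peak for VC; all with
  per-trait Gaussian noise and a zero clamp. Ranges are typical of
  greenhouse tomato (e.g. FI 2–6.5 kg/cm², SSC 4–6 °Brix, LYC up to
  0.09 mg/g).

What the simulator does *not* emulate: occlusion, specular highlights and
illumination drift in images; sensor drift and calibration error; weather
regimes beyond a stationary diurnal cycle; biological coupling of traits
beyond their shared dependence on color. Passing recovery tests therefore
demonstrates that the implementation can learn the relationships it was
built for — not that those relationships hold with field accuracy on real
fruit.

## Recovery experiments and problem sizes

The `experiment_*()` functions run noiseless-recovery checks at desk
scale, chosen once as the package's own evaluation design:

* environment: 12 days of noiseless series, reduced 1 × 32 LSTM, 40
  epochs, last 20% of windows held out — next-step temperature R² ≥ 0.95
  expected (observed ≈ 0.999);
* color: 10 plants, 21 days, reduced 32/16/16 GRU-AT, 40 epochs on
  stride-4 windows, held-out test plants — red R² ≥ 0.90 expected
  (observed ≈ 0.999);
* quality: 320 noiseless pairs, 300 epochs, dropout 0 — per-trait holdout
  R² ≥ 0.99 (observed ≥ 0.997). Dropout is disabled here because a
  noiseless capacity check has nothing to regularize; the 0.4 default
  applies to noisy training, and a companion test shows holdout R²
  falling monotonically as trait noise rises;
* integrated: 10 plants, 18 days, all three stages trained on the train
  split (environment 100 epochs and color 200 epochs, both annealed),
  then a full-season recursive rollout on held-out plants — LYC R² ≥ 0.85
  (observed ≈ 0.99 at the reference seed). The rollout's maturity grade
  is non-decreasing, as the monotone kinetics require.

The full-size architectures (3 × 100, 1 × 160, 2 × 64; GRU hidden 64; DNN
256/128/64) remain the constructors' defaults and are structure-tested;
the reduced sizes exist because the recovery signal is noiseless and the
experiments are meant to run in minutes on one core.

## Numerical choices and edge cases

* Quantiles: type 7; constant series give zero-width fences and flag
  nothing.
* Scaling: a constant variable is a `degenerate scale` error, not a NaN.
* `R²` on zero-variance truth is an error at the metric level and
  reported as `NA` in metric tables.
* Simplex projection: all-zero rows (possible only with pathological
  weights) fall back to the uniform (1/3, 1/3, 1/3).
* The red-fraction → a\* proxy is isotonic regression with linear
  interpolation and flat extrapolation; monotonicity is what makes the
  predicted maturity trajectory inherit the kinetics' monotonicity.
* Checkpoints are JSON at full decimal precision; round-trip predictions
  agree to 1e−12 (decimal text, not bit-exactness).
* All RNG flows through explicit seeds (`withr::with_seed`); training
  functions never touch the global RNG state outside their scope.

## Known limitations

The a\* proxy collapses the three predicted fractions to one scalar
through red alone; when yellow carries independent information the
integrated path cannot use it. Trait predictions inherit every upstream
bias: a rollout that mistimes the color transition shifts the whole
quality trajectory. The grading bins close the published standard's
unassigned ranges by fiat. And the simulator's noiseless recovery results
bound implementation correctness, not field performance.
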