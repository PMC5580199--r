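---
title: "Methods: the asthmawatch risk pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the asthmawatch risk pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asthmawatch)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, the choices made where the design
was genuinely open, and what the synthetic benchmark does and does not
demonstrate.

## The problem

Asthma exacerbations are driven jointly by environment (smoke, dust,
particulates, weather) and physiology (airway function, exertion). A
wearable platform can observe both sides continuously: an optical dust
sensor and a PM2.5 monitor sample the air, a Bluetooth spirometer
measures peak expiratory flow (PEF, L/min) and forced expiratory volume
in one second (FEV1, L) on demand, and a smartwatch contributes heart
rate, tri-axial acceleration and location. The analytic task is to map a
rolling window of these streams, fused with online air-quality and
weather sources, to a three-level asthma attack risk estimate that can be
shown to the wearer in real time. This package implements that analytics
path end to end at desk scale.

## Dust calibration

Optical dust sensors drift with temperature and humidity. The calibration
implemented in `dust_density()` is piecewise in the signs of the humidity
deviation ΔH and temperature deviation ΔT from the reference conditions
under which the sensor was bench-calibrated:

* ΔH = 0, ΔT = 0: ρc = 5.4×10⁻⁴·x − 0.15, with `x` the raw voltage;
* ΔH > 0: a humidity-driven fit αH·H + βH minus a temperature correction
  (αT1·T + βT1 when ΔT > 0, αT2·T + βT2 when ΔT < 0);
* ΔH < 0: the affine voltage fit minus a constant correction
  (αT1 + βT1 or αT2 + βT2 by the sign of ΔT),

with αH = 2.8×10⁻³, βH = 0.1647, αT1 = 0.0005, βT1 = 0.0133,
αT2 = 0.0002, βT2 = 0.0329.

Numerical choices worth stating explicitly:

* **Reference conditions.** The bench calibration's reference temperature
  and humidity are not part of the published constants; they are stored
  in `dust_coefficients()` (defaults 25 °C, 40 %RH) and are overridable,
  including from the `dust_calibration` section of a YAML config.
* **Zero deviations.** Exact zeros of ΔH or ΔT sit on branch boundaries.
  ΔH = 0 is routed to the ΔH < 0 family and ΔT = 0 to the ΔT < 0 family —
  the branches that retain the voltage term and are continuous with the
  both-zero affine case; ΔH = ΔT = 0 itself uses the plain affine fit.
* **As-calibrated fidelity.** The ΔH > 0 branches contain no voltage term
  and the ΔH < 0 corrections subtract (αT + βT) without a temperature
  multiplier. Both look like they could be transcription artifacts of the
  original fit, but second-guessing a calibration is worse than exposing
  it: the branches are implemented exactly as calibrated, with a
  documented deviation hook (`humid_branch_adds_affine`) that adds the
  affine term to the humid branches for sensitivity analyses.
* **Clamping.** The affine fit goes negative below x ≈ 278; densities are
  clamped to zero after calibration and the affected records counted
  (`clamp_nonnegative()`), since a negative density is physically
  meaningless but silently rewriting data is not acceptable either.
* Units of `x` are the sensor's native raw unit and are treated as
  opaque; dust density is likewise reported in calibrated sensor units.

`calibrate_dust_stream()` pairs each dust sample with the most recent
temperature and humidity reading (last observation carried forward,
LOCF); before the first such reading the reference conditions are
assumed, which by construction selects the plain affine branch.

## Preprocessing

Sensors in this class report missing values as a data point completely
out of range (e.g. 65535). `remove_invalid()` drops such samples and `NA`
records against per-channel closed valid ranges — closed because a value
exactly at a limit is a legitimate saturated reading. The report
reconciles exactly: input = kept + out-of-bound + missing, per channel.
Nothing is imputed at this stage; the deployed system removes rather than
fills.

`smooth_stream()` applies a trailing (causal) 6-s moving mean over the
half-open window (t − 6, t]; trailing rather than centered because the
pipeline must run in real time, where future samples do not exist.
Smoothing is applied to the environmental channels only — the activity
statistic below is a within-window variance, which smoothing would
destroy. `baseline_scale()` formalizes "increasing sensitivity when data
deviate from baseline" as an affine gain about the baseline,
v → baseline + gain·(v − baseline), default gain 1 (off); the operation
is exposed but the default pipeline does not apply it, since no gain
value is published.

## Features

Each classification window (60 s, trailing, hop 60 s; half-open
[start, end) so boundary samples are counted exactly once) yields 16
features in a fixed declared order (`feature_names()`):

* **percent FEV1, percent PEF** — 100·current/mean of the subject's three
  at-rest baseline measurements, the percent-of-personal-best convention
  of asthma action plans. Spirometry is episodic, so the window carries
  the last observation at or before its end (LOCF) with a 24-h staleness
  horizon, after which the feature is flagged missing.
* **dust density, particulate matter, temperature, humidity** — trailing
  window means of the cleaned, calibrated, smoothed channels.
* **heart rate reserve** — HRmax = 208 − 0.7·age (an age-predicted
  maximum that remains valid in children); HRR = HRmax − HRrest. Since
  HRR itself is a per-subject constant with no per-window information,
  the window feature is the fraction of reserve in use,
  (mean HR − HRrest)/HRR, clipped to [0, 1.5] (readings slightly above
  the age-predicted maximum occur in practice). The raw constant is
  exposed as `hr_reserve()`.
* **total energy expenditure** — the composite acceleration statistic
  over 5-s accelerometer sub-windows:
  Km = (1/(n−1))·(Q − P/n), with Q the sum of squared samples over the
  three axes and P the sum of squared per-axis sums. This is precisely
  the computational shortcut for the summed per-axis sample variance. The
  source material prints P with the same expression as Q, a typographic
  duplication under which Km would degenerate to Q/n — that literal
  reading is available behind `as_printed = TRUE` for audit, and the
  phrase "vector norm" notwithstanding, no square root is applied by
  default (`sqrt_norm = TRUE` provides one). The window feature is the
  mean of Km over complete sub-windows; mean rather than sum so that the
  value is invariant to the window/sub-window length ratio (sum behind
  `aggregate = "sum"`).
* **eight online-source features** — ozone, pressure, cloud cover, wind
  speed, precipitation probability and intensity, traffic density, AQI —
  joined to the window end by LOCF from a fixture table. A window earlier
  than the first table row is an error rather than an extrapolation.

Missing features are flagged `NA`, never zero-filled; the model layer
imputes them with training-set medians stored in the model bundle, so
prediction-time behavior is fixed by the training data and reproducible.

## Labels

Asthma Control Test (ACT) totals run 5–25, lower meaning worse control.
Bins: 20–25 low, 15–19 medium, ≤14 high risk. The published bin listing
assigns 19 to both low and medium; 19 is resolved to medium, consistent
with the instrument guidance that control may be inadequate at 19 or
less, and 15 to medium per the explicit listing. `act_to_risk()` is
total, exhaustive and monotone on 5–25, which the suite verifies by
enumeration.

Windows are labeled by the nearest ACT observation within ±30 min of the
window end — half the hourly ACT cadence, so that hourly observations
label every window while anything staler is excluded from training.
Equidistant observations resolve to the earlier one (deterministic, and
the earlier observation is the one a causal system would have had).

## Classifier protocol

A probability random forest (`ranger` backend, single-threaded for
determinism) over the 16 features. The evaluation protocol is 10-fold
cross-validation: a seeded random partition into near-equal folds (sizes
differ by ≤1), each fold validated exactly once. Grid search — trees
{100, 300}, depth {unlimited, 5, 10}, features per split {√p, p} — runs
as an inner 5-fold cross-validation *inside each outer training fold*;
nesting is not specified by the source protocol, but without it the
reported outer accuracy would be biased by hyperparameter selection on
validation data. Ties in the grid resolve to the first row; exact
probability ties at prediction resolve toward the higher risk level, a
safety-first choice for a medical alert. Chance level for three classes
is 1/3 (33.33%). Class imbalance is reported (`class_counts`) but not
reweighted, matching the source protocol's silence. A naive Bayes
baseline (`engine = "naive_bayes"`) runs in the identical harness for
comparison.

The model bundle stores the fitted forest, the declared feature order,
imputation medians, winning hyperparameters, seed and a training-data
fingerprint; predictions are pure functions of (bundle, features), and
bundles round-trip through serialization prediction-identically.

## The synthetic generator

`generate()` produces every input the pipeline consumes: sensor records
(accelerometer 20 Hz, heart rate 1 Hz, dust/PM 0.2 Hz,
temperature/humidity 0.1 Hz, spirometry 1/min), an online-source table,
ACT observations and per-window ground truth. An episode script places
smoke and exercise episodes on the timeline:

* smoke at intensity i multiplies mean dust and PM by 1 + i·(5 − 1) and
  depresses spirometry draws by i·35% of baseline (capped at 90%);
* exercise drives heart rate toward HRrest + i·HRR (capped at HRmax) and
  multiplies accelerometer variance by 1 + i·(25 − 1);
* quiet time emits baselines plus Gaussian noise; dropout replaces
  records with the sentinel at probability 0.01.

ACT scores are drawn uniformly within the bin the episode severity
dictates — quiet → 20–25, mild (0 < i < 1) → 15–19, severe (i ≥ 1) →
5–14 — which mirrors the label bins so ground truth is well defined. The
default profile is a 29-year-old with resting HR 60 and baseline PEF
triplet averaging 320 L/min, matching the reported symptom-free average
of the feasibility subject. Default effect sizes were chosen once to be
learnable but noisy (e.g. a mild smoke episode moves PEF about 3.7
channel SDs, mild exercise moves the HR fraction about 25 SDs of the
windowed mean), and the default mixed scenario is six hours in six
hour-aligned blocks, two hours per risk tier, so hourly ACT observations
at block midpoints label every window consistently.

One generative choice deserves emphasis: online-source variables are held
constant within a session, varying only between sessions. Weather and
regional air quality are strongly autocorrelated at the 1–6 h scale, and
during development an earlier i.i.d.-per-row variant demonstrated a
pitfall worth preserving in documentation — with per-hour labels, any
feature that effectively indexes session time lets a forest memorize the
episode timetable rather than the physiology, which inflates
cross-validated accuracy and collapses on a new session. Constant
within-session online features remove that channel entirely.

What the generator does **not** emulate: diurnal physiology, sensor
drift, autocorrelated (non-Gaussian) noise, label noise in ACT
self-reports, location-dependent online features, or the real
co-variation structure of a week in the field. Consequently, pipeline
tests on synthetic data show that the machinery recovers *planted*
structure — they are validity checks of the implementation, not evidence
about field accuracy, and the headline accuracy of the original
feasibility deployment is deliberately not a target of this package.

## Validation suite, problem sizes

The acceptance tests run, at sizes chosen to keep the whole suite within
a few minutes on one core:

* chance-level convergence: 3000 shuffled-label feature vectors, 10-fold
  CV, agreement with 1/3 within 3 standard errors;
* calibration worked examples, finite-difference affinity in `x`
  (slope 5.4×10⁻⁴) and branch exhaustiveness over the sign grid;
* the Km statistic against an independent two-pass variance oracle on
  500 random windows at 10⁻¹⁰ relative tolerance, plus translation
  invariance and k² amplitude scaling;
* ACT bin totality/monotonicity and the anchor scores 25 → low,
  17 → medium, 10 → high;
* end-to-end recovery on the default six-hour mixed scenario (360
  windows, 120 per tier): nested-grid 10-fold CV accuracy at least 30
  percentage points above chance, and, with all effect sizes neutralized,
  return to chance within 3 standard errors;
* cleaning conservation, the 6-s smoothing oracle, and the
  variance-contraction property of the moving mean;
* envelope round-trips, tamper and wrong-key failure, key-length
  contracts (128-bit transport, 256-bit at rest);
* bit-reproducibility of generation, fold assignment, training and
  prediction under fixed seeds.

## Security model of the envelope

Transport uses a fresh random 128-bit AES key per envelope (GCM mode),
wrapped with the recipient's 2048-bit RSA key under OAEP; integrity is
enforced by encrypt-then-MAC (HMAC-SHA256 over IV‖ciphertext, key derived
from the transport key) plus a SHA-256 digest of the plaintext, so a
flipped ciphertext bit fails loudly rather than decrypting to silent
garbage. At rest, payloads re-encrypt under a 256-bit AES-CBC storage key
with the same digest check. Key management is deliberately minimal —
in-memory keys identified by `key_id`; no HSM, rotation or access-control
layer — the envelope is the cryptographic contract, not a deployment.

## Known limitations

* Single-subject design: profiles are per-subject, but the pipeline has
  no cross-subject normalization or mixed-effects structure.
* The ±30 min label horizon and 60-s window are defensible defaults, not
  identified optima; both are configurable.
* The calibration accepts its printed constants as ground truth; no
  re-derivation from co-measurement data is possible or attempted.
* Median imputation of missing features is simple and ignores
  feature correlations; it is stored with the model to keep predictions
  reproducible, not because it is optimal.
* Synthetic validation bounds implementation correctness, not clinical
  performance (see above).
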