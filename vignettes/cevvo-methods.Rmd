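---
title: "Predicting VV-ECMO decannulation from perfusion time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting VV-ECMO decannulation from perfusion time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients in refractory respiratory failure can be supported on venovenous
extracorporeal membrane oxygenation (VV-ECMO). Deciding *when* to attempt a
weaning trial and decannulate is largely a matter of clinical judgement.
The ECMO device itself, however, continuously records the patient–device
interaction: circuit blood flow, pump speed, sweep gas flow, the pressure
drop across the membrane lung and the venous drainage pressure, sampled
every couple of minutes over runs lasting days to weeks. `cevvo` implements
a modelling pipeline that turns one such run — together with a handful of
static clinical variables — into a continuously updatable probability that
the patient will ultimately be weaned and decannulated successfully.

Formally, each patient is a tuple $(s, x_{1:T}, y)$: a static feature
vector $s$, a multivariate perfusion series $x_{1:T}$ with $V = 8$
channels, and a binary outcome $y$ (1 = successful decannulation). The
model learns $\hat p(y \mid s, x_{1:T})$ by minimising the mean binary
cross-entropy

$$L = -\frac{1}{N}\sum_{n=1}^{N}
  \bigl(y_n \log \hat y_n + (1-y_n)\log(1-\hat y_n)\bigr).$$

## Preprocessing

**Derived channels.** Two ratios normalise for patient size and support
intensity: flow/BMI and sweep/flow. At time points where flow is exactly
zero, sweep/flow is defined as 0 (no support implies no attributable gas
exchange), avoiding infinities.

**Truncation augmentation.** To make the prediction available *during* the
run, each patient contributes ten samples: the prefixes containing the
first 10%, 20%, …, 100% of the raw time points. A 118-patient cohort thus
yields 1180 samples. Each sample remembers `end_day`, the day its prefix
ends, which drives the per-day evaluation and the 72/96-hour snapshots.

**Length standardisation.** Every prefix is stretched over a fixed grid of
$T$ steps (2054 at full scale; tests and examples use 64–128). Raw point
$k$ of $K$ (0-based) lands in slot $\lfloor kT/K \rfloor$; slots receiving
several points take their mean, empty slots are forward-filled, and slots
before the first filled one are 0. Averaging precedes forward-filling:
dense regions are summarised first and gaps then inherit the summarised
value, which keeps the result independent of how a dense region is
interleaved with a gap. Because every prefix spans the whole grid, the
model receives no cue about which truncation it is seeing.

**Static encoding.** The published width of the encoded static vector is
32, but its exact composition is not; the schema here is a documented
stand-in with the same width: four numerics (age, BMI, two cannula sizes),
two binaries (pre-ECMO arrest, pre-ECMO shock), and one-hot blocks for sex
(2), cause of respiratory distress (9), reinfusion site (5), drainage site
(5) and ventilation type (5). The outcome is never encoded.

**Scaling.** Min–max scaling per feature (each perfusion channel over all
time steps, each static dimension) is fitted on the training split only and
applied to all splits, without clipping; a feature constant in training
maps to 0.

## The two-headed classifier

The static head encodes $s$ through dense tanh layers of 32, 33 and 25
units. It is trained under an autoencoding scheme: an auxiliary linear
decoder maps the 25-unit code back to the 32 inputs and contributes a
mean-squared reconstruction loss with weight 0.1 (configurable). The
second layer being *wider* than the input is implemented as specified; the
reconstruction term still regularises the code even without a bottleneck.
Whether that auxiliary loss is essential is unknown, so its weight may be
set to 0.

The temporal head first applies a pointwise (1×1) convolution with tanh
activation, expanding the 8 channels to 1024 feature maps (32 in the
`small` profile) — a cheap, parameter-light filter that can scale, mix and
negate channels before the recurrence. An LSTM with as many units as
filters consumes the $T$ steps; its final hidden state summarises the run.

The 25-dim static code and the LSTM state are concatenated (width 1049 at
full scale) and fed to a single sigmoid output neurone. Training is
mini-batch Adam (learning rate 1e-3, batch 32 by default — the original
optimiser settings are not published, so these standard values are exposed
in `model_config()`), with early stopping on validation loss and
restoration of the best weights. The entire network, including the LSTM
backward pass, is implemented in base R matrix operations; the analytic
gradients are verified against central finite differences to ~1e-6 in the
test suite.

The `small` profile (32 filters/units, series of ~128 steps) exercises the
identical code paths at desk scale; all package tests and the worked
examples use it. Reference classifiers — ridge logistic regression,
Gaussian naive Bayes, a one-hidden-layer dense network, and a CART tree —
consume the flattened `T × 8 + 32` feature vector under the same protocol.

## Cross-validation and evaluation

Each iteration shuffles the patients into 5 disjoint groups with a fixed
class composition (18 successful + 5 unsuccessful with the 90/28 cohort;
surplus patients are excluded at random), then rotates the test group
through all 5 positions with the adjacent group as validation; 12
iterations by default. Splits are patient-level: all truncations of a
patient stay together, which the tests assert across every split.

AUROC is the tie-aware Mann–Whitney statistic; average precision is the
step-wise area under the precision–recall curve. Confidence intervals come
from 5000 joint resamples of (label, score) pairs; degenerate single-class
resamples are skipped and counted rather than redrawn (their handling is
otherwise unspecified, and redrawing would bias the resample distribution).
Predictions are pooled across iterations before bootstrapping; per-day
tables bucket samples by `end_day` into half-open intervals $(d-1, d]$.

Model comparisons use a paired permutation test: the statistic is the
metric difference, and the null swaps the two models' scores per sample
with probability ½. The form of the published test is not specified;
per-sample swapping respects the pairing, and an exhaustive-enumeration
path (all $2^n$ patterns for $n \le 20$) guards the Monte-Carlo
implementation in the tests. P-values use the add-one correction.

## Calibration, risk groups and the exact test

Raw sigmoid outputs are recalibrated by Platt scaling — a logistic
regression of training labels on the log-odds of the raw score — which is
strictly monotone and therefore leaves AUROC unchanged. Calibrated
training predictions define $M_D$ and $S_D$ (their mean and SD, computed
over *all* training truncation samples, the natural reading of
"training-set outputs"), and a prediction $x$ falls into risk group 0
($x \le M_D - S_D$), 1, 2 or 3 ($x > M_D + S_D$), with closed upper
boundaries.

For the 72- and 96-hour snapshots, each patient still on support at the
cutoff contributes the prediction whose prefix ends nearest before the
cutoff; patients decannulated earlier are excluded. Group-0 vs group-3
success proportions are compared with Boschloo's exact unconditional test:
ordering statistic = Fisher's one-sided exact p, maximised over a 999-point
grid on the nuisance success probability. One-sided is the default, with
the alternative that the low-risk group has the higher success rate: on the
published snapshot tables the one-sided unconditional p-values (.036 and
.012) round to the printed two decimals, whereas Fisher's one-sided values
(.077 and .030) do not. The test is validated against a full enumeration
oracle and satisfies $p_{\text{Boschloo}} \le p_{\text{Fisher}}$.

## The simulated cohort generator

No patient-level data set is distributable, so `cohort_spec()` /
`generate_cohort()` define the study conditions for everything the package
can demonstrate end-to-end: 90 successful and 28 unsuccessful patients,
runs uniform between 3 and 21 days sampled at 120 s, and jittery
autocorrelated traces. Each raw channel is

*baseline + patient offset + OU noise (+ outcome-dependent wean)*,

with an AR(1)/Ornstein–Uhlenbeck noise process (correlation time 6 h) and
per-patient baseline offsets capturing between-patient heterogeneity.
Static variables are outcome-independent by construction, so the
*only* learnable signal is temporal. The wean of a successful patient has
two components over the final quarter of the run, both scaled by
`effect_size`:

1. a declining mean ramp on flow, pump speed and sweep (support titrated
   down), multiplied by a per-patient Gamma(4, 4) "pace" so that the
   expected final-quartile group gap equals `effect_size * ramp_unit`
   while individual weans vary; and
2. progressive *settling*: the OU noise on those channels is damped by
   $1/(1 + \text{effect\_size} \cdot r)$, $r: 0 \to 1$ across the
   quartile, reflecting the increasingly steady device settings of a real
   wean.

The second component matters methodologically. A deterministic mean ramp
alone is a linear-in-time contrast that a logistic regression on flattened
features detects essentially perfectly, leaving every model at ceiling and
no room for architectural differences; a variance signature is invisible
to linear models but available to a recurrent network, and it lives in
exactly the local temporal structure that heavy smoothing removes. With
`effect_size = 0` the generating law is identical for both outcomes — the
null-safety tests verify that no model can beat AUROC 0.5.

The generator makes no claim of physiologic validity beyond plausible
magnitudes; what passing tests show is that the *pipeline* behaves as
specified on data with this structure, not that the model performs at any
particular level on real patients.

## Gaussian-process cohort synthesis

To isolate temporal dependence as the performance driver, the package
re-creates the surrogate-cohort methodology. Patients are split by
outcome, sorted by run length, and grouped into consecutive triplets
(30 successful + 8 unsuccessful at the published cohort size). For each
triplet, one GP regressor per perfusion variable (8 in total) is
conditioned on the stacked member data: covariates are standardised age,
sex and BMI plus the time-step index; targets are the unnormalised
perfusion values on a uniform grid (the training grid is not published; a
uniform grid of the model's 2054 steps — 128 at desk scale — is used). The
kernel is the RBF *exactly as printed*,
$k(x_i, x_j) = \exp(-d^2 / (2L))$ with Euclidean $d$ — note the
denominator $2L$ rather than the conventional $2L^2$; a
`convention = "squared"` flag provides the textbook form. Targets are
internally standardised per variable, so a relative jitter of 1e-6 on the
kernel diagonal acts as observation noise proportional to each variable's
variance and one Cholesky factorisation serves all 8 regressors; the
jitter escalates (with a warning) when a very smooth kernel makes the
system numerically singular.

Sampling a synthetic patient draws all 8 variables from their posteriors
evaluated at one member's static covariates over the full grid (members
are reused round-robin across draws, since the evaluation covariates are
not published). Successful triplets are sampled 3 times and unsuccessful
ones 18 times, giving the published 90 + 144 = 234 synthetic patients,
each labelled by its source triplet. Fold plans operate at triplet level —
5 groups of 6 successful + 1 unsuccessful triplet (36 synthetic patients
each), surplus unsuccessful triplets excluded at random — so sibling draws
never straddle a train/test boundary.

`length_scale_experiment()` runs the full contrast: synthesise at $L=1$
(posteriors nearly interpolate the rough member traces, preserving local
structure) and $L=100$ (only smooth components survive), train the fusion
network and logistic regression on both, and compare each model's pooled
test AUROC across length scales with the paired permutation test
(predictions pair by synthetic patient id, the fold plan being shared
across length scales). The expected signature is a significant drop for
the recurrent model only: the mean-level signal survives smoothing (so the
linear model is unaffected), but the settling signature does not.

One training choice is specific to these triplet-level folds: the fusion
network trains for a *fixed* epoch budget (60 epochs at learning rate
3e-3 by default) rather than with validation early stopping. Each
validation group's negative class is a single triplet, so validation loss
is dominated by one patient cluster and can be anti-correlated with true
discrimination — in the worst case early stopping would restore the
untrained initial weights. (`min_epochs` in `model_config()` guards the
general training path against that failure mode.) An `n_ensemble` option
additionally allows averaging independently initialised networks,
applied identically at both length scales.

In pilot simulations at these desk-scale sizes the contrast behaves as
expected directionally — the fusion model's AUROC difference between
rough and smooth cohorts is positive in most seeds while the linear
model's difference stays within ±0.015 — but per-seed significance is
limited: much of what the small network learns here is the mean-level
component of the wean, which survives smoothing, so the part of its
performance attributable to local temporal structure is modest. At the
published scale (2054 steps, 1024 units, truncation-augmented training)
the recurrent model has both more capacity and more data with which to
exploit local dynamics; the desk-scale experiment demonstrates the
machinery and the direction of the effect rather than its full size.

## Numerical choices and degenerate inputs

* Probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ before logs.
* An empty series standardises to an all-zero matrix rather than erroring.
* Constant features scale to 0; unscaled-looking inputs at prediction time
  raise a warning, not an error.
* Bootstrap pairs are put in canonical order before resampling, making the
  interval invariant to input ordering under a fixed seed.
* LSTM forget-gate biases initialise at 1 (standard conditioning);
  all other weights are Glorot-uniform.
* Posterior covariance matrices are symmetrised and eigenvalue-clamped at
  0 before sampling.

## Problem sizes used in the shipped tests

The test-suite and examples run the small profile throughout: cohorts of
~10–120 simulated patients, series of 12–128 steps, 1–5 cross-validation
rotations, bootstrap B of 200–1000, and the full 1024-unit geometry is
constructed (but not trained) once to check the published widths. These
sizes are the package's own desk-scale choices; the full-scale defaults
(2054 steps, 1024 units, 12×5 folds, B = 5000) remain available through
the same interfaces.

## Known limitations

* The static schema is a stand-in: published work fixes only its width.
* The generator's weaning signature is stylised; absolute AUROC levels on
  simulated cohorts do not transfer to real patients.
* Training the full 1024-unit model on 2054-step series in base R is
  possible but slow; the implementation favours transparency and exact
  gradient correctness over speed.
* The exact unconditional test maximises over a finite nuisance grid
  (999 points); the supremum could in principle fall between grid points,
  though agreement with an independent implementation is to 5 decimals.
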