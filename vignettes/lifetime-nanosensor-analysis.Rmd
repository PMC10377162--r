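---
title: "Lifetime nanosensor analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifetime nanosensor analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tausense)
```

`tausense` analyses fluorescence-lifetime nanosensors: molecularly
imprinted polymer nanoparticles whose covalently incorporated fluorophore
reports template binding as a drop of its slow lifetime component. This
vignette is the package's own account of the models it fits, the
statistical conventions it follows, and the design decisions taken where
several defensible choices existed.

## 1. The decay model and reconvolution fitting

A TCSPC acquisition bins photon arrival times into `n_channels` channels of
width `channel_width` (ps); channel *i* covers `[i·w, (i+1)·w)` with the
model evaluated at channel centers, and channel 0 starts at *t* = 0. The
measured histogram is the true decay convolved with the instrument response
function (IRF, "prompt"). Rather than deconvolving the data, `decay_fit()`
convolves the model with the measured prompt and fits the result
(*iterative reconvolution*):

* monoexponential: `I(t) = I0 * exp(-t/tau)` plus constant background `A`;
* biexponential: `I(t) = A + B1*exp(-t/tau1) + B2*exp(-t/tau2)`.

The biexponential form is an *approximate* description of a heterogeneous
fluorophore population: `tau1` collects all non-specifically placed
fluorophores, `tau2` those in or near imprinted cavities. When a titration
is analysed, `tau1` is fixed to the value obtained from a free fit of the
blank (zero-analyte) decays and held as a global descriptor — the numeric
value is always data-derived, never hard-coded.

**Objective.** The default objective is Neyman-weighted least squares,
`sum((obs - exp)^2 / max(obs, 1))`, the convention of standard TCSPC
analysis software, whose reduced chi-square (`N_used - p_free` denominator,
no channels excluded by default) is the reported fit quality. A Poisson
maximum-likelihood objective (`objective = "poisson"`, deviance residuals)
is available; it is preferable when many channels hold fewer than ~30
counts, where the Neyman weights are known to inflate chi-square (the
per-channel expectation of the Neyman summand is ≈1.31 at 10
counts/channel versus ≈1.04 at 50).

**Free parameters and bounds.** Amplitudes and background are bounded below
by 0; lifetimes to `[channel_width/10, 10 × window length]`; and a
sub-channel IRF shift (linear interpolation of the prompt, bounded ±5
channels) is a free parameter by default — reconvolution without a shift
parameter is brittle against sub-channel timing offsets. Any parameter can
be held fixed; fixed parameters receive no standard error.

**Initial values.** `initial_guess()` estimates the background as the
*median* of pre-peak channels (robust to the prompt rise leaking into the
baseline window), then regresses log counts on time over the last 30% of
post-peak channels that sit clearly above background. Two robustness rules
matter here: channels enter the tail only if a 9-channel moving average
exceeds the threshold (isolated Poisson outliers in a sparse background
otherwise masquerade as decay tail and flatten the regression), and the
threshold is at least background + 1% of the background-subtracted peak (a
pure `2A` cut admits noise channels when `A` is small). Histograms whose
tail has fewer than 10 usable channels, or no decaying trend, are rejected
with an error.

**Optimization and convergence.** Levenberg–Marquardt
(`minpack.lm::nls.lm`) with tight tolerances (`ftol = 1e-14`,
`ptol = 1e-12`, ≤500 iterations). Non-convergence is a reported state
(`converged = FALSE`), not an exception. On noiseless inputs the fitter
recovers generating parameters to machine-level accuracy (asserted in the
test suite at 1e-6 relative). Standard errors come from the scaled inverse
of `J'J` with diagonal preconditioning and an SVD pseudo-inverse fallback,
so exact (noise-free) fits report zero rather than missing uncertainties.

**Label convention and degeneracy.** Fitted biexponentials are relabelled
so `tau1 <= tau2` (amplitudes swapped along). A fixed lifetime keeps its
label; if a free `tau2` falls below a fixed `tau1` the fit has collapsed
and is flagged. A fit is flagged *degenerate* (warning, flag in the result)
when one amplitude falls below 5% of the other or the lifetimes approach
within 10% — the expected outcome of fitting a biexponential to
monoexponential data, where individual lifetimes are meaningless although
the amplitude-weighted mean remains accurate.

**Verification oracle.** `grid_oracle_fit()` is a brute-force check used
only in tests: on a lifetime grid (≤50 points/axis, ≤1e6 nodes) it solves
amplitudes and background in closed form by weighted linear least squares
at each node — the expectation is linear in them — and returns the
grid-global minimizer of the same objective. The test suite asserts the
iterative optimizer never does worse.

## 2. Binding isotherms

Lifetime titrations are fitted with the **baseline Hill model**

```
tau2(x) = tau2_0 + (tau2_max - tau2_0) * x^n / (EC50^n + x^n)
```

A bare Hill form without baseline (`tau2_max * x^n / (EC50^n + x^n)`)
appears in the sensing literature, but it forces `tau2(0) = 0`, which
contradicts a sensor that reports a finite zero-analyte plateau alongside a
saturation plateau; the baseline form is what reproduces such parameter
sets, so it is the fitted model, with the bare variant retained only for
evaluation (`predict_hill(..., baseline = FALSE)`). With a mass-action
constant *K* in units of M^n (as in `x^n/(K + x^n)`), the half-saturation
concentration is `EC50 = K^(1/n)`; the fit is parameterized directly by
EC₅₀ (molar), which is the quantity reported as the apparent dissociation
constant K_app. Intensity titrations use the Langmuir model
`y = START + (END - START) * x / (k + x)` (the Hill form with `n = 1`; the
test suite asserts the two agree to 1e-9 in EC₅₀ on shared-shape data).

Numerical choices:

* fitting is on log10-concentration internally (conditioning across six
  decades of concentration); EC₅₀ standard errors are delta-method
  back-transforms, and EC₅₀ scales exactly with concentration units
  (equivariance is tested);
* the Hill coefficient is bounded to [0.2, 6];
* starting values come from the data (end plateaus from the extreme
  concentration groups, EC₅₀ from the group nearest the response midpoint,
  `n = 1`);
* **weighting:** the default is an *unweighted* fit. Inverse
  replicate-variance weighting (`weights = "variance"`) is offered, but
  with triplicate groups the sample variances are so noisy that
  weighting *increases* the EC₅₀ sampling error and makes the reported
  standard errors undercover (the package's Monte-Carlo calibration test
  holds 2-se coverage in [88%, 99%] only for the unweighted default, which
  is also the default of common curve-fitting software);
* non-monotone series (beyond twice the pooled replicate noise) warn but
  fit.

**Non-convergence is data, not an error.** Titrations from sensors with no
binding response genuinely fail to define an isotherm, and the package
reports that state (`converged = FALSE`) rather than raising: triggers are
a data span below twice the pooled replicate noise, a fitted transition
smaller than twice its own standard error, an EC₅₀ uncertain by more than a
decade, a half-saturation pinned at its box bound, singular curvature, or
optimizer failure. The metrics stage refuses non-converged fits.

## 3. Sensor figures of merit

From a converged Hill fit and blank statistics, `assemble_metrics()`
composes: `K_aff = 1/K_app` (exact reciprocal, tested to 1e-12);
sensitivity at low concentration `|tau2_max - tau2_0| / K_app` — the
conventional span-over-K figure, *not* the derivative of the Hill curve at
zero, which vanishes for `n > 1`; limit of detection
`3 * sd_blank / sensitivity`; and the 10–90% linear dynamic range
`x_f = EC50 * (f/(1-f))^(1/n)`, whose endpoints satisfy
`x_90/x_10 = 9^(2/n)` with geometric mean exactly EC₅₀. The blank standard
deviation must come from ≥2 replicate blank measurements or an explicit
override — a single blank cannot silently define an LOD. Published values
of these metrics are not always mutually consistent (e.g. an affinity
constant that is not the reciprocal of the printed K_app, or a dynamic
range that does not follow from any printed (EC₅₀, n) pair); the package
computes each metric strictly from its defining formula.

## 4. The synthetic-data generator

The generator emulates the acquisition that motivated the package: 1023
channels at 109.73 ps/channel, decays accumulated to 10,000 counts in the
peak channel, and a titration spanning 100 fM–150 nM (10 log-spaced
points, triplicate).

* **Prompt:** a Gaussian with 500 ps FWHM centred 2 ns into the window,
  discretized by exact bin integrals. Real NanoLED prompts are asymmetric
  with an afterglow tail; a Gaussian is the standard stand-in when the
  prompt's functional form is unrecorded. (Its width and center are
  configurable; the delta limit is supported for testing.)
* **Counting noise:** per-channel Poisson draws around the noiseless
  expectation. Peak normalization is applied to the *expectation* before
  sampling, so the observed peak fluctuates around 10,000 — mimicking
  stop-at-peak acquisition without modelling acquisition order.
* **Background:** default `A = 50` counts/channel (0.5% of peak), a
  typical dark-count floor. This default also keeps the Neyman chi-square
  convention calibrated: with a much sparser baseline (say 10
  counts/channel) a correctly specified fit's reduced chi-square drifts
  above 1 purely through the Neyman weights (Section 1), not through any
  model error.
* **Fast component:** `tau1 = 1.0 ns` with equal amplitudes `B1 = B2`.
  The fast, non-specific lifetime and the amplitude split of a real
  nanoMIP batch are rarely published; both are configurable and the
  titration machinery never depends on their particular values (only
  `tau2` is driven by the isotherm).
* **Response-level noise:** Gaussian, defaulting to published parameter
  uncertainties (0.009 ns for τ₂-level titrations, 500 rfu for intensity).
* **Determinism:** every consumer seed derives child seeds by a Lehmer
  step (kept below 2^31), so identical configurations are bit-identical
  and stages are decoupled.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: detector afterpulsing, pile-up and dead
time; wavelength-resolved emission and anisotropy; prompt asymmetry;
inner-filter and autofluorescence effects of real matrices (wine);
batch-to-batch nanoparticle heterogeneity. Parameter-recovery results here
validate the *estimators*, not any particular laboratory instrument.

## 5. Selectivity and spiked-matrix calls

`run_panel()` fits every replicate decay with `tau1` fixed from the blank,
averages τ₂ per condition, and calls a condition **binder** when the drop
versus blank exceeds 3 pooled replicate standard deviations (the same 3σ
convention as the LOD), **non-binder** when the absolute change stays
below it, and **indeterminate** otherwise — notably for significant
lifetime *increases*, which indicate non-specific surface interactions,
not binding. Published panels make these calls visually from bar charts;
the 3σ rule is the package's quantitative translation. Conditions with
fewer than two surviving (converged) fits are indeterminate.

For spiked-matrix assays the protocol of interest records the prompt on
the unspiked matrix sample (matrix-matched deconvolution). The package
keeps the unspiked-matrix *emission decays* as the reference condition and
takes the matrix-matched *prompt* as a separate histogram
(`matrix_prompt`), recording which histogram served as prompt; fitting an
emission decay against itself as its own IRF would be degenerate. A flag
(`use_matrix_prompt = FALSE`) selects a plain instrument prompt instead.

## 6. Pipeline, problem sizes and reproducibility

`run_pipeline()` chains simulate (or load) → fit decays → build titration
→ fit isotherm → metrics under one validated config with one seed, writes
every intermediate table plus a JSON manifest (seed, config, per-stage
status, file checksums), and guarantees identical numeric outputs for
identical config + seed. A non-converged isotherm is a reported outcome:
the run succeeds, metrics are omitted.

Problem sizes used by the package's own test and acceptance runs were
chosen as the smallest that exercise the statistics faithfully: full
1023-channel acquisitions wherever a published instrument constant is in
play (acceptance recoveries use 50 replicate acquisitions per condition;
unit-level calibration checks use 30–100), miniature 16–128-channel
configurations for convolution oracles and property loops, and 100
simulated titrations for isotherm coverage checks. A complete
full-scale pipeline run (10 concentrations × 3 replicates × 1023
channels) takes a few seconds on one CPU.

## 7. Known limitations

* No global (linked-parameter) fitting across datasets beyond the
  fixed-τ₁ convention; no phasor analysis or lifetime distributions.
* First-order (delta-method) uncertainties only; no uncertainty
  propagation into LOD/LDR beyond the carried standard errors, and no
  alternative LOD definitions.
* The Neyman objective's chi-square calibration degrades below ~30
  counts/channel; switch to `objective = "poisson"` for sparse data.
* Binder calls assume exchangeable replicates and a common noise scale
  across panel conditions (pooled sd).
* The matrix workflow models only the protocol structure, not wine
  photophysics.
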