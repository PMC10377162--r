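# tausense

Fluorescence-lifetime nanosensor analysis by TCSPC reconvolution fitting and
binding-isotherm inference.

## The problem

Molecularly imprinted polymer nanoparticles (nanoMIPs) carrying a covalently
bound fluorophore act as soluble optical sensors: when the template protein
(here serum albumin) occupies an imprinted cavity, the lifetime of the
fluorophores located in or near that cavity drops. Because the fluorescence
lifetime is essentially independent of probe concentration and excitation
intensity, a time-resolved readout is far more robust than an intensity one.

`tausense` implements the complete analysis chain for such sensors, for
spectroscopists and assay developers who have (or want to simulate)
time-correlated single-photon counting (TCSPC) data:

1. **Decay fitting by iterative reconvolution.** A measured photon-counting
   histogram is modelled as the instrument response function (IRF, "prompt")
   convolved with a mono- or biexponential decay,

   *I(t) = I₀ e^(−t/τ)*  or  *I(t) = A + B₁ e^(−t/τ₁) + B₂ e^(−t/τ₂)*,

   minimizing the Neyman-weighted least squares
   Σ (obs − exp)² / max(obs, 1) (a Poisson-deviance objective is available).
   The fast component τ₁ describes fluorophores outside the binding
   cavities and can be held fixed (globally, from a blank fit); the slow
   component τ₂ is the binding-responsive reporter.

2. **Binding-isotherm fitting.** τ₂ versus analyte concentration *x* follows
   a baseline Hill model,

   *τ₂(x) = τ₂₀ + (τ₂max − τ₂₀) · xⁿ / (EC₅₀ⁿ + xⁿ)*,

   and intensity titrations follow the Langmuir form
   *y = START + (END − START) · x / (k + x)*. The fitted EC₅₀ is the
   apparent dissociation constant K_app.

3. **Sensor figures of merit.** K_aff = 1/K_app, sensitivity
   |τ₂max − τ₂₀| / K_app, limit of detection 3·σ_blank/sensitivity, and the
   10–90% linear dynamic range EC₅₀·(f/(1−f))^(1/n).

4. **Selectivity and spiked-matrix workflows** with 3σ binder /
   non-binder / indeterminate calls, and a **synthetic-data generator**
   (Gaussian prompt, Poisson counting noise, stop-at-peak normalization)
   so the whole pipeline is testable without instrument data.

## Worked example

Simulate a blank acquisition at the reference instrument settings
(1023 channels × 109.73 ps, 10,000 counts in the peak) and fit it:

```r
library(tausense)
cfg   <- tcspc_config(seed = 42)
irf   <- make_irf(cfg)
blank <- simulate_decay(
  decay_params("bi", A = 50, amplitudes = c(0.5, 0.5),
               lifetimes = c(1, 4.183)),
  irf, cfg, label = "blank")
fit_biexponential(blank, irf, fixed_tau1 = 1.0)
#> Biexponential reconvolution fit (neyman objective)
#>        estimate std.error fixed
#> A       49.3430  0.257213
#> B1    6471.9268 87.921097
#> B2    6545.3375 41.354807
#> tau1     1.0000        NA fixed
#> tau2     4.1606  0.014794
#> shift   -1.9260  1.448575
#> reduced chi-square: 1.0509  (iterations: 9)
```

The fitted τ₂ (4.161 ± 0.015 ns) recovers the generating 4.183 ns within
statistical scatter, with a reduced χ² near 1 — the counting noise is fully
explained by the model.

The end-to-end pipeline simulates a full titration (10 concentrations from
100 fM to 150 nM, triplicate, plus replicate blanks), fits every decay with
τ₁ fixed from the blanks, fits the Hill isotherm to the fitted τ₂ values
and assembles the sensor metrics:

```r
run_pipeline(validate_config(list(seed = 42)))
#> tausense pipeline run (seed 42)
#>   stages: simulate [ok], fit_decays [ok], build_titration [ok], fit_isotherm [ok], metrics [ok]
#>   fixed tau1 from blank: 0.9924 ns (blank tau2 sd 0.0127 ns)
#>   isotherm: hill fit converged, EC50 = 21.4 pM
#> Lifetime nanosensor figures of merit
#>   tau2_0 / tau2_max     : 4.184 / 3.975 ns
#>   K_app                 : 21.4 pM
#>   K_aff                 : 4.68e+10 M^-1
#>   sensitivity (low conc): 9.81e+09 ns/M
#>   LOD (3 sigma)         : 3.88 pM  (blank sd 0.0127 ns)
#>   linear dynamic range  : 5.63 - 81 pM (10-90%)
#>   decay fit chi2_red    : 1.009
```

The recovered K_app (21.4 pM) agrees with the generating 18 pM within its
fit uncertainty; all intermediate tables and a JSON manifest (seed, config,
checksums) are written to the output directory, and identical config + seed
reproduce every numeric output byte-for-byte.

A thin command-line wrapper over the same functions lives in
`inst/cli/tausense.R` (subcommands `run`, `simulate`, `fit-decays`,
`fit-isotherm`, `metrics`).

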