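# Shared fixtures: all test inputs are generated in code.

# Reference acquisition: 1023 channels x 109.73 ps, peak 10,000 counts.
ref_cfg <- function(seed = 1L, ...) tcspc_config(seed = seed, ...)

# Small, fast configuration for property-style loops.
mini_cfg <- function(seed = 1L, n = 128L, ...) {
  tcspc_config(n_channels = n, channel_width = 100, peak_target = 5000,
               irf_fwhm = 300, irf_center = 800, seed = seed, ...)
}

channel_centers <- function(config) {
  (seq_len(config$n_channels) - 0.5) * config$channel_width
}

# Ideal delta prompt: all counts in the first channel.
delta_irf <- function(config) {
  decay_histogram(channel_centers(config),
                  c(config$peak_target, rep(0, config$n_channels - 1L)),
                  role = "prompt", label = "delta")
}

# Generating truths used across tests (1x sensor lifetime isotherm and
# intensity isotherm).
hill_truth <- function() hill_params(4.183, 3.983, 18e-12, 1.89)
langmuir_truth <- function() langmuir_params(34399, 23103, 30e-12)

# Biexponential template: fixed fast component 1 ns, equal amplitudes,
# dark-count baseline 50 counts/channel.
bi_template <- function(tau2 = 4.183, A = 50) {
  decay_params("bi", A = A, amplitudes = c(0.5, 0.5),
               lifetimes = c(1, tau2))
}
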