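#' Instrument configuration for photon-counting acquisition
#'
#' Bundles the TCSPC acquisition settings used throughout the package:
#' number of time channels, time calibration per channel, the target count of
#' the modal (peak) channel at which acquisition stops, and the shape of the
#' synthetic Gaussian prompt (instrument response function, IRF).
#'
#' Defaults mirror a single-photon-counting spectrometer collecting 1023
#' channels at 109.73 ps per channel to 10,000 counts in the peak channel.
#'
#' @param n_channels Integer number of time bins (>= 2).
#' @param channel_width Time calibration per channel in picoseconds (> 0).
#' @param peak_target Target counts in the modal channel (>= 1).
#' @param irf_fwhm Full width at half maximum of the Gaussian prompt, ps.
#' @param irf_center Prompt peak position, ps from the window start.
#' @param seed Integer RNG seed controlling all simulated noise.
#'
#' @return An object of class `tcspc_config` (a validated list).
#' @examples
#' cfg <- tcspc_config()
#' cfg$n_channels * cfg$channel_width / 1000  # acquisition window, ns
#' @export
tcspc_config <- function(n_channels = 1023L, channel_width = 109.73,
                         peak_target = 10000, irf_fwhm = 500,
                         irf_center = 2000, seed = 1L) {
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 2L) {
    stop("n_channels must be an integer >= 2", call. = FALSE)
  }
  stop_if_not_scalar_number(channel_width, "channel_width", positive = TRUE)
  stop_if_not_scalar_number(peak_target, "peak_target")
  if (peak_target < 1) stop("peak_target must be >= 1", call. = FALSE)
  stop_if_not_scalar_number(irf_fwhm, "irf_fwhm", positive = TRUE)
  stop_if_not_scalar_number(irf_center, "irf_center")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  structure(
    list(n_channels = n_channels, channel_width = channel_width,
         peak_target = peak_target, irf_fwhm = irf_fwhm,
         irf_center = irf_center, seed = seed),
    class = "tcspc_config"
  )
}

#' @export
print.tcspc_config <- function(x, ...) {
  cat("TCSPC instrument configuration\n")
  cat(sprintf("  channels     : %d x %.2f ps (window %.1f ns)\n",
              x$n_channels, x$channel_width,
              x$n_channels * x$channel_width / 1000))
  cat(sprintf("  peak target  : %g counts\n", x$peak_target))
  cat(sprintf("  prompt       : Gaussian, FWHM %.0f ps, center %.0f ps\n",
              x$irf_fwhm, x$irf_center))
  cat(sprintf("  seed         : %d\n", x$seed))
  invisible(x)
}

# Channel-center times in ps for a config (channel i covers [i*w, (i+1)*w),
# i = 0 .. n-1; centers at (i + 1/2) * w).
channel_times <- function(config) {
  (seq_len(config$n_channels) - 0.5) * config$channel_width
}

#' Decay-model parameters
#'
#' Parameters of the mono- or biexponential fluorescence decay model.
#' The monoexponential model is `I(t) = I0 * exp(-t / tau)` (plus a constant
#' background `A` when fitted); the biexponential model is
#' `I(t) = A + B1 * exp(-t / tau1) + B2 * exp(-t / tau2)`.
#' By convention `tau1 <= tau2`: `tau2` is the slow, binding-responsive
#' component and `tau1` the fast non-specific component.
#'
#' @param kind `"mono"` or `"bi"`.
#' @param A Constant background, counts per channel (>= 0).
#' @param amplitudes Pre-exponential amplitude(s): `I0` for mono, `c(B1, B2)`
#'   for bi; all >= 0.
#' @param lifetimes Lifetime(s) in ns: `tau` for mono, `c(tau1, tau2)` for bi;
#'   all > 0, with `tau1 <= tau2` enforced by swapping components.
#'
#' @return An object of class `decay_params`.
#' @examples
#' decay_params("bi", A = 10, amplitudes = c(1, 1), lifetimes = c(1, 4.183))
#' @export
decay_params <- function(kind = c("mono", "bi"), A = 0, amplitudes,
                         lifetimes) {
  kind <- match.arg(kind)
  stop_if_not_scalar_number(A, "A", nonnegative = TRUE)
  np <- if (kind == "mono") 1L else 2L
  if (length(amplitudes) != np || length(lifetimes) != np) {
    stop(sprintf("'%s' model needs %d amplitude(s) and %d lifetime(s)",
                 kind, np, np), call. = FALSE)
  }
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0)) {
    stop("amplitudes must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(lifetimes)) || any(lifetimes <= 0)) {
    stop("lifetimes must be finite and > 0 (ns)", call. = FALSE)
  }
  if (kind == "bi" && lifetimes[1] > lifetimes[2]) {
    ord <- order(lifetimes)
    lifetimes <- lifetimes[ord]
    amplitudes <- amplitudes[ord]
  }
  structure(
    list(kind = kind, A = A, amplitudes = unname(amplitudes),
         lifetimes = unname(lifetimes)),
    class = "decay_params"
  )
}

#' @export
print.decay_params <- function(x, ...) {
  if (x$kind == "mono") {
    cat(sprintf("Monoexponential decay: I0 = %.4g, tau = %.4g ns, A = %.4g\n",
                x$amplitudes[1], x$lifetimes[1], x$A))
  } else {
    cat(sprintf(
      "Biexponential decay: A = %.4g, B1 = %.4g (tau1 = %.4g ns), B2 = %.4g (tau2 = %.4g ns)\n",
      x$A, x$amplitudes[1], x$lifetimes[1], x$amplitudes[2], x$lifetimes[2]))
  }
  invisible(x)
}

# Background-free model decay evaluated at times (ps); lifetimes are ns.
eval_decay_model <- function(params, times_ps) {
  t_ns <- times_ps / 1000
  out <- numeric(length(times_ps))
  for (k in seq_along(params$lifetimes)) {
    out <- out + params$amplitudes[k] * exp(-t_ns / params$lifetimes[k])
  }
  out
}

#' Hill isotherm parameters
#'
#' Parameters of the baseline Hill model used for lifetime titrations:
#' `tau2(x) = tau2_0 + (tau2_max - tau2_0) * x^n / (EC50^n + x^n)`,
#' where `x` is the analyte concentration (molar). For a quenching sensor
#' `tau2_max < tau2_0` and the response decreases with concentration.
#'
#' @param tau2_0 Zero-analyte lifetime, ns.
#' @param tau2_max Saturation lifetime, ns.
#' @param EC50 Half-saturation concentration (apparent dissociation constant
#'   K_app), molar (> 0).
#' @param n Hill coefficient (> 0).
#' @return An object of class `hill_params`.
#' @examples
#' hill_params(4.183, 3.983, 18e-12, 1.89)
#' @export
hill_params <- function(tau2_0, tau2_max, EC50, n = 1) {
  stop_if_not_scalar_number(tau2_0, "tau2_0")
  stop_if_not_scalar_number(tau2_max, "tau2_max")
  stop_if_not_scalar_number(EC50, "EC50", positive = TRUE)
  stop_if_not_scalar_number(n, "n", positive = TRUE)
  structure(list(tau2_0 = tau2_0, tau2_max = tau2_max, EC50 = EC50, n = n),
            class = "hill_params")
}

#' Langmuir isotherm parameters
#'
#' Parameters of the Langmuir binding model used for intensity titrations:
#' `y(x) = START + (END - START) * x / (k + x)`.
#'
#' @param START Response at zero analyte (e.g. rfu).
#' @param END Response at binding saturation.
#' @param k Half-saturation concentration (EC50 / apparent dissociation
#'   constant K_app), molar (> 0).
#' @return An object of class `langmuir_params`.
#' @examples
#' langmuir_params(34399, 23103, 30e-12)
#' @export
langmuir_params <- function(START, END, k) {
  stop_if_not_scalar_number(START, "START")
  stop_if_not_scalar_number(END, "END")
  stop_if_not_scalar_number(k, "k", positive = TRUE)
  structure(list(START = START, END = END, k = k), class = "langmuir_params")
}
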