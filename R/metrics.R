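#' Affinity constant from the apparent dissociation constant
#'
#' `K_aff = 1 / K_app`.
#'
#' @param K_app Apparent dissociation constant, molar (> 0).
#' @return Affinity constant, 1/molar.
#' @examples
#' affinity_constant(28e-12)  # ~3.57e10 M^-1
#' @export
affinity_constant <- function(K_app) {
  if (any(!is.finite(K_app)) || any(K_app <= 0)) {
    stop("K_app must be finite and > 0", call. = FALSE)
  }
  1 / K_app
}

#' Sensitivity at low concentration
#'
#' The lifetime-span-over-affinity figure of merit,
#' `|tau2_max - tau2_0| / K_app`, in ns per molar. Note this is the
#' conventional span/K definition, not the derivative of the Hill curve at
#' zero (which vanishes for Hill coefficient > 1).
#'
#' @param tau2_0,tau2_max Plateau lifetimes, ns (distinct).
#' @param K_app Apparent dissociation constant, molar (> 0).
#' @return Sensitivity, ns/M.
#' @examples
#' sensitivity_low_conc(4.183, 3.983, 28e-12)  # 7.14e9 ns/M
#' @export
sensitivity_low_conc <- function(tau2_0, tau2_max, K_app) {
  stop_if_not_scalar_number(tau2_0, "tau2_0", positive = TRUE)
  stop_if_not_scalar_number(tau2_max, "tau2_max", positive = TRUE)
  stop_if_not_scalar_number(K_app, "K_app", positive = TRUE)
  if (tau2_0 == tau2_max) stop("zero lifetime span", call. = FALSE)
  abs(tau2_max - tau2_0) / K_app
}

#' Limit of detection (3-sigma convention)
#'
#' `LOD = 3 * sigma_blank / sensitivity`.
#'
#' @param sigma_blank Standard deviation of replicate blank responses, ns
#'   (>= 0).
#' @param sensitivity Sensitivity at low concentration, ns/M (> 0).
#' @return Limit of detection, molar.
#' @examples
#' limit_of_detection(0.003, 7.142857e9) * 1e12  # pM
#' @export
limit_of_detection <- function(sigma_blank, sensitivity) {
  stop_if_not_scalar_number(sigma_blank, "sigma_blank", nonnegative = TRUE)
  stop_if_not_scalar_number(sensitivity, "sensitivity", positive = TRUE)
  3 * sigma_blank / sensitivity
}

#' Linear dynamic range of a Hill isotherm
#'
#' Concentrations at which the normalized response reaches `lo_frac` and
#' `hi_frac` of the transition (default 10% and 90%):
#' `x_f = EC50 * (f / (1 - f))^(1 / n)`. The endpoints bracket EC50 and
#' their geometric mean equals EC50 exactly.
#'
#' @param p A [hill_params()], or a converged Hill `isotherm_fit`.
#' @param lo_frac,hi_frac Response fractions in (0, 1), `lo_frac < hi_frac`.
#' @return Named numeric `c(low, high)`, molar.
#' @examples
#' linear_dynamic_range(hill_params(4.183, 3.983, 18e-12, 1.89)) * 1e12
#' @export
linear_dynamic_range <- function(p, lo_frac = 0.10, hi_frac = 0.90) {
  if (inherits(p, "isotherm_fit")) {
    if (p$model != "hill") stop("need a Hill fit", call. = FALSE)
    if (!p$converged) {
      stop("refusing a non-converged isotherm fit", call. = FALSE)
    }
    p <- p$params
  }
  stopifnot(inherits(p, "hill_params"))
  if (!(lo_frac > 0 && hi_frac < 1 && lo_frac < hi_frac)) {
    stop("need 0 < lo_frac < hi_frac < 1", call. = FALSE)
  }
  xf <- function(f) p$EC50 * (f / (1 - f))^(1 / p$n)
  c(low = xf(lo_frac), high = xf(hi_frac))
}

#' Fluorophore calibration line
#'
#' Linear emission-intensity calibration for free fluorophore,
#' `y (rfu) = slope * [fluorophore, nM] + intercept`.
#'
#' @param slope rfu per nM (non-zero).
#' @param intercept rfu.
#' @return An object of class `calibration_line`.
#' @examples
#' calibration_line(0.82, -0.12)
#' @export
calibration_line <- function(slope, intercept = 0) {
  stop_if_not_scalar_number(slope, "slope")
  if (slope == 0) stop("slope must be non-zero", call. = FALSE)
  stop_if_not_scalar_number(intercept, "intercept")
  structure(list(slope = slope, intercept = intercept),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("calibration line: y (rfu) = %.4g x [nM] %+.4g\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Fluorophore concentration from emission intensity
#'
#' Inverts a [calibration_line()]: `x = (y - intercept) / slope`, nM.
#'
#' @param cal A [calibration_line()].
#' @param y Emission intensity, rfu.
#' @return Concentration(s), nM.
#' @examples
#' fluorophore_conc_from_intensity(calibration_line(0.82, -0.12), 0.7)
#' @export
fluorophore_conc_from_intensity <- function(cal, y) {
  stopifnot(inherits(cal, "calibration_line"))
  (y - cal$intercept) / cal$slope
}

#' Fluorophore incorporation percentage
#'
#' `100 * incorporated / added`, both in pmol per mg of polymer.
#'
#' @param added Fluorophore added to polymerization, pmol/mg (> 0).
#' @param incorporated Fluorophore incorporated, pmol/mg (>= 0).
#' @return Percentage.
#' @examples
#' incorporation_percent(6500, 3380)  # 52
#' @export
incorporation_percent <- function(added, incorporated) {
  stop_if_not_scalar_number(added, "added", positive = TRUE)
  stop_if_not_scalar_number(incorporated, "incorporated", nonnegative = TRUE)
  if (incorporated > added) {
    warning("incorporated exceeds added (physically suspect)", call. = FALSE)
  }
  100 * incorporated / added
}

#' Assemble the sensor figures of merit
#'
#' Composes the apparent dissociation constant, affinity constant,
#' sensitivity, limit of detection, and linear dynamic range from a
#' converged Hill isotherm fit and blank statistics.
#'
#' The blank lifetime standard deviation is taken from `blank_tau2`
#' (>= 2 replicate blank measurements) or supplied explicitly via
#' `blank_sd`; a single blank replicate without an explicit override is
#' refused, as is a non-converged isotherm fit.
#'
#' @param hill_fit A converged Hill `isotherm_fit` (or a [hill_params()]
#'   for metric computation from known parameters).
#' @param blank_tau2 Optional numeric vector of replicate blank lifetimes,
#'   ns (length >= 2).
#' @param blank_sd Optional explicit blank standard deviation, ns; overrides
#'   `blank_tau2`.
#' @param decay_chi2 Optional reduced chi-square of the underlying decay
#'   fit, carried through for reporting.
#' @param ldr_fracs Fractions for the linear dynamic range.
#' @return An object of class `sensor_metrics` with fields `K_app` (M),
#'   `K_aff` (1/M), `sensitivity` (ns/M), `LOD` (M), `ldr_low`, `ldr_high`
#'   (M), `chi2_red_decay`, plus the plateau lifetimes.
#' @examples
#' p <- hill_params(4.183, 3.983, 18e-12, 1.89)
#' assemble_metrics(p, blank_sd = 0.003)
#' @export
assemble_metrics <- function(hill_fit, blank_tau2 = NULL, blank_sd = NULL,
                             decay_chi2 = NA_real_,
                             ldr_fracs = c(0.10, 0.90)) {
  if (inherits(hill_fit, "isotherm_fit")) {
    if (hill_fit$model != "hill") {
      stop("metrics require a Hill isotherm fit", call. = FALSE)
    }
    if (!hill_fit$converged) {
      stop("refusing a non-converged isotherm fit (n.a.)", call. = FALSE)
    }
    p <- hill_fit$params
  } else if (inherits(hill_fit, "hill_params")) {
    p <- hill_fit
  } else {
    stop("hill_fit must be an isotherm_fit or hill_params", call. = FALSE)
  }
  if (is.null(blank_sd)) {
    if (is.null(blank_tau2) || length(blank_tau2) < 2L) {
      stop("blank sd unavailable: supply >= 2 replicate blank lifetimes or an explicit blank_sd override",
           call. = FALSE)
    }
    blank_sd <- sd(blank_tau2)
  }
  stop_if_not_scalar_number(blank_sd, "blank_sd", nonnegative = TRUE)
  K_app <- p$EC50
  S <- sensitivity_low_conc(p$tau2_0, p$tau2_max, K_app)
  ldr <- linear_dynamic_range(p, ldr_fracs[1], ldr_fracs[2])
  structure(
    list(K_app = K_app, K_aff = affinity_constant(K_app),
         sensitivity = S, LOD = limit_of_detection(blank_sd, S),
         ldr_low = unname(ldr["low"]), ldr_high = unname(ldr["high"]),
         tau2_0 = p$tau2_0, tau2_max = p$tau2_max, hill_n = p$n,
         blank_sd = blank_sd, chi2_red_decay = decay_chi2),
    class = "sensor_metrics"
  )
}

#' @export
print.sensor_metrics <- function(x, ...) {
  cat("Lifetime nanosensor figures of merit\n")
  cat(sprintf("  tau2_0 / tau2_max     : %.3f / %.3f ns\n",
              x$tau2_0, x$tau2_max))
  cat(sprintf("  K_app                 : %.3g pM\n", x$K_app * 1e12))
  cat(sprintf("  K_aff                 : %.3g M^-1\n", x$K_aff))
  cat(sprintf("  sensitivity (low conc): %.3g ns/M\n", x$sensitivity))
  cat(sprintf("  LOD (3 sigma)         : %.3g pM  (blank sd %.4g ns)\n",
              x$LOD * 1e12, x$blank_sd))
  cat(sprintf("  linear dynamic range  : %.3g - %.3g pM (10-90%%)\n",
              x$ldr_low * 1e12, x$ldr_high * 1e12))
  if (is.finite(x$chi2_red_decay)) {
    cat(sprintf("  decay fit chi2_red    : %.3f\n", x$chi2_red_decay))
  }
  invisible(x)
}

#' @export
as.data.frame.sensor_metrics <- function(x, ...) {
  data.frame(
    metric = c("tau2_0_ns", "tau2_max_ns", "K_app_pM", "K_aff_per_M",
               "sensitivity_ns_per_M", "LOD_pM", "ldr_low_pM", "ldr_high_pM",
               "blank_sd_ns", "chi2_red_decay"),
    value = c(x$tau2_0, x$tau2_max, x$K_app * 1e12, x$K_aff, x$sensitivity,
              x$LOD * 1e12, x$ldr_low * 1e12, x$ldr_high * 1e12,
              x$blank_sd, x$chi2_red_decay)
  )
}
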