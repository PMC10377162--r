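#' Evaluate the Langmuir binding model
#'
#' `y(x) = START + (END - START) * x / (k + x)`.
#'
#' @param p A [langmuir_params()] (or named list with START, END, k).
#' @param x Analyte concentration(s), molar (>= 0).
#' @return Predicted response(s).
#' @examples
#' predict_langmuir(langmuir_params(34399, 23103, 30e-12), 30e-12)  # midpoint
#' @export
predict_langmuir <- function(p, x) {
  if (any(x < 0)) stop("concentrations must be >= 0", call. = FALSE)
  p$START + (p$END - p$START) * x / (p$k + x)
}

#' Evaluate the Hill binding model
#'
#' The baseline form used throughout the package,
#' `tau2(x) = tau2_0 + (tau2_max - tau2_0) * x^n / (EC50^n + x^n)`,
#' which plateaus at `tau2_0` for `x -> 0` and at `tau2_max` at saturation.
#' With `baseline = FALSE` the bare variant
#' `tau2(x) = tau2_max * x^n / (EC50^n + x^n)` (which is zero at `x = 0`)
#' is evaluated instead; it is retained only as a documented variant and is
#' not used for fitting.
#'
#' @param p A [hill_params()].
#' @param x Analyte concentration(s), molar (>= 0).
#' @param baseline Use the baseline form (default `TRUE`).
#' @return Predicted lifetime(s), ns.
#' @examples
#' p <- hill_params(4.183, 3.983, 18e-12, 1.89)
#' predict_hill(p, 18e-12)  # midpoint: (4.183 + 3.983) / 2
#' @export
predict_hill <- function(p, x, baseline = TRUE) {
  if (any(x < 0)) stop("concentrations must be >= 0", call. = FALSE)
  # (x / EC50)^n is better conditioned than x^n / (EC50^n + x^n) at pM scales
  r <- (x / p$EC50)^p$n
  frac <- r / (1 + r)
  frac[x == 0] <- 0
  if (baseline) p$tau2_0 + (p$tau2_max - p$tau2_0) * frac
  else p$tau2_max * frac
}

#' Normalized sensor response
#'
#' Fractional progress of an observed lifetime along the fitted transition,
#' `(tau2_0 - tau2_obs) / (tau2_0 - tau2_max)`, reported as a percentage.
#' 0% at the zero-analyte plateau, 100% at saturation; noisy observations
#' may fall outside `[0, 100]`.
#'
#' @param p A [hill_params()].
#' @param tau2_obs Observed lifetime(s), ns.
#' @return Percentage(s).
#' @export
normalized_response <- function(p, tau2_obs) {
  span <- p$tau2_0 - p$tau2_max
  if (abs(span) < 1e-12) {
    stop("degenerate span: tau2_0 == tau2_max", call. = FALSE)
  }
  100 * (p$tau2_0 - tau2_obs) / span
}

## ---------------------------------------------------------------------------

# Pooled replicate sd of a titration series (NA when no group has >= 2 reps).
pooled_sd <- function(series) {
  s <- series$summary
  ok <- !is.na(s$sd) & s$n >= 2L
  if (!any(ok)) return(NA_real_)
  sqrt(sum(s$sd[ok]^2 * (s$n[ok] - 1)) / sum(s$n[ok] - 1))
}

#' Fit a binding isotherm to a titration series
#'
#' Nonlinear least squares of the Langmuir model (intensity titrations) or
#' the baseline Hill model (lifetime titrations) against replicate
#' responses. Fitting is performed on log10-concentration internally for
#' conditioning; the half-saturation constant is reported in linear molar
#' units. The fit is unweighted by default (the convention of common
#' curve-fitting software, and the calibrated choice when replicate noise is
#' homoscedastic); `weights = "variance"` uses inverse replicate variances
#' instead, when every concentration has at least two replicates. The Hill
#' coefficient is bounded to [0.2, 6]; decreasing responses (saturation
#' below baseline) are handled naturally.
#'
#' Non-convergence is a reported state, not an exception: a series whose
#' response span is smaller than twice the pooled replicate noise (flat
#' data), or for which the optimizer fails, yields `converged = FALSE`; the
#' sensor-metrics stage refuses such fits.
#'
#' @param series A [titration_series()] with >= 4 distinct concentrations.
#' @param model `"hill"` (requires lifetime responses) or `"langmuir"`
#'   (requires intensity responses).
#' @param weights `"none"` (default) or `"variance"` (inverse replicate
#'   variance per concentration).
#' @param n_bounds Bounds for the Hill coefficient.
#' @return An object of class `isotherm_fit`: `coefficients` (named vector:
#'   `tau2_0, tau2_max, EC50, n` or `START, END, k`), `stderr`, `r2_adj`,
#'   `converged`, `params` ([hill_params()]/[langmuir_params()]),
#'   `fitted`, `residuals`, `series`.
#' @examples
#' truth <- hill_params(4.183, 3.983, 18e-12, 1.89)
#' ser <- simulate_response_titration(truth, default_concentrations(),
#'                                    noise_sd = 0, replicates = 3, seed = 1)
#' fit <- isotherm_fit(ser, "hill")
#' coef(fit)
#' @seealso [fit_hill()], [fit_langmuir()]
#' @export
isotherm_fit <- function(series, model = c("hill", "langmuir"),
                         weights = c("none", "variance"),
                         n_bounds = c(0.2, 6)) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  stopifnot(inherits(series, "titration_series"))
  if (nrow(series$summary) < 4L) {
    stop("isotherm fitting needs >= 4 distinct concentrations", call. = FALSE)
  }
  want_kind <- if (model == "hill") "lifetime_tau2" else "intensity"
  if (series$response_kind != want_kind) {
    stop(sprintf("%s model expects %s responses (series has %s)",
                 model, want_kind, series$response_kind), call. = FALSE)
  }
  x <- series$data$concentration
  y <- series$data$response
  smry <- series$summary

  # warn (but proceed) when group means are non-monotone beyond noise
  dm <- diff(smry$mean)
  noise0 <- pooled_sd(series)
  lim0 <- if (is.na(noise0)) 0 else 2 * noise0
  if (any(dm > lim0) && any(dm < -lim0)) {
    warning("titration is non-monotone beyond replicate noise; fit proceeds",
            call. = FALSE)
  }

  # optional per-observation weights: inverse replicate variance
  all_rep <- all(smry$n >= 2L) && all(!is.na(smry$sd)) && all(smry$sd > 0)
  wts <- if (weights == "variance" && all_rep) {
    1 / (smry$sd[match(x, smry$concentration)]^2)
  } else {
    rep(1, length(y))
  }

  lx <- log10(x)
  lo_mean <- smry$mean[1]
  hi_mean <- smry$mean[nrow(smry)]
  mid <- (lo_mean + hi_mean) / 2
  # starting log10-EC50: concentration whose group mean is nearest midpoint
  k0 <- log10(smry$concentration[which.min(abs(smry$mean - mid))])

  if (model == "hill") {
    start <- c(p1 = lo_mean, p2 = hi_mean, lk = k0, n = 1)
    lower <- c(-Inf, -Inf, min(lx) - 6, n_bounds[1])
    upper <- c(Inf, Inf, max(lx) + 6, n_bounds[2])
    fn <- function(p) {
      r <- 10^(p[4] * (lx - p[3]))
      mu <- p[1] + (p[2] - p[1]) * r / (1 + r)
      (mu - y) * sqrt(wts)
    }
  } else {
    start <- c(p1 = lo_mean, p2 = hi_mean, lk = k0)
    lower <- c(-Inf, -Inf, min(lx) - 6)
    upper <- c(Inf, Inf, max(lx) + 6)
    fn <- function(p) {
      r <- 10^(lx - p[3])
      mu <- p[1] + (p[2] - p[1]) * r / (1 + r)
      (mu - y) * sqrt(wts)
    }
  }

  res <- tryCatch(
    minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper, fn = fn,
      control = minpack.lm::nls.lm.control(maxiter = 500L, ftol = 1e-15,
                                           ptol = 1e-13, gtol = 0,
                                           maxfev = 100000L)),
    error = function(e) e
  )

  failed <- inherits(res, "error") || !res$info %in% c(1L, 2L, 3L, 4L)
  p <- if (inherits(res, "error")) start else setNames(res$par, names(start))

  mu <- y + fn(p) / sqrt(wts)
  resid <- y - mu
  n_obs <- length(y)
  n_par <- length(p)
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  r2_adj <- if (!is.na(r2) && n_obs > n_par + 1) {
    1 - (1 - r2) * (n_obs - 1) / (n_obs - n_par - 1)
  } else NA_real_

  # back-transform and delta-method stderr for the half-saturation constant
  k_lin <- 10^p[["lk"]]
  se <- setNames(rep(NA_real_, n_par), names(start))
  cv <- NULL
  if (!failed) {
    cv <- tryCatch(solve(res$hessian) * res$deviance / (n_obs - n_par),
                   error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  se_k <- unname(se["lk"]) * log(10) * k_lin

  # non-convergence as a reported state:
  #  - flat data: response span below twice the pooled replicate noise
  #  - unidentifiable transition: fitted span insignificant, or the
  #    half-saturation constant uncertain by more than a decade
  span_data <- max(smry$mean) - min(smry$mean)
  noise <- pooled_sd(series)
  flat <- !is.na(noise) && noise > 0 && span_data < 2 * noise
  flat <- flat || (!is.na(noise) && noise > 0 && abs(p[2] - p[1]) < 2 * noise)
  if (!is.null(cv)) {
    se_span <- sqrt(max(cv[1, 1] + cv[2, 2] - 2 * cv[1, 2], 0))
    if (se_span > 0 && abs(p[2] - p[1]) < 2 * se_span) flat <- TRUE
    if (is.finite(se["lk"]) && se[["lk"]] > 1) flat <- TRUE
  } else if (!failed) {
    # singular curvature: parameters not jointly identifiable
    flat <- TRUE
  }
  # half-saturation pinned at its box bound: no interior optimum found
  if (p[["lk"]] <= lower[3] + 1e-8 || p[["lk"]] >= upper[3] - 1e-8) {
    flat <- TRUE
  }
  converged <- !failed && !flat

  if (model == "hill") {
    coefs <- c(tau2_0 = unname(p["p1"]), tau2_max = unname(p["p2"]),
               EC50 = unname(k_lin), n = unname(p["n"]))
    stderr <- c(tau2_0 = unname(se["p1"]), tau2_max = unname(se["p2"]),
                EC50 = se_k, n = unname(se["n"]))
    params <- tryCatch(
      hill_params(coefs[["tau2_0"]], coefs[["tau2_max"]], coefs[["EC50"]],
                  coefs[["n"]]),
      error = function(e) NULL)
  } else {
    coefs <- c(START = unname(p["p1"]), END = unname(p["p2"]),
               k = unname(k_lin))
    stderr <- c(START = unname(se["p1"]), END = unname(se["p2"]), k = se_k)
    params <- tryCatch(
      langmuir_params(coefs[["START"]], coefs[["END"]], coefs[["k"]]),
      error = function(e) NULL)
  }
  if (!converged) {
    warning("isotherm fit did not converge (flat or uninformative data)",
            call. = FALSE)
  }

  structure(
    list(model = model, coefficients = coefs, stderr = stderr,
         r2_adj = r2_adj, converged = converged, params = params,
         fitted = mu, residuals = resid, weights = wts, series = series,
         n_obs = n_obs),
    class = "isotherm_fit"
  )
}

#' Fit the Langmuir model to an intensity titration
#'
#' @param series A [titration_series()] with `response_kind = "intensity"`.
#' @param ... Passed to [isotherm_fit()].
#' @return An `isotherm_fit` object.
#' @export
fit_langmuir <- function(series, ...) isotherm_fit(series, "langmuir", ...)

#' Fit the baseline Hill model to a lifetime titration
#'
#' @param series A [titration_series()] with
#'   `response_kind = "lifetime_tau2"`.
#' @param ... Passed to [isotherm_fit()].
#' @return An `isotherm_fit` object.
#' @export
fit_hill <- function(series, ...) isotherm_fit(series, "hill", ...)

## S3 methods ----------------------------------------------------------------

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("%s isotherm fit%s\n",
              if (x$model == "hill") "Hill (baseline)" else "Langmuir",
              if (x$converged) "" else "  [NOT CONVERGED: n.a.]"))
  tab <- data.frame(estimate = x$coefficients, std.error = x$stderr)
  print(format(tab, digits = 5))
  cat(sprintf("adjusted R-squared: %.4f  (%d observations)\n",
              x$r2_adj, x$n_obs))
  invisible(x)
}

#' @export
summary.isotherm_fit <- function(object, ...) {
  print(object)
  hs <- object$coefficients[[if (object$model == "hill") "EC50" else "k"]]
  cat(sprintf("half-saturation (EC50 / K_app): %.4g M (%.4g pM)\n",
              hs, hs * 1e12))
  invisible(object)
}

#' @export
coef.isotherm_fit <- function(object, ...) object$coefficients

#' @export
fitted.isotherm_fit <- function(object, ...) object$fitted

#' @export
residuals.isotherm_fit <- function(object, ...) object$residuals

#' @export
predict.isotherm_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$series$data$concentration
       else if (is.list(newdata)) newdata$concentration
       else newdata
  if (object$model == "hill") predict_hill(object$params, x)
  else predict_langmuir(object$params, x)
}

#' @export
plot.isotherm_fit <- function(x, ...) {
  d <- x$series$data
  grid <- 10^seq(log10(min(d$concentration)) - 0.3,
                 log10(max(d$concentration)) + 0.3, length.out = 200)
  yl <- if (x$model == "hill") "tau2 (ns)" else "intensity (rfu)"
  plot(d$concentration, d$response, log = "x",
       xlab = "analyte concentration (M)", ylab = yl,
       main = sprintf("%s isotherm", x$model), ...)
  lines(grid, predict(x, grid), col = 2, lwd = 1.5)
  invisible(x)
}
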