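#' Forward convolution of a decay model with the instrument response
#'
#' Computes the expected counts per channel for iterative reconvolution:
#' the discrete linear convolution of the (unit-normalized, optionally
#' sub-channel-shifted) IRF with the exponential decay model evaluated at
#' channel centers, truncated to the acquisition window, plus the constant
#' background `A`. The expectation is linear in each amplitude and in `A`.
#'
#' @param irf Prompt [decay_histogram()]; normalized internally to unit sum.
#' @param params A [decay_params()].
#' @param shift Sub-channel IRF shift in ps (positive = later), implemented
#'   by linear interpolation; must stay within ±5 channels.
#' @return Numeric vector of expected counts per channel.
#' @examples
#' cfg <- tcspc_config(n_channels = 64)
#' irf <- make_irf(cfg)
#' convolve_model(irf, decay_params("mono", amplitudes = 1, lifetimes = 4))[1:5]
#' @export
convolve_model <- function(irf, params, shift = 0) {
  stopifnot(inherits(irf, "decay_histogram"), inherits(params, "decay_params"))
  w <- irf_weights(irf)   # errors on all-zero IRF
  n <- length(w)
  cw <- irf$channel_width
  if (abs(shift) > 5 * cw) {
    stop("IRF shift exceeds +/-5 channels", call. = FALSE)
  }
  w <- shift_weights(w, shift / cw)
  d <- eval_decay_model(params, irf$times)
  out <- convolve(w, rev(d), type = "open")[seq_len(n)]
  pmax(out, 0) + params$A
}

# Shift a weight vector by s channels (fractional, linear interpolation).
# Mass shifted beyond the window is dropped.
shift_weights <- function(w, s) {
  if (s == 0) return(w)
  n <- length(w)
  i0 <- floor(s)
  f <- s - i0
  idx <- seq_len(n)
  lag1 <- idx - i0       # source index for weight (1 - f)
  lag2 <- idx - i0 - 1L  # source index for weight f
  g1 <- ifelse(lag1 >= 1L & lag1 <= n, w[pmin(pmax(lag1, 1L), n)], 0)
  g2 <- ifelse(lag2 >= 1L & lag2 <= n, w[pmin(pmax(lag2, 1L), n)], 0)
  (1 - f) * g1 + f * g2
}

#' Reduced chi-square of a fitted decay
#'
#' Neyman-weighted goodness of fit,
#' `sum((obs - exp)^2 / max(obs, 1)) / (N_used - p)`, the convention of
#' standard TCSPC analysis software. By default no channels are excluded;
#' `min_counts` optionally restricts the sum to channels with at least that
#' many observed counts.
#'
#' @param observed,expected Count vectors of equal length.
#' @param n_free_params Number of free fit parameters `p` (< N_used).
#' @param min_counts Optional inclusion threshold on observed counts.
#' @return The reduced chi-square (>= 0).
#' @examples
#' reduced_chi_square(c(100, 50, 25), c(100, 50, 25), 2)
#' @export
reduced_chi_square <- function(observed, expected, n_free_params,
                               min_counts = NULL) {
  if (length(observed) != length(expected)) {
    stop("observed and expected lengths differ", call. = FALSE)
  }
  use <- if (is.null(min_counts)) rep(TRUE, length(observed))
         else observed >= min_counts
  n_used <- sum(use)
  if (n_free_params >= n_used) {
    stop("n_free_params must be smaller than the number of channels used",
         call. = FALSE)
  }
  o <- observed[use]
  e <- expected[use]
  sum((o - e)^2 / pmax(o, 1)) / (n_used - n_free_params)
}

#' Initial parameter guess for a decay fit
#'
#' Heuristic starting values: background `A` from the mean of pre-peak
#' baseline channels; the tail lifetime from a log-linear regression on the
#' last 30% of post-peak channels with counts above `2 * A`; amplitudes from
#' the background-subtracted peak height. For the biexponential model the
#' guesses are `tau1 = tau_tail / 3`, `tau2 = tau_tail` with equal
#' amplitudes.
#'
#' @param decay A [decay_histogram()].
#' @param model `"mono"` or `"bi"`.
#' @return A [decay_params()].
#' @export
initial_guess <- function(decay, model = c("mono", "bi")) {
  model <- match.arg(model)
  stopifnot(inherits(decay, "decay_histogram"))
  counts <- decay$counts
  t_ns <- decay$times / 1000
  peak <- which.max(counts)
  # median over pre-peak channels: robust to the prompt rise leaking into
  # the tail of the baseline window
  baseline_idx <- seq_len(max(peak - 8L, 0L))
  A <- if (length(baseline_idx) >= 3L) median(counts[baseline_idx]) else 0
  # tail channels must sit clearly above background: twice the baseline,
  # and at least 1% of the background-subtracted peak height (a 2A cut
  # alone admits channels that are pure background noise when A is small)
  thresh <- max(2 * A, A + 0.01 * (counts[peak] - A), 1)
  # smooth before thresholding so isolated Poisson outliers in the
  # background cannot masquerade as decay tail
  sm <- stats::filter(counts, rep(1 / 9, 9), sides = 2)
  sm[is.na(sm)] <- counts[is.na(sm)]
  cand <- which(seq_along(counts) > peak & sm > thresh)
  n_tail <- ceiling(0.3 * length(cand))
  tail_idx <- tail(cand, n_tail)
  tail_idx <- tail_idx[counts[tail_idx] - A > 0]
  if (length(tail_idx) < 10L) {
    stop("histogram too sparse for an initial guess (tail has < 10 usable channels)",
         call. = FALSE)
  }
  fit <- lm(log(counts[tail_idx] - A) ~ t_ns[tail_idx])
  slope <- coef(fit)[2]
  if (!is.finite(slope) || slope >= 0) {
    stop("no decaying tail in histogram (flat or rising counts)",
         call. = FALSE)
  }
  tau_tail <- -1 / slope
  height <- max(counts[peak] - A, 1)
  if (model == "mono") {
    decay_params("mono", A = A, amplitudes = height, lifetimes = tau_tail)
  } else {
    decay_params("bi", A = A, amplitudes = c(height / 2, height / 2),
                 lifetimes = c(tau_tail / 3, tau_tail))
  }
}

# Invert a (near-)positive-definite J'J with diagonal preconditioning,
# falling back to a pseudo-inverse; returns NULL only for non-finite input.
robust_inverse <- function(H) {
  if (any(!is.finite(H))) return(NULL)
  d <- sqrt(diag(H))
  d[d <= 0 | !is.finite(d)] <- 1
  Hs <- H / outer(d, d)
  inv <- tryCatch(solve(Hs), error = function(e) NULL)
  if (is.null(inv)) {
    s <- svd(Hs)
    pos <- s$d > max(s$d) * 1e-12
    if (!any(pos)) return(NULL)
    inv <- s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  }
  inv / outer(d, d)
}

# Full parameter vector layout per model.
par_names <- function(model) {
  if (model == "mono") c("I0", "tau", "A", "shift")
  else c("A", "B1", "B2", "tau1", "tau2", "shift")
}

params_from_vector <- function(model, p) {
  if (model == "mono") {
    decay_params("mono", A = p[["A"]], amplitudes = p[["I0"]],
                 lifetimes = p[["tau"]])
  } else {
    # construct without the tau1<=tau2 swap: ordering handled post-fit
    structure(list(kind = "bi", A = p[["A"]],
                   amplitudes = c(p[["B1"]], p[["B2"]]),
                   lifetimes = c(p[["tau1"]], p[["tau2"]])),
              class = "decay_params")
  }
}

#' Fit a decay model by iterative reconvolution
#'
#' Fits the monoexponential model `I(t) = I0 * exp(-t/tau)` (plus background
#' `A`) or the biexponential model `I(t) = A + B1*exp(-t/tau1) +
#' B2*exp(-t/tau2)` to a photon-counting histogram by minimizing
#' Neyman-weighted least squares `sum((obs - exp)^2 / max(obs, 1))` (or the
#' Poisson C-statistic) over the free parameters, where the expectation is
#' the model convolved with the measured prompt ([convolve_model()]). A
#' sub-channel IRF shift is a free parameter by default.
#'
#' Any parameter can be held fixed via `fixed` (e.g. `fixed = list(tau1 = 1)`
#' to use a globally fixed fast component); fixed parameters get no standard
#' error. For the biexponential model the label convention `tau1 <= tau2` is
#' enforced by swapping components (with their amplitudes) after the fit.
#'
#' Non-convergence is a reported state (`converged = FALSE`), not an error.
#'
#' @param decay Decay [decay_histogram()].
#' @param irf Prompt [decay_histogram()] on the same time axis.
#' @param model `"mono"` or `"bi"`.
#' @param fixed Named list of parameters to fix at the given values; names
#'   among `I0, tau, A, shift` (mono) or `A, B1, B2, tau1, tau2, shift` (bi).
#' @param init Optional [decay_params()] or named vector of starting values;
#'   defaults to [initial_guess()].
#' @param objective `"neyman"` (default, weights `1/max(obs,1)`) or
#'   `"poisson"` (deviance residuals / C-statistic).
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return An object of class `decay_fit` with components `coefficients`
#'   (full named parameter vector), `stderr`, `fixed`, `params`
#'   ([decay_params()]), `chi2_red`, `fitted`, `residuals` (weighted),
#'   `shift` (ps), `converged`, `degenerate`, `n_iter`.
#' @examples
#' cfg <- tcspc_config(n_channels = 256, seed = 3)
#' irf <- make_irf(cfg)
#' truth <- decay_params("mono", A = 5, amplitudes = 1, lifetimes = 4)
#' d <- simulate_decay(truth, irf, cfg)
#' fit <- decay_fit(d, irf, model = "mono")
#' coef(fit)["tau"]
#' @seealso [fit_monoexponential()], [fit_biexponential()],
#'   [grid_oracle_fit()]
#' @export
decay_fit <- function(decay, irf, model = c("mono", "bi"), fixed = list(),
                      init = NULL, objective = c("neyman", "poisson"),
                      max_iter = 500L) {
  model <- match.arg(model)
  objective <- match.arg(objective)
  stopifnot(inherits(decay, "decay_histogram"),
            inherits(irf, "decay_histogram"))
  if (length(decay$counts) != length(irf$counts) ||
      abs(decay$channel_width - irf$channel_width) >
        1e-6 * decay$channel_width) {
    stop("decay and irf do not share the same time axis", call. = FALSE)
  }
  nm <- par_names(model)
  if (length(fixed)) {
    bad <- setdiff(names(fixed), nm)
    if (length(bad)) {
      stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  obs <- decay$counts
  cw <- decay$channel_width
  window_ns <- length(obs) * cw / 1000

  # starting values
  if (is.null(init)) {
    init <- initial_guess(decay, model)
  }
  start <- if (inherits(init, "decay_params")) {
    if (init$kind != model) stop("init model kind mismatch", call. = FALSE)
    if (model == "mono") {
      c(I0 = init$amplitudes[1], tau = init$lifetimes[1], A = init$A,
        shift = 0)
    } else {
      c(A = init$A, B1 = init$amplitudes[1], B2 = init$amplitudes[2],
        tau1 = init$lifetimes[1], tau2 = init$lifetimes[2], shift = 0)
    }
  } else {
    full <- setNames(rep(NA_real_, length(nm)), nm)
    full["shift"] <- 0
    full[names(init)] <- unlist(init)
    if (any(is.na(full))) {
      stop("incomplete init vector: missing ",
           paste(nm[is.na(full)], collapse = ", "), call. = FALSE)
    }
    full
  }
  for (f in names(fixed)) start[f] <- fixed[[f]]

  lower <- setNames(rep(0, length(nm)), nm)
  upper <- setNames(rep(Inf, length(nm)), nm)
  tau_nm <- intersect(nm, c("tau", "tau1", "tau2"))
  lower[tau_nm] <- cw / 10 / 1000
  upper[tau_nm] <- 10 * window_ns
  lower["shift"] <- -5 * cw
  upper["shift"] <- 5 * cw
  start <- pmin(pmax(start, lower), upper)

  free <- setdiff(nm, names(fixed))
  if (length(free) == 0L) stop("no free parameters", call. = FALSE)
  wts <- 1 / pmax(obs, 1)

  resid_fn <- function(pfree) {
    p <- start
    p[free] <- pfree
    e <- convolve_model(irf, params_from_vector(model, p),
                        shift = p[["shift"]])
    if (objective == "neyman") {
      (e - obs) * sqrt(wts)
    } else {
      e <- pmax(e, 1e-12)
      dev <- 2 * (e - obs + ifelse(obs > 0, obs * log(obs / e), 0))
      sign(obs - e) * sqrt(pmax(dev, 0))
    }
  }

  res <- tryCatch(
    minpack.lm::nls.lm(
      par = start[free], lower = lower[free], upper = upper[free],
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = as.integer(max_iter), ftol = 1e-14, ptol = 1e-12,
        gtol = 0, maxfev = 100000L)),
    error = function(e) e
  )

  if (inherits(res, "error")) {
    fit_par <- start
    converged <- FALSE
    n_iter <- 0L
    hess <- NULL
    message_txt <- conditionMessage(res)
  } else {
    fit_par <- start
    fit_par[free] <- res$par
    converged <- res$info %in% c(1L, 2L, 3L, 4L)
    n_iter <- res$niter
    hess <- res$hessian
    message_txt <- res$message
  }

  expected <- convolve_model(irf, params_from_vector(model, fit_par),
                             shift = fit_par[["shift"]])
  p_free <- length(free)
  chi2 <- reduced_chi_square(obs, expected, p_free)

  stderr <- setNames(rep(NA_real_, length(nm)), nm)
  if (!is.null(hess)) {
    cv <- robust_inverse(hess)
    if (!is.null(cv)) {
      stderr[free] <- sqrt(pmax(diag(cv) * chi2, 0))
    }
  }

  degenerate <- FALSE
  if (model == "bi") {
    amp_collapse_frac <- 0.05
    tau_gap_frac <- 0.10
    # enforce tau1 <= tau2 labelling by swapping components; a fixed
    # lifetime keeps its label (the fixed mask must stay meaningful), and a
    # free tau2 ending up below a fixed tau1 is a collapsed fit
    tau_fixed <- intersect(names(fixed), c("tau1", "tau2"))
    if (fit_par[["tau1"]] > fit_par[["tau2"]]) {
      if (length(tau_fixed) == 0L) {
        fit_par[c("tau1", "tau2")] <- fit_par[c("tau2", "tau1")]
        fit_par[c("B1", "B2")] <- fit_par[c("B2", "B1")]
        stderr[c("tau1", "tau2")] <- stderr[c("tau2", "tau1")]
        stderr[c("B1", "B2")] <- stderr[c("B2", "B1")]
      } else {
        degenerate <- TRUE
      }
    }
    amp <- fit_par[c("B1", "B2")]
    if (converged &&
        (min(amp) < amp_collapse_frac * max(amp) ||
         abs(fit_par[["tau2"]] - fit_par[["tau1"]]) <
           tau_gap_frac * fit_par[["tau2"]])) {
      degenerate <- TRUE
      warning("degenerate biexponential fit: one component collapsed (data may be monoexponential)",
              call. = FALSE)
    }
  }
  if (!converged) {
    warning("decay fit did not converge; parameters flagged unreliable",
            call. = FALSE)
  }

  structure(
    list(model = model, coefficients = fit_par, stderr = stderr,
         fixed = names(fixed),
         params = params_from_vector(model, fit_par),
         chi2_red = chi2, fitted = expected,
         residuals = (obs - expected) * sqrt(wts),
         shift = unname(fit_par[["shift"]]),
         converged = converged, degenerate = degenerate,
         n_iter = n_iter, objective = objective, message = message_txt,
         data = decay, irf = irf),
    class = "decay_fit"
  )
}

#' Fit the monoexponential decay model by reconvolution
#'
#' Convenience wrapper around [decay_fit()] with `model = "mono"`.
#'
#' @inheritParams decay_fit
#' @return A `decay_fit` object.
#' @export
fit_monoexponential <- function(decay, irf, init = NULL, fixed = list(),
                                objective = c("neyman", "poisson")) {
  decay_fit(decay, irf, model = "mono", fixed = fixed, init = init,
            objective = match.arg(objective))
}

#' Fit the biexponential decay model by reconvolution
#'
#' Convenience wrapper around [decay_fit()] with `model = "bi"`. The fast
#' component `tau1` can be clamped to a globally fixed value (e.g. the value
#' obtained from a blank fit) via `fixed_tau1`.
#'
#' @inheritParams decay_fit
#' @param fixed_tau1 Optional fixed value of `tau1` in ns (> 0).
#' @return A `decay_fit` object.
#' @export
fit_biexponential <- function(decay, irf, fixed_tau1 = NULL, init = NULL,
                              fixed = list(),
                              objective = c("neyman", "poisson")) {
  if (!is.null(fixed_tau1)) {
    stop_if_not_scalar_number(fixed_tau1, "fixed_tau1", positive = TRUE)
    fixed$tau1 <- fixed_tau1
  }
  decay_fit(decay, irf, model = "bi", fixed = fixed, init = init,
            objective = match.arg(objective))
}

#' Brute-force grid oracle for the reconvolution objective
#'
#' Exhaustive search over a lifetime grid, solving amplitudes and background
#' in closed form by (weighted) linear least squares at each node — the
#' expectation is linear in `I0`/`B1`/`B2`/`A` for fixed lifetimes. Returns
#' the grid-global minimizer of the same Neyman objective as [decay_fit()].
#' Intended as an independent verification oracle for the iterative
#' optimizer, not for routine fitting.
#'
#' @param decay,irf As in [decay_fit()].
#' @param tau_grid Numeric vector (mono) or list of two vectors (bi) of
#'   candidate lifetimes, ns; at most 50 points per axis and 1e6 nodes.
#' @param shift Fixed IRF shift, ps.
#' @param fit_background If `FALSE`, background `A` is fixed at 0.
#' @return The best-fitting [decay_params()], with attributes `objective`
#'   (the achieved weighted sum of squares) and `shift`.
#' @export
grid_oracle_fit <- function(decay, irf, tau_grid, shift = 0,
                            fit_background = TRUE) {
  stopifnot(inherits(decay, "decay_histogram"),
            inherits(irf, "decay_histogram"))
  if (!is.list(tau_grid)) tau_grid <- list(tau_grid)
  if (!length(tau_grid) %in% 1:2) {
    stop("tau_grid must have 1 (mono) or 2 (bi) axes", call. = FALSE)
  }
  if (any(vapply(tau_grid, length, 1L) > 50L)) {
    stop("at most 50 grid points per axis", call. = FALSE)
  }
  if (prod(vapply(tau_grid, length, 1L)) > 1e6) {
    stop("grid too large (> 1e6 nodes)", call. = FALSE)
  }
  model <- if (length(tau_grid) == 1L) "mono" else "bi"
  obs <- decay$counts
  wts <- 1 / pmax(obs, 1)
  n <- length(obs)
  w <- shift_weights(irf_weights(irf), shift / irf$channel_width)
  base_conv <- function(tau) {
    d <- exp(-(decay$times / 1000) / tau)
    pmax(convolve(w, rev(d), type = "open")[seq_len(n)], 0)
  }
  # cache per-axis convolutions
  conv_cache <- lapply(tau_grid, function(axis) lapply(axis, base_conv))

  solve_node <- function(cols) {
    X <- do.call(cbind, cols)
    if (fit_background) X <- cbind(X, 1)
    fit <- stats::lm.wfit(X, obs, wts)
    beta <- pmax(fit$coefficients, 0)
    beta[is.na(beta)] <- 0
    e <- drop(X %*% beta)
    list(obj = sum(wts * (obs - e)^2), beta = beta)
  }

  best <- NULL
  if (model == "mono") {
    for (i in seq_along(tau_grid[[1]])) {
      node <- solve_node(conv_cache[[1]][i])
      if (is.null(best) || node$obj < best$obj) {
        best <- c(node, list(taus = tau_grid[[1]][i]))
      }
    }
  } else {
    for (i in seq_along(tau_grid[[1]])) {
      for (j in seq_along(tau_grid[[2]])) {
        t1 <- tau_grid[[1]][i]
        t2 <- tau_grid[[2]][j]
        if (t1 >= t2) next
        node <- solve_node(list(conv_cache[[1]][[i]], conv_cache[[2]][[j]]))
        if (is.null(best) || node$obj < best$obj) {
          best <- c(node, list(taus = c(t1, t2)))
        }
      }
    }
    if (is.null(best)) stop("empty grid after tau1 < tau2 filter",
                            call. = FALSE)
  }
  k <- length(best$taus)
  A <- if (fit_background) best$beta[k + 1L] else 0
  out <- decay_params(model, A = A, amplitudes = best$beta[seq_len(k)],
                      lifetimes = best$taus)
  attr(out, "objective") <- best$obj
  attr(out, "shift") <- shift
  out
}

## S3 methods ----------------------------------------------------------------

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("%s reconvolution fit (%s objective)%s\n",
              if (x$model == "mono") "Monoexponential" else "Biexponential",
              x$objective,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$coefficients, std.error = x$stderr)
  tab$fixed <- ifelse(rownames(tab) %in% x$fixed, "fixed", "")
  print(format(tab, digits = 5))
  cat(sprintf("reduced chi-square: %.4f  (iterations: %d)\n",
              x$chi2_red, x$n_iter))
  if (x$degenerate) cat("warning: degenerate fit (component collapse)\n")
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.decay_fit")
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  print(x$fit)
  r <- x$fit$residuals
  cat(sprintf("weighted residuals: mean %.4f, sd %.4f, range [%.2f, %.2f]\n",
              mean(r), sd(r), min(r), max(r)))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @export
fitted.decay_fit <- function(object, ...) object$fitted

#' @export
residuals.decay_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  if (type == "weighted") object$residuals
  else object$data$counts - object$fitted
}

#' @export
predict.decay_fit <- function(object, ...) object$fitted

#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  e <- object$fitted
  with_seed(seed, replicate(nsim, rpois(length(e), e), simplify = FALSE))
}

#' @export
plot.decay_fit <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  t_ns <- x$data$times / 1000
  plot(t_ns, pmax(x$data$counts, 0.5), log = "y", pch = ".", cex = 2,
       xlab = "time (ns)", ylab = "counts",
       main = sprintf("%sexponential reconvolution fit",
                      if (x$model == "mono") "mono" else "bi"))
  lines(t_ns, pmax(x$fitted, 0.5), col = 2, lwd = 1.5)
  plot(t_ns, x$residuals, type = "h", xlab = "time (ns)",
       ylab = "weighted residual")
  abline(h = 0, col = "grey")
  invisible(x)
}
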