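#' Generate a synthetic Gaussian prompt (IRF)
#'
#' Builds an instrument-response histogram over the configured time axis.
#' Channel weights are exact Gaussian bin integrals (channel i covers
#' `[i*w, (i+1)*w)` ps), scaled so the modal channel equals `peak_target`
#' and rounded to nonnegative integer counts. The Gaussian prompt is a
#' stand-in for a pulsed-LED excitation profile; its FWHM and center are set
#' in the [tcspc_config()].
#'
#' @param config A [tcspc_config()].
#' @return A [decay_histogram()] with `role = "prompt"`.
#' @examples
#' irf <- make_irf(tcspc_config(n_channels = 64, irf_center = 1000))
#' which.max(irf$counts)
#' @export
make_irf <- function(config) {
  stopifnot(inherits(config, "tcspc_config"))
  w <- config$channel_width
  n <- config$n_channels
  if (config$irf_center < 0 || config$irf_center > n * w) {
    stop("irf_center lies outside the acquisition window (truncated prompt)",
         call. = FALSE)
  }
  sigma <- config$irf_fwhm / (2 * sqrt(2 * log(2)))
  edges <- (0:n) * w
  p <- pnorm(edges, mean = config$irf_center, sd = sigma)
  weights <- diff(p)
  if (sum(weights) <= 0) {
    # FWHM far below channel width: all mass in the channel holding the center
    weights <- numeric(n)
    weights[min(n, floor(config$irf_center / w) + 1L)] <- 1
  }
  counts <- round(weights * config$peak_target / max(weights))
  decay_histogram(channel_times(config), counts, channel_width = w,
                  role = "prompt", label = "synthetic Gaussian prompt")
}

#' Simulate a photon-counting decay histogram
#'
#' Forward-models the measured decay: the unit-normalized IRF is convolved
#' (discrete linear convolution) with the exponential decay model evaluated
#' at channel centers, the constant background `A` is added, and the whole
#' expectation is rescaled so the modal channel equals the configured
#' `peak_target` (mimicking stop-at-peak acquisition). Observed counts are
#' then drawn channel-wise from a Poisson law with that expectation, using
#' the RNG seed in `config` (or `seed` if given).
#'
#' @param params A [decay_params()].
#' @param irf A prompt [decay_histogram()] on the same time axis.
#' @param config A [tcspc_config()].
#' @param noise If `FALSE`, return the rounded noiseless expectation.
#' @param seed Optional seed overriding `config$seed`.
#' @param label Label stored in the returned histogram.
#' @return A [decay_histogram()] with `role = "decay"`; the noiseless
#'   expectation (counts scale) is attached as attribute `"expectation"`.
#' @examples
#' cfg <- tcspc_config(n_channels = 256, seed = 7)
#' irf <- make_irf(cfg)
#' d <- simulate_decay(decay_params("mono", amplitudes = 1, lifetimes = 4),
#'                     irf, cfg)
#' @export
simulate_decay <- function(params, irf, config, noise = TRUE, seed = NULL,
                           label = "") {
  stopifnot(inherits(params, "decay_params"),
            inherits(irf, "decay_histogram"),
            inherits(config, "tcspc_config"))
  if (length(irf$counts) != config$n_channels ||
      abs(irf$channel_width - config$channel_width) >
        1e-6 * config$channel_width) {
    stop("irf and config do not share the same time axis", call. = FALSE)
  }
  if (any(params$lifetimes * 1000 < config$channel_width / 10)) {
    warning("lifetime shorter than channel_width/10: decay is under-resolved",
            call. = FALSE)
  }
  if (params$A >= config$peak_target) {
    stop("background A must stay below peak_target", call. = FALSE)
  }
  # A is already on the observed-counts scale: rescale only the decay part
  # so the expected modal channel hits peak_target
  conv <- convolve_model(irf, params, shift = 0) - params$A
  expected <- conv * (config$peak_target - params$A) / max(conv) + params$A
  counts <- if (noise) {
    with_seed(if (is.null(seed)) config$seed else seed,
              rpois(length(expected), expected))
  } else {
    expected
  }
  out <- decay_histogram(channel_times(config), counts,
                         channel_width = config$channel_width,
                         role = "decay", label = label)
  attr(out, "expectation") <- expected
  out
}

#' Simulate a decay-level analyte titration
#'
#' One simulated decay per analyte concentration: the slow lifetime
#' component `tau2` of the template parameters is replaced by the baseline
#' Hill prediction at each concentration, all other parameters held fixed.
#' Each concentration gets a distinct child seed derived deterministically
#' from `config$seed`.
#'
#' @param hill A [hill_params()] describing the generating dose-response.
#' @param concentrations Strictly positive molar concentrations, ascending.
#' @param params_template A biexponential [decay_params()] whose `tau2` slot
#'   is driven by the isotherm.
#' @param irf,config As in [simulate_decay()].
#' @param noise Passed through to [simulate_decay()].
#' @return A list with one element per concentration, each a list with
#'   `concentration` (molar), `tau2` (generating value, ns) and `decay`.
#' @export
simulate_decay_titration <- function(hill, concentrations, params_template,
                                     irf, config, noise = TRUE) {
  stopifnot(inherits(hill, "hill_params"),
            inherits(params_template, "decay_params"))
  if (params_template$kind != "bi") {
    stop("params_template must be biexponential (tau2 is titrated)",
         call. = FALSE)
  }
  if (length(concentrations) == 0L) {
    stop("empty concentration list", call. = FALSE)
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be sorted strictly ascending", call. = FALSE)
  }
  lapply(seq_along(concentrations), function(i) {
    x <- concentrations[i]
    tau2 <- predict_hill(hill, x)
    p <- decay_params("bi", A = params_template$A,
                      amplitudes = params_template$amplitudes,
                      lifetimes = c(params_template$lifetimes[1], tau2))
    d <- simulate_decay(p, irf, config, noise = noise,
                        seed = child_seed(config$seed, i),
                        label = sprintf("%.6g M", x))
    list(concentration = x, tau2 = tau2, decay = d)
  })
}

#' Simulate a response-level titration table
#'
#' Replicate sensor responses (lifetime in ns for a Hill model, intensity in
#' rfu for a Langmuir model) at each concentration: the model prediction plus
#' independent Gaussian noise of the stated standard deviation.
#'
#' @param model A [hill_params()] or [langmuir_params()].
#' @param concentrations Strictly positive molar concentrations.
#' @param noise_sd Gaussian noise sd in response units (>= 0).
#' @param replicates Replicates per concentration (>= 1).
#' @param seed Integer RNG seed.
#' @return A [titration_series()].
#' @examples
#' simulate_response_titration(langmuir_params(34399, 23103, 30e-12),
#'                             10^seq(-13, -8, length.out = 6),
#'                             noise_sd = 500, replicates = 3, seed = 1)
#' @export
simulate_response_titration <- function(model, concentrations, noise_sd = 0,
                                        replicates = 3L, seed = 1L) {
  if (!inherits(model, "hill_params") && !inherits(model, "langmuir_params")) {
    stop("model must be hill_params or langmuir_params", call. = FALSE)
  }
  stop_if_not_scalar_number(noise_sd, "noise_sd", nonnegative = TRUE)
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("replicates must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  pred <- if (inherits(model, "hill_params")) {
    predict_hill(model, concentrations)
  } else {
    predict_langmuir(model, concentrations)
  }
  conc <- rep(concentrations, each = replicates)
  mu <- rep(pred, each = replicates)
  resp <- with_seed(seed, mu + rnorm(length(mu), sd = noise_sd))
  titration_series(
    conc, resp,
    response_kind = if (inherits(model, "hill_params")) "lifetime_tau2"
                    else "intensity",
    replicate = rep(seq_len(replicates), times = length(concentrations))
  )
}

#' Default log-spaced concentration grid
#'
#' Ten points log-spaced over the titration range 100 fM to 150 nM.
#'
#' @param n Number of points.
#' @param from,to Range bounds, molar.
#' @return Numeric vector of molar concentrations, ascending.
#' @export
default_concentrations <- function(n = 10L, from = 100e-15, to = 150e-9) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Simulate a selectivity panel
#'
#' The template protein's response follows the generating Hill model at the
#' given concentration; non-binder proteins return the zero-analyte lifetime
#' `tau2_0` plus an optional per-protein drift (to mimic slight nonspecific
#' lifetime increments), plus blank-level Gaussian noise.
#'
#' @param binding A [hill_params()] for the template protein.
#' @param nonbinders Character vector of non-binder protein labels (may be
#'   empty).
#' @param concentration Template analyte concentration, molar (> 0).
#' @param seed Integer RNG seed.
#' @param noise_sd Blank-level noise sd, ns (default 0: deterministic panel).
#' @param drift Named numeric vector of additive lifetime offsets (ns) for
#'   individual non-binders, e.g. `c(BSA = 0.01)`; default none.
#' @param template_label Label of the template row.
#' @return A data frame with columns `label`, `concentration`, `tau2`.
#' @export
simulate_selectivity_panel <- function(binding, nonbinders = character(),
                                       concentration, seed = 1L,
                                       noise_sd = 0, drift = NULL,
                                       template_label = "HSA") {
  stopifnot(inherits(binding, "hill_params"))
  stop_if_not_scalar_number(concentration, "concentration", positive = TRUE)
  labels <- c(template_label, nonbinders)
  tau2 <- c(predict_hill(binding, concentration),
            rep(binding$tau2_0, length(nonbinders)))
  if (!is.null(drift) && length(nonbinders)) {
    idx <- match(names(drift), nonbinders)
    ok <- !is.na(idx)
    tau2[1L + idx[ok]] <- tau2[1L + idx[ok]] + drift[ok]
  }
  if (noise_sd > 0) {
    tau2 <- with_seed(seed, tau2 + rnorm(length(tau2), sd = noise_sd))
  }
  data.frame(label = labels,
             concentration = c(concentration,
                               rep(NA_real_, length(nonbinders))),
             tau2 = tau2)
}
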