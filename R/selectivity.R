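#' Percent lifetime change versus blank
#'
#' Raw relative drop of the binding-site lifetime,
#' `100 * (tau2_blank - tau2_sample) / tau2_blank`. Positive values are
#' drops (binding/quenching); negative values are increments (as seen for
#' some non-specific interactions). The span-normalized variant is
#' [normalized_response()].
#'
#' @param tau2_blank Blank lifetime, ns (> 0).
#' @param tau2_sample Sample lifetime(s), ns.
#' @return Percentage change(s).
#' @examples
#' percent_tau2_change(4.183, 3.983)  # 4.78
#' @export
percent_tau2_change <- function(tau2_blank, tau2_sample) {
  if (!is.finite(tau2_blank) || tau2_blank <= 0) {
    stop("tau2_blank must be > 0", call. = FALSE)
  }
  100 * (tau2_blank - tau2_sample) / tau2_blank
}

# Fit a list of replicate decays biexponentially with a fixed tau1,
# returning surviving tau2 values (non-converged fits excluded).
fit_condition_tau2 <- function(decays, irf, fixed_tau1, objective) {
  vals <- vapply(decays, function(d) {
    fit <- tryCatch(
      suppressWarnings(fit_biexponential(d, irf, fixed_tau1 = fixed_tau1,
                                         objective = objective)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) NA_real_
    else unname(coef(fit)[["tau2"]])
  }, numeric(1))
  vals[!is.na(vals)]
}

as_decay_list <- function(x) {
  if (inherits(x, "decay_histogram")) list(x) else x
}

#' Run a selectivity panel
#'
#' Fits every replicate decay of every condition biexponentially against the
#' prompt, with the fast component `tau1` fixed globally to the value
#' obtained from a free fit of the blank (zero-analyte) decays. Per
#' condition, surviving (converged) replicate lifetimes are averaged and
#' compared with the blank: a condition is called a `binder` when the
#' lifetime drop exceeds `threshold_sd` times the pooled replicate standard
#' deviation (3-sigma convention by default), `non-binder` when the absolute
#' change stays below it, and `indeterminate` otherwise — in particular for
#' significant lifetime *increases*, which indicate non-specific
#' interactions rather than binding. Conditions with fewer than two
#' surviving fits are `indeterminate`.
#'
#' @param blank_decays List of >= 2 replicate blank [decay_histogram()]s.
#' @param sample_decays Named list; each element a list of replicate decays
#'   for one condition (protein).
#' @param irf Prompt [decay_histogram()] used for deconvolution.
#' @param concentrations Optional named molar concentrations per condition
#'   (reporting only).
#' @param threshold_sd Binding-call threshold in pooled-sd units.
#' @param fixed_tau1 Optional explicit fast-component lifetime, ns;
#'   default: derived from the blank fits.
#' @param objective Decay-fit objective, see [decay_fit()].
#' @return A data frame of class `panel_result` with columns `label`,
#'   `concentration`, `tau2`, `tau2_stderr`, `n_fits`, `delta_pct`, `call`;
#'   attributes `pooled_sd`, `threshold_sd`, `tau1_fixed`, `prompt_label`.
#' @export
run_panel <- function(blank_decays, sample_decays, irf,
                      concentrations = NULL, threshold_sd = 3,
                      fixed_tau1 = NULL, objective = "neyman") {
  blank_decays <- as_decay_list(blank_decays)
  if (length(blank_decays) < 2L) {
    stop("need >= 2 replicate blank decays", call. = FALSE)
  }
  if (length(sample_decays) &&
      (is.null(names(sample_decays)) || any(!nzchar(names(sample_decays))))) {
    stop("sample_decays must be a named list (one entry per condition)",
         call. = FALSE)
  }
  sample_decays <- lapply(sample_decays, as_decay_list)

  if (is.null(fixed_tau1)) {
    t1 <- vapply(blank_decays, function(d) {
      fit <- tryCatch(
        suppressWarnings(fit_biexponential(d, irf, objective = objective)),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) NA_real_
      else unname(coef(fit)[["tau1"]])
    }, numeric(1))
    t1 <- t1[!is.na(t1)]
    if (length(t1) == 0L) {
      stop("no converged blank fit to derive the fixed tau1 from",
           call. = FALSE)
    }
    fixed_tau1 <- mean(t1)
  }

  conditions <- c(list(blank = blank_decays), sample_decays)
  tau2 <- lapply(conditions, fit_condition_tau2, irf = irf,
                 fixed_tau1 = fixed_tau1, objective = objective)

  if (length(tau2$blank) < 2L) {
    stop("fewer than 2 converged blank fits: no reference lifetime",
         call. = FALSE)
  }
  blank_mean <- mean(tau2$blank)

  # pooled within-condition replicate sd over conditions with >= 2 fits
  sds <- vapply(tau2, function(v) if (length(v) >= 2) sd(v) else NA_real_,
                numeric(1))
  ns <- vapply(tau2, length, 1L)
  ok <- !is.na(sds)
  pooled <- if (any(ok)) {
    sqrt(sum(sds[ok]^2 * (ns[ok] - 1)) / sum(ns[ok] - 1))
  } else NA_real_

  rows <- lapply(names(conditions), function(lab) {
    v <- tau2[[lab]]
    m <- if (length(v)) mean(v) else NA_real_
    se <- if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_
    delta <- if (lab == "blank") 0 else percent_tau2_change(blank_mean, m)
    call <- if (lab == "blank") {
      "non-binder"
    } else if (length(v) < 2L || !is.finite(m)) {
      "indeterminate"
    } else {
      drop <- blank_mean - m
      lim <- threshold_sd * pooled
      if (!is.finite(lim)) "indeterminate"
      else if (drop > lim) "binder"
      else if (abs(drop) <= lim) "non-binder"
      else "indeterminate"   # significant increase: non-specific interaction
    }
    conc <- if (!is.null(concentrations) && lab %in% names(concentrations)) {
      concentrations[[lab]]
    } else NA_real_
    data.frame(label = lab, concentration = conc, tau2 = m,
               tau2_stderr = se, n_fits = length(v), delta_pct = delta,
               call = call)
  })
  out <- do.call(rbind, rows)
  attr(out, "pooled_sd") <- pooled
  attr(out, "threshold_sd") <- threshold_sd
  attr(out, "tau1_fixed") <- fixed_tau1
  attr(out, "prompt_label") <- irf$label
  class(out) <- c("panel_result", "data.frame")
  out
}

#' @export
print.panel_result <- function(x, ...) {
  cat("Selectivity panel result\n")
  cat(sprintf("  fixed tau1 %.4g ns; pooled replicate sd %.4g ns; threshold %g sd\n",
              attr(x, "tau1_fixed"), attr(x, "pooled_sd"),
              attr(x, "threshold_sd")))
  cat(sprintf("  prompt: %s\n", attr(x, "prompt_label")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run a spiked-matrix (wine) assay
#'
#' Applies the panel calling logic of [run_panel()] to a spiked-matrix
#' experiment: unspiked-matrix decays are the reference (blank) condition,
#' compared against matrix samples spiked with the target analyte and with
#' an unrelated protein. Following the matrix-matched protocol, the prompt
#' used for deconvolution is the one recorded on the unspiked matrix sample
#' (`matrix_prompt`); set `use_matrix_prompt = FALSE` to use a plain
#' instrument prompt (`instrument_prompt`) instead. The result records which
#' histogram served as prompt.
#'
#' @param matrix_blank_decays List of >= 2 unspiked-matrix decays (reference
#'   condition).
#' @param matrix_spiked_decays List of decays spiked with the target
#'   analyte.
#' @param unrelated_spiked_decays List of decays spiked with an unrelated
#'   protein.
#' @param matrix_prompt Prompt [decay_histogram()] recorded on the unspiked
#'   matrix sample (matrix-matched).
#' @param instrument_prompt Optional plain instrument prompt.
#' @param use_matrix_prompt Use the matrix-matched prompt (default `TRUE`).
#' @param spike_concentration Molar spike concentration (reporting only).
#' @param ... Passed to [run_panel()] (`threshold_sd`, `fixed_tau1`, ...).
#' @return A `panel_result` (see [run_panel()]); attribute `prompt_label`
#'   names the histogram used as prompt.
#' @export
run_matrix_assay <- function(matrix_blank_decays, matrix_spiked_decays,
                             unrelated_spiked_decays, matrix_prompt = NULL,
                             instrument_prompt = NULL,
                             use_matrix_prompt = TRUE,
                             spike_concentration = NA_real_, ...) {
  matrix_blank_decays <- as_decay_list(matrix_blank_decays)
  if (length(matrix_blank_decays) < 2L) {
    stop("missing matrix blank: need >= 2 unspiked-matrix decays",
         call. = FALSE)
  }
  prompt <- if (use_matrix_prompt) matrix_prompt else instrument_prompt
  if (is.null(prompt)) {
    stop(if (use_matrix_prompt) {
      "missing matrix-matched prompt (recorded on the unspiked matrix sample)"
    } else {
      "missing instrument prompt"
    }, call. = FALSE)
  }
  conc <- c(spiked = spike_concentration,
            unrelated_spiked = spike_concentration)
  run_panel(matrix_blank_decays,
            list(spiked = as_decay_list(matrix_spiked_decays),
                 unrelated_spiked = as_decay_list(unrelated_spiked_decays)),
            irf = prompt, concentrations = conc, ...)
}
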