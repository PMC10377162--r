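# Synthetic-data generator: prompt construction, decay forward model,
# titrations, noise models.

test_that("Gaussian prompt peaks at the configured center and respects the delta limit", {
  cfg <- ref_cfg(irf_fwhm = 500, irf_center = 5000)
  irf <- make_irf(cfg)
  expect_s3_class(irf, "decay_histogram")
  expect_identical(irf$role, "prompt")
  # channel containing 5 ns: [i*w, (i+1)*w) covers 5000 ps for i = 45 (1-based 46)
  expect_equal(which.max(irf$counts), floor(5000 / cfg$channel_width) + 1L)
  expect_equal(max(irf$counts), cfg$peak_target)
  expect_true(all(irf$counts >= 0))
  expect_true(all(irf$counts == round(irf$counts)))

  # FWHM far below the channel width: all weight collapses into one channel
  cfg2 <- tcspc_config(n_channels = 64, channel_width = 100,
                       irf_fwhm = 1e-6, irf_center = 550, peak_target = 1000)
  irf2 <- make_irf(cfg2)
  expect_equal(sum(irf2$counts > 0), 1L)
  expect_equal(which.max(irf2$counts), 6L)  # 550 ps lies in channel 6

  # truncated prompt is rejected
  expect_error(make_irf(tcspc_config(n_channels = 16, channel_width = 100,
                                     irf_center = 5000)),
               "outside")
})

test_that("prompt channel weights match a numerical-quadrature oracle", {
  # FWHM = 2 channel widths, center on a channel boundary
  cfg <- tcspc_config(n_channels = 32, channel_width = 100, irf_fwhm = 200,
                      irf_center = 800, peak_target = 5000)
  irf <- make_irf(cfg)
  sigma <- 200 / (2 * sqrt(2 * log(2)))
  oracle <- vapply(seq_len(cfg$n_channels), function(i) {
    stats::integrate(function(t) stats::dnorm(t, 800, sigma),
                     (i - 1) * 100, i * 100, rel.tol = 1e-12)$value
  }, numeric(1))
  expect_equal(irf$counts, round(oracle / max(oracle) * cfg$peak_target))
  # stored normalized weights sum to one
  expect_equal(sum(irf$counts / sum(irf$counts)), 1, tolerance = 1e-9)
})

test_that("noise-free mono decay with a delta prompt is a bare exponential peaking at t = 0", {
  cfg <- ref_cfg()
  irf <- delta_irf(cfg)
  d <- simulate_decay(decay_params("mono", A = 0, amplitudes = 1,
                                   lifetimes = 3.086),
                      irf, cfg, noise = FALSE)
  expect_equal(which.max(d$counts), 1L)
  expect_equal(max(d$counts), cfg$peak_target)
  t_ns <- d$times / 1000
  expect_equal(d$counts / d$counts[1],
               exp(-(t_ns - t_ns[1]) / 3.086), tolerance = 1e-9)
})

test_that("convolved expectation matches a by-hand convolution oracle and conserves counts", {
  # 16-channel miniature: Gaussian-ish IRF, biexponential with equal amplitudes
  cfg <- tcspc_config(n_channels = 16, channel_width = 500, irf_fwhm = 500,
                      irf_center = 1500, peak_target = 1000)
  irf <- make_irf(cfg)
  params <- decay_params("bi", A = 0, amplitudes = c(0.5, 0.5),
                         lifetimes = c(1, 4.183))
  got <- convolve_model(irf, params, shift = 0)
  # independent oracle: explicit double loop over the convolution sum
  wts <- irf$counts / sum(irf$counts)
  t_ns <- channel_centers(cfg) / 1000
  model <- 0.5 * exp(-t_ns / 1) + 0.5 * exp(-t_ns / 4.183)
  oracle <- numeric(16)
  for (j in 1:16) {
    for (i in 1:j) oracle[j] <- oracle[j] + wts[i] * model[j - i + 1]
  }
  expect_equal(got, oracle, tolerance = 1e-10)

  # conservation: noise-off totals equal the analytic sum of the series
  d <- simulate_decay(params, irf, cfg, noise = FALSE)
  expect_equal(sum(d$counts),
               sum(oracle) * cfg$peak_target / max(oracle),
               tolerance = 1e-6)
})

test_that("decay-level titration drives tau2 along the generating Hill curve", {
  truth <- hill_truth()
  cfg <- mini_cfg(seed = 9)
  irf <- make_irf(cfg)
  template <- bi_template()
  conc <- c(1e-13, 18e-12, 150e-9)
  sims <- simulate_decay_titration(truth, conc, template, irf, cfg,
                                   noise = FALSE)
  tau2 <- vapply(sims, `[[`, 1, "tau2")
  # midpoint of the span at x = EC50
  expect_equal(tau2[2], (4.183 + 3.983) / 2, tolerance = 1e-12)
  # saturation limit
  expect_equal(tau2[3], 3.983, tolerance = 1e-4)
  # zero-analyte limit of the generating curve
  expect_equal(predict_hill(truth, 0), 4.183)

  expect_error(simulate_decay_titration(truth, numeric(0), template, irf,
                                        cfg), "empty")
  expect_error(simulate_decay_titration(truth, c(2e-12, 1e-12), template,
                                        irf, cfg), "ascending")
  expect_error(simulate_decay_titration(truth, c(-1e-12, 1e-12), template,
                                        irf, cfg), "positive")
})

test_that("response titrations reproduce isotherm values and the stated noise level", {
  lt <- langmuir_truth()
  ser <- simulate_response_titration(lt, c(1e-15, 30e-12), noise_sd = 0,
                                     replicates = 2, seed = 1)
  # midpoint at x = k: (34399 + 23103) / 2 = 28751 rfu
  expect_equal(ser$summary$mean[2], 28751)
  expect_equal(predict_langmuir(lt, 0), 34399)

  # Monte-Carlo check of the Gaussian noise model at the lifetime level
  truth <- hill_truth()
  conc <- default_concentrations(10)
  devs <- unlist(lapply(1:80, function(s) {
    ser <- simulate_response_titration(truth, conc, noise_sd = 0.009,
                                       replicates = 3, seed = s)
    ser$data$response - rep(predict_hill(truth, conc), each = 3)
  }))
  expect_equal(sd(devs), 0.009, tolerance = 0.05)
})

test_that("identical seeds reproduce decays bit-for-bit and distinct seeds differ", {
  cfg <- mini_cfg(seed = 42)
  irf <- make_irf(cfg)
  p <- bi_template()
  d1 <- simulate_decay(p, irf, cfg)
  d2 <- simulate_decay(p, irf, cfg)
  d3 <- simulate_decay(p, irf, cfg, seed = 43)
  expect_identical(d1$counts, d2$counts)
  expect_true(any(d1$counts != d3$counts))
})

test_that("Poisson realizations average to the noiseless expectation", {
  cfg <- tcspc_config(n_channels = 64, channel_width = 200, irf_fwhm = 400,
                      irf_center = 1000, peak_target = 2000, seed = 1)
  irf <- make_irf(cfg)
  p <- bi_template(A = 20)
  e <- attr(simulate_decay(p, irf, cfg, noise = FALSE), "expectation")
  n_rep <- 200
  acc <- numeric(length(e))
  for (s in seq_len(n_rep)) {
    acc <- acc + simulate_decay(p, irf, cfg, seed = s)$counts
  }
  m <- acc / n_rep
  expect_true(all(abs(m - e) <= 3 * sqrt(e / n_rep) + 1e-9))
})

test_that("generating Hill curve is monotone nonincreasing for a quenching sensor", {
  truth <- hill_truth()
  x <- 10^seq(-14, -7, length.out = 100)
  y <- predict_hill(truth, x)
  expect_true(all(diff(y) <= 0))
})

test_that("selectivity panel rows follow the generating construction", {
  truth <- hill_truth()
  pan <- simulate_selectivity_panel(truth,
                                    c("BSA", "HTR", "ovalbumin", "lysozyme"),
                                    concentration = 18e-12, seed = 1)
  expect_equal(nrow(pan), 5L)
  expect_equal(pan$tau2[pan$label == "HSA"], 4.083)
  expect_true(all(pan$tau2[pan$label != "HSA"] == 4.183))

  # empty non-binder list: single-row panel
  solo <- simulate_selectivity_panel(truth, character(), 18e-12)
  expect_equal(nrow(solo), 1L)

  # additive drift for one non-binder
  drifted <- simulate_selectivity_panel(truth, c("BSA", "HTR"), 18e-12,
                                        drift = c(BSA = 0.01))
  expect_equal(drifted$tau2[drifted$label == "BSA"], 4.193)
  expect_equal(drifted$tau2[drifted$label == "HTR"], 4.183)
})

test_that("under-resolved lifetimes trigger a warning", {
  cfg <- mini_cfg()
  irf <- make_irf(cfg)
  p <- decay_params("mono", amplitudes = 1, lifetimes = 0.005)  # 5 ps
  expect_warning(simulate_decay(p, irf, cfg, noise = FALSE),
                 "under-resolved")
})
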