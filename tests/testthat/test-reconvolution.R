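# Iterative reconvolution fitting: forward model, initial guesses,
# optimizer behavior, chi-square convention, grid oracle.

test_that("delta prompt is the identity kernel and the model is linear in amplitudes", {
  cfg <- mini_cfg()
  irf <- delta_irf(cfg)
  p <- decay_params("mono", A = 7, amplitudes = 3, lifetimes = 2.5)
  e <- convolve_model(irf, p, shift = 0)
  bare <- 3 * exp(-(channel_centers(cfg) / 1000) / 2.5) + 7
  expect_equal(e, bare, tolerance = 1e-12)

  # doubling B1 doubles (expected - A) when B2 = 0
  g <- make_irf(cfg)
  p1 <- decay_params("bi", A = 4, amplitudes = c(1, 0), lifetimes = c(1, 4))
  p2 <- decay_params("bi", A = 4, amplitudes = c(2, 0), lifetimes = c(1, 4))
  expect_equal(convolve_model(g, p2) - 4, 2 * (convolve_model(g, p1) - 4),
               tolerance = 1e-12)

  # all-zero IRF is rejected
  z <- decay_histogram(channel_centers(cfg), rep(0, cfg$n_channels),
                       role = "prompt")
  expect_error(convolve_model(z, p), "all-zero")
})

test_that("16-channel toy convolution matches a by-hand oracle, including integer shifts", {
  w <- 100
  times <- (1:16 - 0.5) * w
  irf_counts <- c(0, 25, 50, 25, rep(0, 12))  # weights (.25,.5,.25) at ch 2-4
  irf <- decay_histogram(times, irf_counts, role = "prompt")
  tau <- 5 * w / 1000  # 5 channel widths, in ns
  p <- decay_params("mono", A = 0, amplitudes = 1, lifetimes = tau)
  got <- convolve_model(irf, p, shift = 0)
  model <- exp(-(times / 1000) / tau)
  oracle <- numeric(16)
  wts <- c(0, 0.25, 0.5, 0.25, rep(0, 12))
  for (j in 1:16) for (i in 1:j) {
    oracle[j] <- oracle[j] + wts[i] * model[j - i + 1]
  }
  expect_equal(got, oracle, tolerance = 1e-10)

  # a one-channel shift equals convolution with the IRF moved one channel
  shifted <- convolve_model(irf, p, shift = w)
  irf2 <- decay_histogram(times, c(0, irf_counts[-16]), role = "prompt")
  expect_equal(shifted, convolve_model(irf2, p, shift = 0),
               tolerance = 1e-10)
  expect_error(convolve_model(irf, p, shift = 6 * w), "5 channels")
})

test_that("initial guess recovers lifetime, background, and flags degenerate input", {
  cfg <- ref_cfg()
  irf <- delta_irf(cfg)
  d <- simulate_decay(decay_params("mono", A = 0, amplitudes = 1,
                                   lifetimes = 3.5),
                      irf, cfg, noise = FALSE)
  g <- initial_guess(d, "mono")
  expect_equal(g$lifetimes[1], 3.5, tolerance = 0.05)

  # flat histogram: no decaying tail
  flat <- decay_histogram(channel_centers(mini_cfg(n = 64L)), rep(100, 64))
  expect_error(initial_guess(flat), "tail")

  # baseline estimate on noisy data with A = 50 (Poisson counting scatter)
  g2 <- make_irf(cfg)
  d2 <- simulate_decay(bi_template(A = 50), g2, cfg, seed = 5)
  guess <- initial_guess(d2, "bi")
  n_base <- which.max(d2$counts) - 8L
  expect_lt(abs(guess$A - 50), 3 * sqrt(50 / n_base))
  expect_error(initial_guess(decay_histogram((1:30 - .5) * 100,
                                             rep(c(5, 0), 15))),
               "sparse")
})

test_that("reduced chi-square follows the Neyman convention", {
  expect_equal(reduced_chi_square(c(100, 50, 25), c(100, 50, 25), 2), 0)

  # obs = exp + sqrt(exp): each channel contributes exp / (exp + sqrt(exp))
  e <- rep(10000, 100)
  o <- e + sqrt(e)
  expected_value <- sum((o - e)^2 / pmax(o, 1)) / (100 - 2)
  expect_equal(reduced_chi_square(o, e, 2), expected_value)
  expect_equal(reduced_chi_square(o, e, 2), 100 / 98, tolerance = 0.02)

  expect_error(reduced_chi_square(1:5, 1:5, 5), "smaller")
  expect_error(reduced_chi_square(1:4, 1:5, 1), "differ")

  # min_counts excludes channels from both sum and degrees of freedom
  o2 <- c(0, 0, 100, 100)
  e2 <- c(5, 5, 100, 100)
  expect_equal(reduced_chi_square(o2, e2, 1, min_counts = 1), 0)
})

test_that("noiseless decays are recovered to machine-level accuracy (both models)", {
  cfg <- ref_cfg()
  irf <- delta_irf(cfg)

  d <- simulate_decay(decay_params("mono", A = 0, amplitudes = 1,
                                   lifetimes = 3.086),
                      irf, cfg, noise = FALSE)
  f <- fit_monoexponential(d, irf)
  expect_true(f$converged)
  expect_equal(coef(f)[["tau"]], 3.086, tolerance = 1e-6)

  db <- simulate_decay(decay_params("bi", A = 0, amplitudes = c(0.5, 0.5),
                                    lifetimes = c(1, 4.183)),
                       irf, cfg, noise = FALSE)
  fb <- fit_biexponential(db, irf)
  expect_true(fb$converged)
  expect_equal(coef(fb)[["tau1"]], 1, tolerance = 1e-4)
  expect_equal(coef(fb)[["tau2"]], 4.183, tolerance = 1e-6)
  expect_true(coef(fb)[["tau1"]] <= coef(fb)[["tau2"]])

  # fixing tau1 leaves tau2 recovery unchanged and drops one free parameter
  fb2 <- fit_biexponential(db, irf, fixed_tau1 = 1.0)
  expect_equal(coef(fb2)[["tau2"]], 4.183, tolerance = 1e-6)
  expect_true(is.na(fb2$stderr[["tau1"]]))
  expect_equal(sum(!is.na(fb2$stderr)), sum(!is.na(fb$stderr)) - 1L)
})

test_that("Poisson decays at acquisition scale are recovered within uncertainty", {
  cfg <- ref_cfg(seed = 8)
  irf <- make_irf(cfg)
  d <- simulate_decay(decay_params("mono", A = 50, amplitudes = 1,
                                   lifetimes = 3.457),
                      irf, cfg)
  f <- fit_monoexponential(d, irf)
  expect_true(f$converged)
  expect_lt(abs(coef(f)[["tau"]] - 3.457), 3 * f$stderr[["tau"]])
  expect_gt(f$chi2_red, 0.8)
  expect_lt(f$chi2_red, 1.2)

  # fixed-parameter contract: tau clamped at truth, I0 still recovered
  ff <- fit_monoexponential(d, irf, fixed = list(tau = 3.457))
  expect_true(is.na(ff$stderr[["tau"]]))
  expect_false(is.na(ff$stderr[["I0"]]))
  expect_identical(coef(ff)[["tau"]], 3.457)
})

test_that("biexponential fit on mono-generated data collapses with a degeneracy warning", {
  cfg <- ref_cfg(seed = 12)
  irf <- make_irf(cfg)
  d <- simulate_decay(decay_params("mono", A = 50, amplitudes = 1,
                                   lifetimes = 3.2),
                      irf, cfg)
  expect_warning(fb <- fit_biexponential(d, irf), "degenerate")
  # the amplitude-weighted lifetime still matches the generating value
  co <- coef(fb)
  tau_eff <- (co[["B1"]] * co[["tau1"]] + co[["B2"]] * co[["tau2"]]) /
    (co[["B1"]] + co[["B2"]])
  expect_equal(tau_eff, 3.2, tolerance = 0.02)
})

test_that("optimizer never loses to the brute-force grid oracle", {
  # seeded small instances: optimizer objective <= oracle objective + slack
  cfg <- tcspc_config(n_channels = 96, channel_width = 150, irf_fwhm = 300,
                      irf_center = 900, peak_target = 2000)
  irf <- make_irf(cfg)
  for (s in 1:20) {
    d <- simulate_decay(decay_params("mono", A = 10, amplitudes = 1,
                                     lifetimes = 3 + (s %% 5) * 0.4),
                        irf, cfg, seed = s)
    f <- fit_monoexponential(d, irf, fixed = list(shift = 0))
    grid <- seq(1, 8, length.out = 50)
    oracle <- grid_oracle_fit(d, irf, grid, shift = 0)
    opt_obj <- sum(f$residuals^2)
    expect_lte(opt_obj, attr(oracle, "objective") * (1 + 1e-9) + 1e-9)
  }
})

test_that("grid oracle finds the truth on noiseless toys and agrees with the optimizer", {
  cfg <- tcspc_config(n_channels = 128, channel_width = 150, irf_fwhm = 300,
                      irf_center = 900, peak_target = 5000)
  irf <- make_irf(cfg)

  # mono noiseless: oracle tau equals truth to grid resolution
  d <- simulate_decay(decay_params("mono", A = 0, amplitudes = 1,
                                   lifetimes = 3.25),
                      irf, cfg, noise = FALSE)
  grid <- seq(2.05, 4.5, by = 0.05)
  oracle <- grid_oracle_fit(d, irf, grid, shift = 0, fit_background = FALSE)
  expect_lte(abs(oracle$lifetimes[1] - 3.25), 0.05 / 2 + 1e-12)

  # bi toy: optimizer and oracle agree within one grid step per lifetime
  db <- simulate_decay(decay_params("bi", A = 10, amplitudes = c(0.5, 0.5),
                                    lifetimes = c(1.2, 4.2)),
                       irf, cfg, seed = 3)
  f <- fit_biexponential(db, irf, fixed = list(shift = 0))
  g1 <- seq(0.5, 2.5, by = 0.05)
  g2 <- seq(3.1, 5.55, by = 0.05)
  ob <- grid_oracle_fit(db, irf, list(g1, g2), shift = 0)
  expect_lte(abs(coef(f)[["tau1"]] - ob$lifetimes[1]), 0.05 + 1e-9)
  expect_lte(abs(coef(f)[["tau2"]] - ob$lifetimes[2]), 0.05 + 1e-9)

  expect_error(grid_oracle_fit(d, irf, seq(1, 5, length.out = 60)),
               "50 grid points")
})

test_that("fitted lifetimes always respect the tau1 <= tau2 label convention", {
  cfg <- mini_cfg(n = 256L)
  irf <- make_irf(cfg)
  for (s in 1:8) {
    d <- simulate_decay(bi_template(tau2 = 3 + 0.3 * s, A = 20), irf, cfg,
                        seed = 100 + s)
    f <- suppressWarnings(fit_biexponential(d, irf))
    expect_lte(coef(f)[["tau1"]], coef(f)[["tau2"]])
  }
})

test_that("fitted tau2 is unbiased with calibrated uncertainty over replicate acquisitions", {
  cfg <- ref_cfg()
  irf <- make_irf(cfg)
  truth <- bi_template(tau2 = 4.183, A = 50)
  n_rep <- 30
  est <- se <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    d <- simulate_decay(truth, irf, cfg, seed = 2000 + s)
    f <- fit_biexponential(d, irf, fixed_tau1 = 1.0)
    est[s] <- coef(f)[["tau2"]]
    se[s] <- f$stderr[["tau2"]]
  }
  # mean recovery within 3 standard errors of the mean
  expect_lt(abs(mean(est) - 4.183), 3 * sd(est) / sqrt(n_rep))
  # relative bias below 0.5%
  expect_lt(abs(mean(est) - 4.183) / 4.183, 0.005)
  # nominal +/- 2 se coverage
  cover <- mean(abs(est - 4.183) < 2 * se)
  expect_gte(cover, 0.80)
})
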