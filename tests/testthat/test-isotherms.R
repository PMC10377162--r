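# Binding isotherms: model evaluation, fitting, convergence reporting.

test_that("Langmuir model evaluates exactly", {
  p <- langmuir_truth()
  expect_equal(predict_langmuir(p, 30e-12), (34399 + 23103) / 2)
  expect_equal(predict_langmuir(p, 0), 34399)
  expect_equal(predict_langmuir(p, 90e-12),
               34399 + (23103 - 34399) * (90 / 120))
  expect_error(predict_langmuir(p, -1e-12), ">= 0")
})

test_that("baseline Hill model evaluates exactly and reduces to Langmuir at n = 1", {
  p <- hill_truth()
  expect_equal(predict_hill(p, 18e-12), (4.183 + 3.983) / 2)
  expect_equal(predict_hill(p, 0), 4.183)
  # x = 2 EC50: tau2_0 + span * 2^n / (1 + 2^n)
  expect_equal(predict_hill(p, 36e-12),
               4.183 - 0.200 * (2^1.89 / (1 + 2^1.89)))

  p1 <- hill_params(34399, 23103, 30e-12, 1)
  lg <- langmuir_truth()
  x <- 10^seq(-14, -8, length.out = 50)
  expect_equal(predict_hill(p1, x), predict_langmuir(lg, x),
               tolerance = 1e-12)

  # bare (no-baseline) variant vanishes at x = 0
  expect_equal(predict_hill(p, 0, baseline = FALSE), 0)
  expect_equal(predict_hill(p, 1e-3, baseline = FALSE), 3.983,
               tolerance = 1e-6)
})

test_that("noiseless titrations are recovered to 1e-6 relative accuracy", {
  conc <- default_concentrations(10)

  serL <- simulate_response_titration(langmuir_truth(), conc, 0, 3, seed = 1)
  fL <- fit_langmuir(serL)
  expect_true(fL$converged)
  expect_equal(coef(fL)[["START"]], 34399, tolerance = 1e-6)
  expect_equal(coef(fL)[["END"]], 23103, tolerance = 1e-6)
  expect_equal(coef(fL)[["k"]], 30e-12, tolerance = 1e-6)

  serH <- simulate_response_titration(hill_truth(), conc, 0, 3, seed = 2)
  fH <- fit_hill(serH)
  expect_true(fH$converged)
  expect_equal(coef(fH)[["tau2_0"]], 4.183, tolerance = 1e-6)
  expect_equal(coef(fH)[["tau2_max"]], 3.983, tolerance = 1e-6)
  expect_equal(coef(fH)[["EC50"]], 18e-12, tolerance = 1e-6)
  expect_equal(coef(fH)[["n"]], 1.89, tolerance = 1e-6)
  expect_gt(fH$r2_adj, 0.9999)
})

test_that("noisy titrations recover the half-saturation constant within uncertainty", {
  # a 3-stderr interval misses the truth only in the extreme tail, so over
  # ten seeded titrations at most one miss is tolerated
  conc <- default_concentrations(10)
  hitsH <- hitsL <- logical(10)
  for (s in 1:10) {
    fH <- fit_hill(simulate_response_titration(hill_truth(), conc, 0.009, 3,
                                               seed = s))
    expect_true(fH$converged)
    hitsH[s] <- abs(coef(fH)[["EC50"]] - 18e-12) < 3 * fH$stderr[["EC50"]]

    fL <- fit_langmuir(simulate_response_titration(langmuir_truth(), conc,
                                                   500, 3, seed = s))
    expect_true(fL$converged)
    hitsL[s] <- abs(coef(fL)[["k"]] - 30e-12) < 3 * fL$stderr[["k"]]
  }
  expect_gte(sum(hitsH), 9L)
  expect_gte(sum(hitsL), 9L)
})

test_that("flat titrations report non-convergence instead of raising", {
  conc <- default_concentrations(10)

  # constant intensity + noise (the 10x batch behaviour)
  flatI <- simulate_response_titration(langmuir_params(28890, 28890.001,
                                                       30e-12),
                                       conc, 573, 3, seed = 9)
  fI <- suppressWarnings(fit_langmuir(flatI))
  expect_false(fI$converged)

  # nearly flat lifetime series: 4.008 -> 4.000 ns with sd 0.018
  flatH <- simulate_response_titration(hill_params(4.008, 4.000, 18e-12, 1),
                                       conc, 0.018, 3, seed = 10)
  fF <- suppressWarnings(fit_hill(flatH))
  expect_false(fF$converged)
})

test_that("series shape is validated before fitting", {
  few <- simulate_response_titration(hill_truth(), c(1e-12, 1e-11, 1e-10),
                                     0, 3, seed = 1)
  expect_error(fit_hill(few), ">= 4 distinct")

  # model/response-kind pairing is enforced
  serI <- simulate_response_titration(langmuir_truth(),
                                      default_concentrations(6), 0, 2,
                                      seed = 1)
  expect_error(fit_hill(serI), "lifetime_tau2")
  serH <- simulate_response_titration(hill_truth(),
                                      default_concentrations(6), 0, 2,
                                      seed = 1)
  expect_error(fit_langmuir(serH), "intensity")

  # non-monotone beyond noise: warn but proceed
  x <- default_concentrations(6)
  y <- c(4.2, 4.0, 4.3, 3.9, 3.7, 3.6)
  ser <- titration_series(rep(x, each = 2),
                          rep(y, each = 2) + rep(c(-1e-4, 1e-4), 6),
                          "lifetime_tau2")
  w <- capture_warnings(fit_hill(ser))
  expect_true(any(grepl("non-monotone", w)))
})

test_that("Hill with n = 1 and Langmuir agree on shared-shape data", {
  conc <- default_concentrations(12)
  truth <- hill_params(4.183, 3.983, 30e-12, 1)
  y <- predict_hill(truth, rep(conc, each = 3))
  serH <- titration_series(rep(conc, each = 3), y, "lifetime_tau2")
  serL <- titration_series(rep(conc, each = 3), y, "intensity")
  fH <- fit_hill(serH)
  fL <- fit_langmuir(serL)
  expect_equal(coef(fH)[["EC50"]], coef(fL)[["k"]], tolerance = 1e-9)
  expect_equal(coef(fH)[["n"]], 1, tolerance = 1e-7)
})

test_that("fitted EC50 is equivariant under concentration rescaling", {
  conc <- default_concentrations(10)
  ser <- simulate_response_titration(hill_truth(), conc, 0.003, 3, seed = 11)
  f1 <- fit_hill(ser)
  for (c_scale in c(1e3, 1e-2)) {
    ser2 <- titration_series(ser$data$concentration * c_scale,
                             ser$data$response, "lifetime_tau2",
                             replicate = ser$data$replicate)
    f2 <- fit_hill(ser2)
    expect_equal(coef(f2)[["EC50"]], coef(f1)[["EC50"]] * c_scale,
                 tolerance = 1e-6)
    expect_equal(coef(f2)[["n"]], coef(f1)[["n"]], tolerance = 1e-6)
    expect_equal(coef(f2)[["tau2_0"]], coef(f1)[["tau2_0"]],
                 tolerance = 1e-9)
  }
})

test_that("EC50 estimation is calibrated across seeded simulations", {
  conc <- default_concentrations(10)
  truth <- hill_truth()
  n_sim <- 100
  est <- se <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    f <- suppressWarnings(
      fit_hill(simulate_response_titration(truth, conc, 0.009, 3, seed = s)))
    est[s] <- coef(f)[["EC50"]]
    se[s] <- f$stderr[["EC50"]]
  }
  expect_lt(abs(mean(est) - 18e-12) / 18e-12, 0.10)   # relative bias
  cover <- mean(abs(est - 18e-12) < 2 * se)
  expect_gte(cover, 0.88)
  expect_lte(cover, 0.99)
})

test_that("normalized response maps the transition to 0-100%", {
  p <- hill_truth()
  expect_equal(normalized_response(p, 4.183), 0)
  expect_equal(normalized_response(p, 3.983), 100)
  expect_equal(normalized_response(p, predict_hill(p, 18e-12)), 50)
  expect_error(normalized_response(hill_params(4, 4 + 1e-14, 1e-12, 1), 4),
               "degenerate")
})
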