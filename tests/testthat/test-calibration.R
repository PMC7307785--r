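test_that("EGABA from a single current inverts the Ohmic relation", {
  expect_equal(egaba_from_current(0, 2, -70), -70)
  expect_equal(egaba_from_current(20, 2, -70), -80)
  expect_error(egaba_from_current(10, 0, -70), "> 0")
  # round trip with a GABA-A style current at known reversal
  g <- 1.8; eg <- -74.3; vh <- -60
  I <- g * (vh - eg)
  expect_equal(egaba_from_current(I, g, vh), eg, tolerance = 1e-10)
})

test_that("chloride <-> EGABA conversions invert each other", {
  expect_equal(cl_from_egaba(-77.41), 4.25, tolerance = 1e-3)
  for (cl in c(2, 4.25, 10, 30)) {
    expect_equal(cl_from_egaba(egaba_from_cl(cl)), cl, tolerance = 1e-8)
  }
  # experimental constant set (10/25 mM bicarbonate)
  eg <- egaba_from_cl(5, HCO3_i = 10, HCO3_o = 25)
  expect_equal(cl_from_egaba(eg, HCO3_i = 10, HCO3_o = 25), 5,
               tolerance = 1e-8)
  # EGABA = EHCO3 forces ECl = EHCO3
  cc <- phys_constants()
  EHCO3 <- nernst(-1, 12, 23, cc)
  expect_equal(cl_from_egaba(EHCO3), 135 * exp(EHCO3 / cc$RTF),
               tolerance = 1e-8)
  expect_error(cl_from_egaba(50), "attainable")
})

test_that("recovery fitting recovers the generating pump strength", {
  tr <- generate_recovery(P_true = 0.001, noise_sd = 0)
  fit <- fit_recovery(tr$time_s, tr$cl_mM)
  expect_s3_class(fit, "kcc2_recovery_fit")
  expect_equal(fit$P_conc, 0.001, tolerance = 0.01)
  expect_equal(fit$tau_s, 1 / (0.001 * 140), tolerance = 0.01)
  expect_equal(fit$P_current, 1.9297e-5, tolerance = 0.02)
  # model-interface methods
  expect_named(coef(fit)[1:2], c("P_conc", "P_current"))
  expect_equal(predict(fit), tr$cl_mM, tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-6)
  expect_output(print(fit), "pump-strength")
  expect_output(print(summary(fit)), "rate-line R")
})

test_that("degenerate recovery traces are reported as unidentifiable", {
  t <- seq(2, 90, by = 5)
  expect_error(fit_recovery(t, rep(4.25, length(t))), "unidentifiable")
  expect_error(fit_recovery(t[1:3], c(5, 4.5, 4.3)), "at least 4")
  expect_error(fit_recovery(c(1, 1, 2, 3), c(5, 4.8, 4.5, 4.3)),
               "strictly increasing")
})

test_that("the pump-strength estimator is consistent as noise shrinks", {
  errs <- vapply(c(0.5, 0.1, 0.01), function(sd) {
    est <- vapply(1:20, function(s) {
      tr <- generate_recovery(noise_sd = sd, seed = s)
      fit_recovery(tr$time_s, tr$cl_mM, baseline = 4.25)$P_conc
    }, numeric(1))
    abs(stats::median(est) - 0.001)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-5)
})

test_that("noisy recovery estimates are unbiased within Monte-Carlo bounds", {
  est <- vapply(1:100, function(s) {
    tr <- generate_recovery(noise_sd = 0.3, seed = s)
    fit_recovery(tr$time_s, tr$cl_mM)$P_conc
  }, numeric(1))
  expect_lt(abs(stats::median(est) / 0.001 - 1), 0.1)
  # no systematic sign of bias: both over- and under-estimates occur
  expect_gt(mean(est > 0.001), 0.15)
  expect_gt(mean(est < 0.001), 0.15)
})

test_that("leak tuning hits the target and is idempotent", {
  m <- small_model()
  m$params$leak$gk <- 2e-4   # start well away from the tuned value
  mt <- tune_leaks(m, target_rin = 365)
  expect_equal(mt$tuning$achieved_rin, 365, tolerance = 0.01)
  g <- leak_densities(mt)
  expect_equal(unname(g["gna"] / g["gk"]), 0.23, tolerance = 1e-12)
  expect_equal(unname(g["gcl"] / g["gk"]), 0.4, tolerance = 1e-12)
  # idempotent: re-tuning changes the densities < 0.1%
  mt2 <- tune_leaks(mt, target_rin = 365)
  expect_equal(mt2$params$leak$gk / mt$params$leak$gk, 1, tolerance = 1e-3)
  # passive scaling: doubling every density lowers the input resistance;
  # for a neuron with extended cables the drop lies between the
  # isopotential limit (1/2) and the semi-infinite-cable limit (1/sqrt(2))
  md <- mt
  md$params$leak$gk <- mt$params$leak$gk * 2
  rin2 <- measure_rin(md)
  expect_lt(rin2, 365 / sqrt(2) * 1.02)
  expect_gt(rin2, 365 / 2 * 0.98)
})

test_that("balanced-pair search returns cells in the tolerance band", {
  m <- small_model()
  res <- balanced_pair_search(m, n_exc = c(100, 250), n_inh = c(0, 300),
                              trials = 1, duration = 400, seed = 3)
  expect_equal(dim(res$rates), c(2, 2))
  # monotone in excitation at fixed inhibition
  expect_true(all(res$rates[2, ] >= res$rates[1, ]))
  # a band wider than the observed range returns every cell
  wide <- balanced_pair_search(m, n_exc = c(100, 250), n_inh = c(0, 300),
                               target_hz = mean(res$rates),
                               tol_hz = diff(range(res$rates)) + 100,
                               trials = 1, duration = 400, seed = 3)
  expect_equal(nrow(wide$pairs), 4)
  expect_error(balanced_pair_search(m, numeric(0), 1), "non-empty")
})
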