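test_that("poisson trains have exponential interval statistics", {
  expect_identical(poisson_train(0, 1000, 1), numeric(0))
  expect_error(poisson_train(-1, 100), ">= 0")
  tt <- poisson_train(5, 4e6, seed = 42)
  expect_false(is.unsorted(tt))
  expect_true(all(tt >= 0 & tt < 4e6))
  # law of large numbers: mean ISI within 2% of 200 ms
  expect_equal(mean(diff(tt)), 200, tolerance = 0.02)
  # reproducibility
  expect_identical(tt, poisson_train(5, 4e6, seed = 42))
})

test_that("event counts are Poisson distributed across seeds", {
  lambda <- 5 * 2   # 5 Hz for 2 s
  counts <- vapply(1:1000, function(s) length(poisson_train(5, 2000, s)),
                   numeric(1))
  # chi-square goodness of fit against Poisson(lambda), pooled tails
  ks <- 0:20
  p <- stats::dpois(ks, lambda)
  p[length(p)] <- 1 - sum(p[-length(p)])
  obs <- tabulate(pmin(counts, 20) + 1, nbins = 21)
  keep <- p * 1000 >= 5
  chi <- sum((obs[keep] - 1000 * p[keep])^2 / (1000 * p[keep]))
  expect_lt(chi, stats::qchisq(0.99, sum(keep) - 1))
})

test_that("dual-exponential conductance is normalized with known peak time", {
  expect_equal(dual_exp_conductance(0, 0.2, 1.7), 0)
  expect_equal(dual_exp_conductance(1e5, 0.2, 1.7), 0, tolerance = 1e-12)
  expect_equal(dual_exp_conductance(-3, 0.2, 1.7), 0)
  tp <- dual_exp_peak_time(0.2, 1.7)
  expect_equal(tp, 0.485, tolerance = 1e-2)
  # closed-form argmax agrees with numeric maximization
  num <- stats::optimize(function(t) -dual_exp_conductance(t, 0.2, 1.7),
                         c(0, 10))$minimum
  expect_equal(tp, num, tolerance = 1e-4)
  # unit peak for any valid pair
  for (taus in list(c(0.2, 1.7), c(2.04, 75.2), c(1, 3))) {
    expect_equal(
      dual_exp_conductance(dual_exp_peak_time(taus[1], taus[2]),
                           taus[1], taus[2]), 1, tolerance = 1e-12)
  }
  expect_error(dual_exp_conductance(1, 2, 1), "tau_rise")
})

test_that("NMDA magnesium block is a sigmoid with the stated value at -65 mV", {
  expect_gt(nmda_mg_factor(200), 0.999)
  expect_lt(nmda_mg_factor(-300), 1e-6)
  v <- seq(-90, 40, by = 1)
  expect_true(all(diff(nmda_mg_factor(v)) > 0))
  expect_equal(nmda_mg_factor(-65, mg_mM = 1),
               1 / (1 + (1 / 3.57) * exp(-0.062 * -65)), tolerance = 1e-12)
  expect_equal(nmda_mg_factor(-65), 0.06, tolerance = 0.03)
})

test_that("GABA-A kinetic scheme has the analytic fixed point and decay", {
  expect_equal(gabaa_open_fraction(0, 0, 1), 0)
  # sustained 1 mM transmitter: s -> alpha/(alpha + beta)
  s <- 0
  for (i in 1:2000) s <- gabaa_open_fraction(s, 1, 0.05)
  expect_equal(s, 5 / 5.18, tolerance = 1e-6)
  # free decay with time constant 1/beta
  s1 <- gabaa_open_fraction(0.8, 0, 1 / 0.18)
  expect_equal(s1, 0.8 * exp(-1), tolerance = 1e-12)
})

test_that("GABA-A current splits 4:1 and reverses exactly at EGABA", {
  z <- gabaa_current(0, -60, -92.42, -17.39)
  expect_equal(unname(z), c(0, 0, 0))
  out <- gabaa_current(1, -71.35, -92.42, -17.39)
  expect_equal(out[["ICl"]], 16.86, tolerance = 1e-3)
  expect_equal(out[["IHCO3"]], -10.79, tolerance = 1e-3)
  expect_equal(out[["total"]], 6.06, tolerance = 1e-2)
  # zero crossing at the weighted reversal, components nonzero there
  eg <- egaba_combine(-92.42, -17.39)
  at <- gabaa_current(2.5, eg, -92.42, -17.39)
  expect_equal(at[["total"]], 0, tolerance = 1e-10)
  expect_true(abs(at[["ICl"]]) > 1)
  just_above <- gabaa_current(2.5, eg + 0.01, -92.42, -17.39)[["total"]]
  just_below <- gabaa_current(2.5, eg - 0.01, -92.42, -17.39)[["total"]]
  expect_gt(just_above, 0)
  expect_lt(just_below, 0)
})

test_that("fluctuating conductance matches its moments and is reproducible", {
  expect_identical(fluctuating_conductance(100, 0), numeric(100))
  g <- fluctuating_conductance(1e6, 4, seed = 3)
  expect_true(all(g >= 0))
  expect_equal(mean(g), 4e-4, tolerance = 0.01)
  expect_equal(stats::sd(g) / mean(g), 0.1, tolerance = 0.05)
  expect_identical(g, fluctuating_conductance(1e6, 4, seed = 3))
})

test_that("synapses are placed evenly along the target section", {
  m <- neuron_model()
  idx <- place_synapses(m, "distal", 40)
  expect_length(idx, 40)
  expect_true(all(m$comp$section[idx] == "distal"))
  # even distribution: every distal compartment receives 2 of the 40
  expect_true(all(table(idx) == 2))
  expect_error(place_synapses(m, "dendrite", 5), "unknown section")
})
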