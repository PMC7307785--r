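test_that("the unstimulated model sits at its rest fixed point", {
  m <- neuron_model()
  rs <- rest_state(m)
  sim <- simulate_neuron(m, no_stimulus(), duration = 1000, init = rs,
                         record = "all", record_dt = 10)
  expect_length(sim$spikes, 0)
  drift <- abs(sim$end_state$v - rs$v)
  expect_lt(max(drift), 0.5)
  expect_lt(max(abs(sim$end_state$cl - 4.25)), 0.05)
})

test_that("a small somatic step reports the tuned input resistance", {
  m <- neuron_model()
  rin <- measure_rin(m)
  # the shipped leak densities are tuned for 365 MOhm
  expect_equal(rin, 365, tolerance = 0.02)
  # Ohmic response: doubling the (small) current doubles the deflection
  rin2 <- measure_rin(m, amp_nA = -0.02)
  expect_equal(rin2, rin, tolerance = 0.02)
})

test_that("halving dt leaves the somatic trace essentially unchanged", {
  m <- small_model()
  soma <- section_index(m, "soma")[2]
  run <- function(dt) {
    simulate_neuron(m, no_stimulus(), duration = 700, dt = dt,
                    chloride = "static", record = soma, record_dt = 1,
                    inject = data.frame(comp = "soma", amp_nA = -0.02,
                                        t0 = 200, t1 = 600))$vm[, 1]
  }
  v1 <- run(0.025)
  v2 <- run(0.0125)
  expect_lt(sqrt(mean((v1 - v2)^2)), 0.5)
})

test_that("identical configuration and seeds reproduce bit-for-bit", {
  m <- small_model()
  a <- simulate_neuron(m, fin_stimulus(40, 40, 8), duration = 300, seed = 11)
  b <- simulate_neuron(m, fin_stimulus(40, 40, 8), duration = 300, seed = 11)
  expect_identical(a$vm, b$vm)
  expect_identical(a$cl, b$cl)
  expect_identical(a$spikes, b$spikes)
  g <- simulate_neuron(m, gclamp_stimulus(10, 5), duration = 300, seed = 4)
  h <- simulate_neuron(m, gclamp_stimulus(10, 5), duration = 300, seed = 4)
  expect_identical(g$vm, h$vm)
})

test_that("with chloride fluxes disabled, dynamic and static runs agree", {
  m <- no_cl_flux_model()
  st <- fin_stimulus(60, 0, 10)
  a <- simulate_neuron(m, st, duration = 400, chloride = "dynamic", seed = 5)
  b <- simulate_neuron(m, st, duration = 400, chloride = "static", seed = 5)
  expect_equal(a$vm, b$vm, tolerance = 1e-12)
  expect_identical(a$spikes, b$spikes)
})

test_that("the passive system decays monotonically back to rest", {
  m <- small_model(list(channels = list(gna = 0, gk = 0, gm = 0)))
  soma <- section_index(m, "soma")[2]
  sim <- simulate_neuron(m, no_stimulus(), duration = 400,
                         chloride = "static", record = soma, record_dt = 0.5,
                         inject = data.frame(comp = "soma", amp_nA = 0.05,
                                             t0 = 0, t1 = 100))
  v <- sim$vm[, 1]
  t <- sim$t
  relax <- v[t > 101]
  expect_true(all(diff(relax) < 1e-9))
  expect_equal(relax[length(relax)], v[1], tolerance = 0.05)
})

test_that("numerical divergence is reported with step and compartment", {
  m <- small_model()
  expect_error(
    simulate_neuron(m, no_stimulus(), duration = 100, chloride = "static",
                    inject = data.frame(comp = "soma", amp_nA = 1e4,
                                        t0 = 0, t1 = 100)),
    "numerical failure")
})

test_that("threshold crossing detection finds constructed events", {
  t <- seq(0, 100, by = 0.1)
  v <- rep(-70, length(t))
  expect_identical(detect_spikes(v, t), numeric(0))
  # 7 injected crossings at known times
  at <- c(10, 20, 30, 50, 70, 80, 95)
  for (a in at) v[t >= a & t < a + 0.5] <- 10
  got <- detect_spikes(v, t, threshold = -20, lockout = 2)
  expect_length(got, 7)
  expect_equal(got, at, tolerance = 0.2)
  # doubled sampling rate: same events
  t2 <- seq(0, 100, by = 0.05)
  v2 <- rep(-70, length(t2))
  for (a in at) v2[t2 >= a & t2 < a + 0.5] <- 10
  expect_length(detect_spikes(v2, t2), 7)
  # refractory lockout suppresses double counting
  vv <- rep(-70, length(t))
  vv[t >= 40 & t < 40.2] <- 0
  vv[t >= 40.4 & t < 40.6] <- 0
  expect_length(detect_spikes(vv, t, lockout = 2), 1)
})

test_that("simulation results carry spikes, traces and a config snapshot", {
  m <- small_model()
  sim <- simulate_neuron(m, fin_stimulus(80, 0, 20), duration = 300,
                         seed = 2, record = "soma", record_dt = 1)
  expect_s3_class(sim, "neuron_sim")
  expect_true(all(diff(sim$spikes) > 0))
  expect_equal(ncol(sim$vm), length(section_index(m, "soma")))
  expect_equal(nrow(sim$vm), length(sim$t))
  expect_equal(sim$config$duration, 300)
  expect_output(print(sim), "spikes at axon tip")
})
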