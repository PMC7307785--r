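test_that("Nernst potentials reproduce the default reversal table", {
  expect_equal(nernst(-1, 4.25, 135), -92.42, tolerance = 0.05 / 92)
  expect_equal(nernst(1, 5, 5), 0)
  expect_equal(nernst(-1, 7, 7), 0)
  expect_equal(nernst(1, 140, 4), -95.0, tolerance = 1e-3)
  expect_error(nernst(-1, 0, 135), "> 0")
})

test_that("EGABA is the 4:1 weighted mean of its ionic reversals", {
  expect_equal(egaba_combine(-92.42, -17.39), -77.41, tolerance = 0.05 / 77)
  expect_equal(egaba_combine(-55, -55), -55)
  expect_equal(egaba_combine(-74, -17.39), -62.68, tolerance = 1e-3)
  rv <- reversal_potentials()
  expect_equal(rv[["EGABA"]], -77.41, tolerance = 1e-3)
  expect_equal(rv[["ECl"]], -92.42, tolerance = 1e-3)
})

test_that("a flat profile with no fluxes is a chloride_step fixed point", {
  geo <- list(area_cm2 = rep(1e-7, 5), vol_L = rep(1e-14, 5),
              vol_um3 = rep(10, 5))
  gd <- diffusion_couplings(rep(10, 5), rep(1, 5))
  cl <- rep(6.5, 5)
  out <- chloride_step(cl, rep(0, 5), 0, geo, gd, 0.025)
  expect_equal(out, cl)
})

test_that("two sealed compartments equilibrate to the volume-weighted mean", {
  # analytic equilibrium of a closed two-box diffusion system
  L <- c(10, 10); d <- c(1, 2)
  g1 <- cyl_geometry(L[1], d[1]); g2 <- cyl_geometry(L[2], d[2])
  geo <- list(area_cm2 = c(g1$area_cm2, g2$area_cm2),
              vol_L = c(g1$vol_L, g2$vol_L),
              vol_um3 = c(g1$vol_um3, g2$vol_um3))
  gd <- diffusion_couplings(L, d)
  cl <- c(10, 4)
  total0 <- sum(cl * geo$vol_um3)
  for (i in 1:20000) cl <- chloride_step(cl, c(0, 0), 0, geo, gd, 0.025)
  target <- (10 * g1$vol_um3 + 4 * g2$vol_um3) / (g1$vol_um3 + g2$vol_um3)
  expect_equal(cl, rep(target, 2), tolerance = 1e-6)
  expect_equal(sum(cl * geo$vol_um3) / total0, 1, tolerance = 1e-10)
})

test_that("a closed compartment with KCC2 relaxes to the equilibrium point", {
  # oracle: dense-output reference integration of dCl/dt = -r(Cl)
  skip_if_not_installed("deSolve")
  g <- cyl_geometry(20, 1)
  geo <- list(area_cm2 = g$area_cm2, vol_L = g$vol_L, vol_um3 = g$vol_um3)
  P_cur <- convert_pump_strength(0.001, g$vol_L, g$area_cm2)
  fac <- g$area_cm2 / (phys_constants()$F * g$vol_L) * 1e-3  # mM/ms scale
  rhs <- function(t, y, p) list(-P_cur * (140 * y - 540) * fac)
  ref <- deSolve::ode(c(cl = 10), seq(0, 5000, by = 500), rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  cl <- 10
  path <- cl
  for (i in 1:200000) {
    cl <- chloride_step(cl, 0, P_cur, geo, numeric(0), 0.025)
    if (i %% 20000 == 0) path <- c(path, cl)
  }
  expect_equal(path, unname(ref[, "cl"]), tolerance = 1e-4)
  # monotone decay toward Ko*Clo/Ki; continue on a coarser step until
  # the equilibrium concentration is reached
  expect_true(all(diff(path) < 0))
  for (i in 1:150000) cl <- chloride_step(cl, 0, P_cur, geo, numeric(0), 0.5)
  expect_equal(cl, 540 / 140, tolerance = 1e-3)
})

test_that("chloride underflow is reported with its location", {
  geo <- list(area_cm2 = c(1e-7, 1e-7), vol_L = c(1e-15, 1e-15),
              vol_um3 = c(1, 1))
  gd <- diffusion_couplings(c(10, 10), c(1, 1))
  expect_error(
    chloride_step(c(0.004, 5), c(-1, 0), 0, geo, gd, 1),
    "underflow")
})

test_that("engine diffusion conserves total chloride on a sealed cable", {
  m <- no_cl_flux_model()
  # step concentration profile, diffusion the only active chloride process
  cl0 <- rep(4, m$n)
  cl0[section_index(m, "distal")] <- 12
  sim <- simulate_neuron(m, no_stimulus(), duration = 2000,
                         chloride = "dynamic", init = list(cl = cl0),
                         record = m$n, record_dt = 2000)
  total0 <- sum(cl0 * m$comp$vol_um3)
  total1 <- sum(sim$end_state$cl * m$comp$vol_um3)
  expect_equal(total1 / total0, 1, tolerance = 1e-8)
  # the step profile relaxes: distal falls, elsewhere rises
  expect_lt(max(sim$end_state$cl), 12)
  expect_gt(min(sim$end_state$cl), 4)
})

test_that("engine chloride relaxation matches the R reference step", {
  # identical explicit update: C++ engine vs chloride_step, diffusion +
  # KCC2 only (leaks and synapses off), small model
  m <- no_cl_flux_model()
  m$params$kcc2$scale[] <- 100
  cl0 <- seq(4, 10, length.out = m$n)
  sim <- simulate_neuron(m, no_stimulus(), duration = 50,
                         chloride = "dynamic", init = list(cl = cl0),
                         record = m$n, record_dt = 50)
  geo <- list(area_cm2 = m$comp$area_cm2, vol_L = m$comp$vol_L,
              vol_um3 = m$comp$vol_um3)
  kscale <- m$params$kcc2$scale[m$comp$section] / 100
  cl <- cl0
  for (i in 1:2000) {
    cl <- chloride_step(cl, rep(0, m$n), m$params$kcc2$P * kscale, geo,
                        m$interfaces$g_diff, 0.025)
  }
  expect_equal(sim$end_state$cl, unname(cl), tolerance = 1e-9)
})

test_that("a fine-cable step profile approaches the analytic diffusion limit", {
  # sealed uniform cable, step initial condition; analytic solution by
  # cosine eigenfunction expansion
  ncomp <- c(20, 60)
  errs <- vapply(ncomp, function(nc) {
    L <- 200; d <- 1; D <- 2.03
    Lc <- L / nc
    geo_one <- cyl_geometry(Lc, d)
    geo <- list(area_cm2 = rep(geo_one$area_cm2, nc),
                vol_L = rep(geo_one$vol_L, nc),
                vol_um3 = rep(geo_one$vol_um3, nc))
    gd <- diffusion_couplings(rep(Lc, nc), rep(d, nc), D)
    x <- (seq_len(nc) - 0.5) * Lc
    cl <- ifelse(x < L / 2, 10, 2)
    tend <- 500
    dt <- 0.025
    for (i in seq_len(tend / dt)) {
      cl <- chloride_step(cl, rep(0, nc), 0, geo, gd, dt)
    }
    modes <- 1:200
    ana <- 6 + Reduce(`+`, lapply(modes, function(k) {
      bk <- 16 / (k * pi) * sin(k * pi / 2)  # step about its mean of 6
      bk * cos(k * pi * x / L) * exp(-D * (k * pi / L)^2 * tend)
    }))
    sqrt(mean((cl - ana)^2))
  }, numeric(1))
  expect_lt(errs[2], errs[1])            # L2 error decreases with refinement
  expect_lt(errs[2], 0.05)
})

test_that("dynamic potassium holds rest and tracks EK under drive", {
  m <- enable_dynamic_potassium(small_model())
  sim <- simulate_neuron(m, no_stimulus(), duration = 10000,
                         record = m$n, record_dt = 1000)
  expect_lt(max(abs(sim$end_state$cl - 4.25)) / 4.25, 0.01)
  expect_lt(max(abs(sim$end_state$ki - 140)) / 140, 0.01)
  # sustained strong distal drive moves [K+]i (KCC2 potassium efflux)
  sim2 <- simulate_neuron(m, gclamp_stimulus(12, 8), duration = 500,
                          seed = 1, record = m$n, record_dt = 500)
  expect_lt(min(sim2$end_state$ki), 139)
})
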