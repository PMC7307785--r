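test_that("mean rate is count over window", {
  expect_equal(mean_rate(c(10, 200, 300, 700, 900), 1000), 5)
  expect_equal(mean_rate(numeric(0), 1000), 0)
  # additivity over disjoint equal windows
  sp <- c(runif(7, 0, 500), runif(3, 500, 1000))
  r1 <- mean_rate(sp[sp < 500], 500)
  r2 <- mean_rate(sp[sp >= 500], 500)
  expect_equal(mean_rate(sp, 1000), (r1 + r2) / 2)
  expect_error(mean_rate(1, 0), "> 0")
})

test_that("instantaneous firing rate implements the pooled-window formula", {
  trains <- list(c(95), c(92, 99), numeric(0), numeric(0), numeric(0))
  expect_equal(ifr(trains, 100, 20), 3 / (5 * 0.02))
  expect_equal(ifr(list(numeric(0)), c(50, 100)), c(0, 0))
  # identical trials reduce to the single-trial windowed rate
  tr <- c(30, 45, 61, 88)
  expect_equal(ifr(replicate(4, tr, simplify = FALSE), 90, 20),
               ifr(list(tr), 90, 20))
  expect_warning(ifr(list(tr), 10, 20), "truncated")
  # integral over contiguous bins recovers total count / K
  trains2 <- list(c(15, 35, 77), c(5, 55))
  bins <- seq(20, 100, by = 20)
  counts <- sum(ifr(trains2, bins, 20)) * 0.02
  expect_equal(counts, 5 / 2)
})

test_that("x50 extraction matches the logistic midpoint and translates", {
  x <- seq(0, 20, by = 0.1)
  mk <- function(shift) data.frame(x = x,
    rate = 60 / (1 + exp(-(x - 8 - shift))))
  h <- half_max(mk(0))
  expect_equal(h$x50, 8, tolerance = 0.05)
  # right-shifting the curve shifts x50 by exactly the shift
  h2 <- half_max(mk(3))
  expect_equal(h2$x50 - h$x50, 3, tolerance = 0.05)
  expect_error(half_max(data.frame(x = x, rate = 0 * x)), "never fires")
  expect_error(half_max(data.frame(x = 1:3, rate = c(0, 1, 2)),
                        max_rate = 60), "does not reach")
})

test_that("the chloride index follows the offset formula and its identities", {
  x <- seq(0, 10, by = 0.5)
  logi <- function(mid) data.frame(x = x, rate = 40 / (1 + exp(-2 * (x - mid))))
  no_inh <- logi(2); dyn <- logi(3); sta <- logi(4)
  ci <- chloride_index(dyn, sta, no_inh)
  expect_equal(ci$a, 1, tolerance = 0.02)
  expect_equal(ci$b, 2, tolerance = 0.02)
  expect_equal(ci$index, 0.5, tolerance = 0.02)
  # dynamic == static -> index 0
  ci0 <- chloride_index(sta, sta, no_inh)
  expect_equal(ci0$index, 0, tolerance = 1e-10)
  # dynamic == no-inhibition -> index 1
  ci1 <- chloride_index(no_inh, sta, no_inh)
  expect_equal(ci1$index, 1, tolerance = 1e-10)
  # b = 0 is undefined
  expect_error(chloride_index(no_inh, no_inh, no_inh), "undefined")
})

test_that("the chloride index ignores affine rescaling of the rate axis", {
  x <- seq(0, 10, by = 0.25)
  logi <- function(mid, a = 1, b = 0) {
    data.frame(x = x, rate = b + a * 50 / (1 + exp(-3 * (x - mid))))
  }
  ci <- chloride_index(logi(4), logi(6), logi(2))
  ci_scaled <- chloride_index(logi(4, 0.37), logi(6, 0.37), logi(2, 0.37))
  expect_equal(ci_scaled$index, ci$index, tolerance = 1e-6)
})

test_that("input-output curves rise with excitatory drive", {
  m <- small_model()
  cv <- io_curve(m, c(50, 150, 300), 0, "synapses", "static",
                 trials = 1, duration = 500, seed = 6)
  expect_s3_class(cv, "io_curve")
  r <- cv$curve$rate
  expect_true(all(diff(r) >= -1))   # non-decreasing up to sampling jitter
  expect_gt(r[3], r[1])
  expect_error(io_curve(m, numeric(0)), "non-empty")
  expect_error(io_curve(m, c(3, 1, 2)), "sorted")
})

test_that("distal inhibition under static chloride shifts x50 rightward", {
  m <- small_model()
  grid <- seq(0, 44, by = 4)
  ref <- io_curve(m, grid, 0, "conductance", "static", trials = 1,
                  duration = 600, seed = 9)
  inh <- io_curve(m, grid, 8, "conductance", "static", trials = 1,
                  duration = 600, seed = 9)
  h0 <- half_max(ref)
  h8 <- half_max(inh, max_rate = h0$max_rate)
  expect_gt(h8$x50, h0$x50)
})

test_that("index sweeps run end to end and validate their input", {
  tab <- data.frame(pkcc2_pct = c(50, 100), distal_diam = c(0.5, 0.5),
                    inhibition = c(6, 6))
  sw <- index_egaba_sweep(tab, small_model(), grid = seq(0, 32, by = 8),
                          trials = 1, seed = 2)
  expect_s3_class(sw, "chloride_index_sweep")
  expect_equal(sw$n_undefined, 0)
  expect_true(all(is.finite(sw$table$index)))
  expect_true(all(is.finite(sw$table$degaba)))
  # weaker extrusion accumulates more chloride: larger index and dEGABA
  expect_gt(sw$table$index[1], sw$table$index[2])
  expect_gt(sw$table$degaba[1], sw$table$degaba[2])
  expect_error(index_egaba_sweep(tab[0, ], small_model()), "non-empty")
})
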