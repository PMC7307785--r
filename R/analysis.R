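#' Mean firing rate from spike times
#'
#' @param spikes spike times (ms).
#' @param window_ms counting window (ms).
#' @return rate (Hz).
#' @export
mean_rate <- function(spikes, window_ms = 1000) {
  if (window_ms <= 0) stop("window must be > 0")
  1000 * length(spikes) / window_ms
}

#' Instantaneous firing rate pooled over trials
#'
#' `IFR(t) = (1 / (K dt)) * sum_k n_k(t)` where `n_k(t)` counts trial-k
#' spikes in the backward window `[t - dt, t]`.
#'
#' @param spike_trains list of spike-time vectors (ms), one per trial.
#' @param t evaluation time(s) (ms).
#' @param delta_ms time bin (ms), default 20.
#' @return IFR (Hz), same length as `t`.
#' @export
ifr <- function(spike_trains, t, delta_ms = 20) {
  if (!length(spike_trains)) stop("need at least one trial")
  if (delta_ms <= 0) stop("time bin must be > 0")
  if (any(t < delta_ms)) {
    warning("window truncated: some t < delta_ms")
  }
  K <- length(spike_trains)
  vapply(t, function(tt) {
    cnt <- sum(vapply(spike_trains, function(sp) {
      sum(sp > tt - delta_ms & sp <= tt)
    }, numeric(1)))
    cnt / (K * delta_ms / 1000)
  }, numeric(1))
}

#' Neuronal input-output curve
#'
#' Mean output firing rate (over trials) as a function of excitatory drive,
#' at a fixed inhibition level, in a fixed chloride mode.  The abscissa is
#' either a grid of excitatory synapse counts (event-driven drive) or of
#' relative excitatory conductances (fluctuating-conductance drive).
#'
#' @param model a (tuned) [neuron_model()].
#' @param grid abscissa grid, sorted ascending.
#' @param inhibition inhibition level: number of inhibitory synapses
#'   (`abscissa = "synapses"`) or relative inhibitory conductance
#'   (`abscissa = "conductance"`).
#' @param abscissa `"conductance"` (gclamp drive) or `"synapses"` (f-in).
#' @param chloride chloride mode for the runs.
#' @param trials trials per grid point.
#' @param duration simulation length (ms).
#' @param rate_hz per-synapse input frequency for the f-in drive (Hz).
#' @param inh_section section receiving inhibition.
#' @param seed master seed; each (grid point, trial) gets its own stream.
#' @param keep_degaba if `TRUE`, record the end-of-run distal EGABA shift of
#'   every run.
#' @return object of class `io_curve`: data.frame of `x`, `rate` plus
#'   per-run detail and metadata.
#' @export
io_curve <- function(model, grid, inhibition = 0,
                     abscissa = c("conductance", "synapses"),
                     chloride = c("dynamic", "static"),
                     trials = 3, duration = 1000, rate_hz = 5,
                     inh_section = "distal", seed = 1,
                     keep_degaba = FALSE) {
  abscissa <- match.arg(abscissa)
  chloride <- match.arg(chloride)
  if (!length(grid)) stop("grid must be non-empty")
  if (is.unsorted(grid)) stop("grid must be sorted ascending")
  rates <- matrix(NA_real_, length(grid), trials)
  degaba <- matrix(NA_real_, length(grid), trials)
  for (i in seq_along(grid)) {
    for (k in seq_len(trials)) {
      stim <- if (abscissa == "conductance") {
        gclamp_stimulus(rel_exc = grid[i], rel_inh = inhibition,
                        inh_section = inh_section)
      } else {
        fin_stimulus(n_exc = grid[i], n_inh = inhibition, rate_hz = rate_hz,
                     inh_section = inh_section)
      }
      sim <- simulate_neuron(model, stim, duration = duration,
                             chloride = chloride,
                             seed = subseed(seed, i * 1000 + k),
                             record = model$n, record_dt = duration)
      rates[i, k] <- mean_rate(sim$spikes, duration)
      if (keep_degaba) degaba[i, k] <- distal_degaba(sim)
    }
  }
  structure(list(
    curve = data.frame(x = grid, rate = rowMeans(rates)),
    rates = rates, degaba = if (keep_degaba) rowMeans(degaba) else NULL,
    abscissa = abscissa, chloride = chloride, inhibition = inhibition,
    trials = trials, duration = duration
  ), class = "io_curve")
}

#' @export
print.io_curve <- function(x, ...) {
  cat(sprintf("input-output curve (%s abscissa, %s chloride, i = %g, %d trials)\n",
              x$abscissa, x$chloride, x$inhibition, x$trials))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' @export
plot.io_curve <- function(x, ...) {
  graphics::plot(x$curve$x, x$curve$rate, type = "b",
                 xlab = if (x$abscissa == "conductance")
                   "relative excitatory conductance" else "excitatory synapses",
                 ylab = "output rate (Hz)", ...)
  invisible(x)
}

#' Abscissa at half-maximal firing rate
#'
#' `x50` is extracted by piecewise-linear interpolation of the rising limb
#' of the (trial-averaged) curve: the first upward crossing of half the
#' reference maximum.  The rising limb is made monotone with a running
#' maximum before interpolating, which suppresses sampling jitter.
#'
#' @param curve an [io_curve()] or a data.frame with columns `x`, `rate`.
#' @param max_rate reference maximal rate; defaults to the curve's own
#'   maximum.  For distally inhibited curves pass the no-inhibition
#'   plateau, which distal inhibition does not change.
#' @return list with `x50`, `half_rate`, `max_rate`.
#' @export
half_max <- function(curve, max_rate = NULL) {
  df <- if (inherits(curve, "io_curve")) curve$curve else as.data.frame(curve)
  if (is.null(max_rate)) max_rate <- max(df$rate)
  if (max_rate <= 0) stop("curve never fires: x50 undefined")
  half <- max_rate / 2
  r <- cummax(df$rate)              # monotone rising limb
  if (max(r) < half) {
    stop("curve does not reach half of the reference maximum: x50 undefined")
  }
  i <- which(r >= half)[1]
  if (i == 1) {
    x50 <- df$x[1]
  } else {
    x0 <- df$x[i - 1]; x1 <- df$x[i]
    r0 <- r[i - 1]; r1 <- r[i]
    x50 <- x0 + (half - r0) / (r1 - r0) * (x1 - x0)
  }
  list(x50 = x50, half_rate = half, max_rate = max_rate)
}

#' The chloride index
#'
#' Quantifies how much chloride dynamics erode the input-output offset
#' produced by inhibition: with `a = x50(dynamic, i) - x50(i = 0)` and
#' `b = x50(static, i) - x50(i = 0)`, the index is `1 - a/b`.  Zero means
#' chloride dynamics are irrelevant; one means the dynamic-chloride offset
#' vanished entirely.
#'
#' @param curve_dynamic,curve_static [io_curve()]s at the same inhibition
#'   level, dynamic and static chloride.
#' @param curve_no_inh the no-inhibition reference curve.
#' @return object of class `chloride_index`: list with `a`, `b`, `index`,
#'   the three `x50` values, and `degaba` (distal EGABA shift of the
#'   dynamic run, if it was recorded).
#' @export
chloride_index <- function(curve_dynamic, curve_static, curve_no_inh) {
  ref <- half_max(curve_no_inh)
  h_dyn <- half_max(curve_dynamic, max_rate = ref$max_rate)
  h_sta <- half_max(curve_static, max_rate = ref$max_rate)
  a <- h_dyn$x50 - ref$x50
  b <- h_sta$x50 - ref$x50
  if (abs(b) < .Machine$double.eps^0.5) {
    stop("static-chloride offset b = 0: chloride index undefined")
  }
  degaba <- NA_real_
  if (inherits(curve_dynamic, "io_curve") && !is.null(curve_dynamic$degaba)) {
    # EGABA shift taken at the grid point nearest the dynamic x50, where
    # the input-output offset itself is measured
    i <- which.min(abs(curve_dynamic$curve$x - h_dyn$x50))
    degaba <- curve_dynamic$degaba[i]
  }
  structure(list(a = a, b = b, index = 1 - a / b,
                 x50_dynamic = h_dyn$x50, x50_static = h_sta$x50,
                 x50_no_inh = ref$x50, degaba = degaba),
            class = "chloride_index")
}

#' @export
print.chloride_index <- function(x, ...) {
  cat(sprintf("chloride index = %.3f  (a = %.3f, b = %.3f)\n",
              x$index, x$a, x$b))
  cat(sprintf("  x50: no-inh %.3f | dynamic %.3f | static %.3f\n",
              x$x50_no_inh, x$x50_dynamic, x$x50_static))
  if (is.finite(x$degaba)) {
    cat(sprintf("  distal EGABA shift (dynamic run): %+.2f mV\n", x$degaba))
  }
  invisible(x)
}

#' Full chloride-index protocol for one model configuration
#'
#' Runs the three input-output curves (no inhibition, dynamic and static
#' chloride at inhibition `i`) under the fluctuating-conductance drive and
#' returns the chloride index with the distal EGABA shift attached.
#'
#' @param model the model configuration.
#' @param inhibition relative inhibitory conductance `i`.
#' @param grid excitatory relative-conductance grid.
#' @param trials,duration,seed as in [io_curve()]; trials defaults to the
#'   protocol's 3-trial averaging.
#' @param curve_no_inh optionally a precomputed no-inhibition reference
#'   curve (shared across inhibition levels).
#' @return a `chloride_index` object.
#' @export
chloride_index_protocol <- function(model, inhibition,
                                    grid = seq(0, 32, by = 2),
                                    trials = 3, duration = 1000, seed = 1,
                                    curve_no_inh = NULL) {
  if (is.null(curve_no_inh)) {
    curve_no_inh <- io_curve(model, grid, 0, "conductance", "static",
                             trials = trials, duration = duration,
                             seed = subseed(seed, 1))
  }
  cd <- io_curve(model, grid, inhibition, "conductance", "dynamic",
                 trials = trials, duration = duration,
                 seed = subseed(seed, 2), keep_degaba = TRUE)
  cs <- io_curve(model, grid, inhibition, "conductance", "static",
                 trials = trials, duration = duration,
                 seed = subseed(seed, 3))
  chloride_index(cd, cs, curve_no_inh)
}

#' Sweep of chloride index versus distal EGABA shift
#'
#' Runs the chloride-index protocol over a grid of model manipulations
#' (KCC2 pump strength, distal diameter, input-resistance scaling, distal
#' KCC2 scaling, run duration, dynamic potassium) and correlates the index
#' with the end-of-run distal EGABA shift across all sweep points.
#'
#' @param sweep data.frame with any of the columns `pkcc2_pct`,
#'   `distal_diam`, `rin_scale`, `distal_kcc2_pct`, `duration`,
#'   `dynamic_k`, `inhibition`.  Missing columns take defaults.
#' @param base_model base model (tuned); per-row overrides are applied on
#'   top of it.
#' @param grid excitatory conductance grid passed to the protocol.
#' @param trials trials per grid point.
#' @param seed master seed.
#' @param progress print one line per sweep point.
#' @return object of class `chloride_index_sweep`: the sweep table with
#'   `index` and `degaba` columns, the Pearson `r` (and its test), and the
#'   count of sweep points where the index was undefined.
#' @export
index_egaba_sweep <- function(sweep, base_model = NULL,
                              grid = seq(0, 32, by = 2), trials = 3,
                              seed = 1, progress = FALSE) {
  if (!nrow(sweep)) stop("sweep must be non-empty")
  if (is.null(base_model)) base_model <- neuron_model()
  defaults <- list(pkcc2_pct = 100, distal_diam = NULL, rin_scale = 1,
                   distal_kcc2_pct = NULL, duration = 1000,
                   dynamic_k = FALSE, inhibition = 4)
  for (nm in names(defaults)) {
    if (!nm %in% names(sweep)) sweep[[nm]] <- defaults[[nm]] %||% NA
  }
  sweep$index <- NA_real_
  sweep$degaba <- NA_real_
  # cache the no-inhibition reference per distinct model configuration
  cfg_key <- function(row) paste(row$pkcc2_pct, row$distal_diam,
                                 row$rin_scale, row$distal_kcc2_pct,
                                 row$duration, row$dynamic_k)
  ref_cache <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(sweep))) {
    row <- sweep[r, ]
    pp <- base_model$params
    pp$kcc2$scale <- pp$kcc2$scale * row$pkcc2_pct / 100
    if (!is.na(row$distal_kcc2_pct)) {
      pp$kcc2$scale[["distal"]] <-
        pp$kcc2$scale[["distal"]] * row$distal_kcc2_pct / 100
    }
    if (!is.na(row$distal_diam)) pp$sections$distal$diam <- row$distal_diam
    if (row$rin_scale != 1) pp$leak$gk <- pp$leak$gk / row$rin_scale
    m <- neuron_model(pp)
    if (isTRUE(row$dynamic_k)) m <- enable_dynamic_potassium(m)
    key <- cfg_key(row)
    ref <- if (!is.null(ref_cache[[key]])) ref_cache[[key]] else {
      ref_cache[[key]] <- io_curve(
        m, grid, 0, "conductance", "static", trials = trials,
        duration = row$duration, seed = subseed(seed, r))
      ref_cache[[key]]
    }
    ci <- tryCatch(
      chloride_index_protocol(m, row$inhibition, grid, trials,
                              row$duration, seed = subseed(seed, 100 + r),
                              curve_no_inh = ref),
      error = function(e) NULL)
    if (!is.null(ci)) {
      sweep$index[r] <- ci$index
      sweep$degaba[r] <- ci$degaba
    }
    if (progress) {
      message(sprintf("sweep %d/%d: index %.3f, dEGABA %+.2f mV",
                      r, nrow(sweep), sweep$index[r], sweep$degaba[r]))
    }
  }
  ok <- is.finite(sweep$index) & is.finite(sweep$degaba)
  if (sum(ok) >= 3 && stats::sd(sweep$index[ok]) > 0 &&
      stats::sd(sweep$degaba[ok]) > 0) {
    ct <- stats::cor.test(sweep$index[ok], sweep$degaba[ok])
    r_pearson <- unname(ct$estimate)
  } else {
    ct <- NULL
    r_pearson <- NA_real_
    if (sum(ok) >= 3) warning("zero variance across sweep: correlation undefined")
  }
  structure(list(table = sweep, r = r_pearson, cor_test = ct,
                 n_undefined = sum(!ok)),
            class = "chloride_index_sweep")
}

#' @export
print.chloride_index_sweep <- function(x, ...) {
  ok <- is.finite(x$table$index)
  cat(sprintf("chloride index sweep: %d points (%d undefined)\n",
              nrow(x$table), x$n_undefined))
  cat(sprintf("  Pearson r(index, dEGABA) = %.4f\n", x$r))
  if (!is.null(x$cor_test)) {
    cat(sprintf("  p = %.3g over n = %d points\n", x$cor_test$p.value, sum(ok)))
  }
  invisible(x)
}

#' @export
plot.chloride_index_sweep <- function(x, ...) {
  ok <- is.finite(x$table$index) & is.finite(x$table$degaba)
  graphics::plot(x$table$degaba[ok], x$table$index[ok],
                 xlab = "distal EGABA shift (mV)", ylab = "chloride index",
                 ...)
  invisible(x)
}
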