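#' EGABA from a single GABA-A current
#'
#' Solves `I = g (Vhold - EGABA)` for EGABA, the single-current estimation
#' used once the resting conductance is known.
#'
#' @param I current (pA, positive outward).
#' @param g GABA-A conductance (nS).
#' @param Vhold holding potential (mV).
#' @return EGABA (mV).
#' @export
egaba_from_current <- function(I, g, Vhold) {
  if (any(g <= 0)) stop("conductance must be > 0")
  Vhold - I / g
}

#' Intracellular chloride from EGABA
#'
#' Inverts the 4:1 permeability-weighted reversal relation
#' `EGABA = (4/5) ECl + (1/5) EHCO3` and the Nernst equation for `[Cl-]i`.
#' Two constant sets are supported: the model defaults
#' (`[HCO3-]i/o = 12/23 mM`) and the experimental-analysis set (10/25 mM).
#'
#' @param EGABA reversal potential (mV).
#' @param HCO3_i,HCO3_o bicarbonate concentrations (mM).
#' @param Cl_o extracellular chloride (mM).
#' @param constants physical constants.
#' @return `[Cl-]i` (mM).
#' @export
#' @examples
#' cl_from_egaba(-77.41)  # ~4.25 mM
cl_from_egaba <- function(EGABA, HCO3_i = 12, HCO3_o = 23, Cl_o = 135,
                          constants = phys_constants()) {
  if (any(c(HCO3_i, HCO3_o, Cl_o) <= 0)) stop("concentrations must be > 0")
  EHCO3 <- nernst(-1, HCO3_i, HCO3_o, constants)
  ECl <- (EGABA - 0.2 * EHCO3) / 0.8
  cl <- Cl_o * exp(ECl / constants$RTF)
  if (any(cl >= Cl_o) || any(cl <= 0)) {
    stop("EGABA outside the physically attainable range for these ",
         "bicarbonate concentrations")
  }
  cl
}

#' Forward computation: EGABA from intracellular chloride
#' @param Cl_i intracellular chloride (mM).
#' @inheritParams cl_from_egaba
#' @return EGABA (mV).
#' @export
egaba_from_cl <- function(Cl_i, HCO3_i = 12, HCO3_o = 23, Cl_o = 135,
                          constants = phys_constants()) {
  egaba_combine(nernst(-1, Cl_i, Cl_o, constants),
                nernst(-1, HCO3_i, HCO3_o, constants))
}

#' Estimate the KCC2 pump strength from a chloride-recovery trace
#'
#' Reproduces the perforated-patch analysis: the `[Cl-]i` recovery after a
#' chloride load is fitted with a single exponential
#' `Cl(t) = baseline + A exp(-t / tau)`; the fitted curve is differentiated
#' analytically to give the extrusion rate `V(t) = -dCl/dt`, which is then
#' regressed linearly on the KCC2 bracket `[K+]i Cl(t) - [K+]o [Cl-]o`.
#' The slope of that line is the pump strength estimate.
#'
#' @param time_s sample times (s), strictly increasing, at least 4.
#' @param cl_mM `[Cl-]i` samples (mM).
#' @param baseline known resting `[Cl-]i` (mM); if `NULL` the baseline is a
#'   free fit parameter.
#' @param Ki,Ko,Clo fixed concentrations (mM).
#' @param cell_volume_L,cell_area_cm2 geometry used to express the estimate
#'   in current-density units (defaults: the recorded-cell values).
#' @return An object of class `kcc2_recovery_fit` with components
#'   `P_conc` (mM^-1 s^-1), `P_current` (mA mM^-2 cm^-2), `tau_s`,
#'   `baseline`, `amplitude`, the underlying `nls` fit, the rate-regression
#'   `lm`, and the data.
#' @export
fit_recovery <- function(time_s, cl_mM, baseline = NULL,
                         Ki = 140, Ko = 4, Clo = 135,
                         cell_volume_L = 1.058e-12, cell_area_cm2 = 529e-8) {
  if (length(time_s) < 4) stop("need at least 4 samples to fit a recovery")
  if (any(diff(time_s) <= 0)) stop("sample times must be strictly increasing")
  if (length(time_s) != length(cl_mM)) stop("time and concentration lengths differ")
  if (stats::sd(cl_mM) < 1e-9) {
    stop("trace already at baseline: extrusion rate regression is ",
         "unidentifiable")
  }
  a0 <- max(cl_mM[1] - (baseline %||% min(cl_mM)), 1e-3)
  tau0 <- max(diff(range(time_s)) / 3, 1e-3)
  df <- data.frame(t = time_s, cl = cl_mM)
  if (is.null(baseline)) {
    fit <- minpack.lm::nlsLM(cl ~ b + A * exp(-t / tau), data = df,
                             start = list(b = min(cl_mM), A = a0, tau = tau0),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    b <- stats::coef(fit)[["b"]]
  } else {
    b <- baseline
    fit <- minpack.lm::nlsLM(cl ~ b + A * exp(-t / tau), data = df,
                             start = list(A = a0, tau = tau0),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  A <- stats::coef(fit)[["A"]]
  tau <- stats::coef(fit)[["tau"]]
  if (!is.finite(tau) || tau <= 0) stop("recovery fit gave a non-positive tau")
  if (abs(A) < 1e-6) {
    stop("trace already at baseline: extrusion rate regression is ",
         "unidentifiable")
  }
  # analytic derivative of the fitted exponential at the sample times
  cl_fit <- b + A * exp(-time_s / tau)
  v_extrusion <- (A / tau) * exp(-time_s / tau)    # -dCl/dt, mM/s
  bracket <- Ki * cl_fit - Ko * Clo                # mM^2
  reg <- stats::lm(v_extrusion ~ bracket)
  P <- unname(stats::coef(reg)[["bracket"]])
  structure(list(
    P_conc = P,
    P_current = convert_pump_strength(P, cell_volume_L, cell_area_cm2),
    tau_s = tau, baseline = b, amplitude = A,
    exp_fit = fit, rate_fit = reg,
    data = df,
    cell_volume_L = cell_volume_L, cell_area_cm2 = cell_area_cm2,
    Ki = Ki, Ko = Ko, Clo = Clo
  ), class = "kcc2_recovery_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kcc2_recovery_fit <- function(x, ...) {
  cat("KCC2 pump-strength estimate from chloride recovery\n")
  cat(sprintf("  tau = %.3g s, baseline = %.3g mM, amplitude = %.3g mM\n",
              x$tau_s, x$baseline, x$amplitude))
  cat(sprintf("  P = %.4g mM^-1 s^-1  =  %.4g mA mM^-2 cm^-2\n",
              x$P_conc, x$P_current))
  invisible(x)
}

#' @export
summary.kcc2_recovery_fit <- function(object, ...) {
  res <- stats::residuals(object$exp_fit)
  out <- list(P_conc = object$P_conc, P_current = object$P_current,
              tau_s = object$tau_s, baseline = object$baseline,
              amplitude = object$amplitude,
              rmse_mM = sqrt(mean(res^2)), n = nrow(object$data),
              rate_r_squared = suppressWarnings(summary(object$rate_fit))$r.squared)
  class(out) <- "summary.kcc2_recovery_fit"
  out
}

#' @export
print.summary.kcc2_recovery_fit <- function(x, ...) {
  cat("KCC2 recovery fit summary\n")
  cat(sprintf("  n = %d samples, residual RMSE = %.3g mM\n", x$n, x$rmse_mM))
  cat(sprintf("  tau = %.4g s, baseline = %.4g mM, amplitude = %.4g mM\n",
              x$tau_s, x$baseline, x$amplitude))
  cat(sprintf("  P = %.5g mM^-1 s^-1 (%.5g mA mM^-2 cm^-2), ",
              x$P_conc, x$P_current))
  cat(sprintf("rate-line R^2 = %.4f\n", x$rate_r_squared))
  invisible(x)
}

#' @export
coef.kcc2_recovery_fit <- function(object, ...) {
  c(P_conc = object$P_conc, P_current = object$P_current,
    tau_s = object$tau_s, baseline = object$baseline,
    amplitude = object$amplitude)
}

#' @export
predict.kcc2_recovery_fit <- function(object, time_s = NULL, ...) {
  if (is.null(time_s)) time_s <- object$data$t
  object$baseline + object$amplitude * exp(-time_s / object$tau_s)
}

#' @export
residuals.kcc2_recovery_fit <- function(object, ...) {
  object$data$cl - predict(object)
}

#' @export
plot.kcc2_recovery_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$cl, xlab = "time after load (s)",
                 ylab = "[Cl-]i (mM)", ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Measure somatic input resistance with a hyperpolarizing step
#'
#' A small somatic current step (default -10 pA for 500 ms) after a settling
#' period; Rin is the plateau voltage deflection divided by the injected
#' current.  Chloride is held static during the measurement.
#'
#' @param model a [neuron_model()].
#' @param amp_nA step amplitude (nA).
#' @param settle_ms settling time before the step (ms).
#' @param step_ms step duration (ms).
#' @param dt time step (ms).
#' @return input resistance (MOhm).
#' @export
measure_rin <- function(model, amp_nA = -0.01, settle_ms = 300,
                        step_ms = 500, dt = 0.025) {
  soma <- section_index(model, "soma")
  mid <- soma[ceiling(length(soma) / 2)]
  dur <- settle_ms + step_ms
  sim <- simulate_neuron(
    model, no_stimulus(), duration = dur, dt = dt, chloride = "static",
    record = mid, record_dt = 1,
    inject = data.frame(comp = mid, amp_nA = amp_nA,
                        t0 = settle_ms, t1 = dur))
  v <- sim$vm[, 1]
  t <- sim$t
  v_base <- mean(v[t > settle_ms - 50 & t <= settle_ms])
  v_plat <- mean(v[t > dur - 50])
  (v_plat - v_base) / amp_nA   # mV / nA = MOhm
}

#' Tune leak conductances to a target input resistance
#'
#' Scales the common leak magnitude, with the K:Na:Cl ratio fixed, until
#' the measured somatic input resistance is within `tol` of the target.
#' Optionally reports the emergent resting state of the tuned model (with
#' KCC2 active and chloride dynamic).
#'
#' @param model a [neuron_model()].
#' @param target_rin target input resistance (MOhm).
#' @param tol relative tolerance on the achieved Rin.
#' @param report_rest if `TRUE`, run an unstimulated simulation and report
#'   the emergent resting Vm and `[Cl-]i`.
#' @param rest_ms duration of the rest-state run (ms).
#' @param max_iter iteration cap for the scaling search.
#' @return the tuned model, with a `$tuning` element recording the achieved
#'   Rin, the leak densities, and (optionally) the resting state.
#' @export
tune_leaks <- function(model, target_rin = 365, tol = 0.01,
                       report_rest = FALSE, rest_ms = 3000, max_iter = 12) {
  if (target_rin <= 0) stop("target input resistance must be > 0")
  gk <- model$params$leak$gk
  rin <- NA_real_
  for (i in seq_len(max_iter)) {
    model$params$leak$gk <- gk
    rin <- measure_rin(model)
    if (abs(rin - target_rin) / target_rin < tol / 2) break
    # Rin scales almost exactly as 1/g: fixed-point update
    gk <- gk * rin / target_rin
  }
  if (abs(rin - target_rin) / target_rin > tol) {
    stop(sprintf("leak tuning failed to converge: Rin = %.1f MOhm", rin))
  }
  tuning <- list(achieved_rin = rin, target_rin = target_rin,
                 densities = leak_densities(model))
  if (report_rest) {
    sim <- simulate_neuron(model, no_stimulus(), duration = rest_ms,
                           chloride = "dynamic",
                           record = section_index(model, "soma"))
    soma <- section_index(model, "soma")
    tuning$rest_vm <- mean(sim$end_state$v[soma])
    tuning$rest_cl <- mean(sim$end_state$cl[soma])
  }
  model$tuning <- tuning
  model
}

#' Search for balanced excitatory:inhibitory synapse configurations
#'
#' Runs the event-driven stimulus over a grid of excitatory and inhibitory
#' synapse counts and returns the pairs whose mean output rate (over
#' trials) falls within a tolerance band of the target rate.
#'
#' @param model a (tuned) [neuron_model()].
#' @param n_exc,n_inh grids of synapse counts.
#' @param rate_hz per-synapse input frequency (Hz).
#' @param target_hz target output rate (Hz).
#' @param tol_hz half-width of the acceptance band (Hz).
#' @param trials trials per grid cell.
#' @param duration simulation length (ms).
#' @param inh_section where the inhibitory synapses go.
#' @param chloride chloride mode.
#' @param seed master seed.
#' @return list with `rates` (matrix, exc x inh), `pairs` (data.frame of
#'   accepted configurations) and the grids.
#' @export
balanced_pair_search <- function(model, n_exc, n_inh, rate_hz = 5,
                                 target_hz = 5, tol_hz = 1, trials = 3,
                                 duration = 1000, inh_section = "distal",
                                 chloride = "dynamic", seed = 1) {
  if (!length(n_exc) || !length(n_inh)) stop("grids must be non-empty")
  rates <- matrix(NA_real_, length(n_exc), length(n_inh),
                  dimnames = list(n_exc, n_inh))
  for (i in seq_along(n_exc)) {
    for (j in seq_along(n_inh)) {
      rr <- vapply(seq_len(trials), function(k) {
        sim <- simulate_neuron(
          model,
          fin_stimulus(n_exc[i], n_inh[j], rate_hz, inh_section = inh_section),
          duration = duration, chloride = chloride,
          seed = subseed(seed, i * 10000 + j * 100 + k),
          record = model$n, record_dt = duration)
        mean_rate(sim$spikes, duration)
      }, numeric(1))
      rates[i, j] <- mean(rr)
    }
  }
  hit <- which(abs(rates - target_hz) <= tol_hz, arr.ind = TRUE)
  pairs <- data.frame(n_exc = n_exc[hit[, 1]], n_inh = n_inh[hit[, 2]],
                      rate_hz = rates[hit])
  list(rates = rates, pairs = pairs, n_exc = n_exc, n_inh = n_inh,
       target_hz = target_hz, tol_hz = tol_hz)
}
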