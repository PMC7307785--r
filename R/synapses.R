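#' Homogeneous Poisson spike train
#'
#' Inter-event intervals are sampled from a negative exponential
#' distribution (SD = mean), the classical model of irregular presynaptic
#' firing at a set mean input frequency.
#'
#' @param rate_hz mean event rate (Hz).
#' @param duration_ms train duration (ms).
#' @param seed integer seed; the draw is reproducible for a fixed seed and
#'   leaves the global RNG state untouched.
#' @return sorted event times in ms, within `[0, duration_ms)`.
#' @export
poisson_train <- function(rate_hz, duration_ms, seed = NULL) {
  if (rate_hz < 0) stop("rate must be >= 0")
  if (rate_hz == 0 || duration_ms <= 0) return(numeric(0))
  run <- function() {
    mean_isi <- 1000 / rate_hz
    # draw in blocks until the duration is covered
    out <- numeric(0)
    t <- 0
    repeat {
      k <- max(16L, ceiling((duration_ms - t) / mean_isi * 1.5))
      isi <- stats::rexp(k, rate = 1 / mean_isi)
      tt <- t + cumsum(isi)
      out <- c(out, tt)
      t <- tt[length(tt)]
      if (t >= duration_ms) break
    }
    out[out < duration_ms]
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# evaluate fn with a local RNG state
with_seed <- function(seed, expr) {
  expr <- substitute(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval(expr, envir = parent.frame())
}

#' Deterministic sub-seed expansion
#'
#' Expands one master seed into independent per-stream seeds with a
#' counter-based linear-congruential hash, so adding a new consumer (a
#' recorder, an extra trial) never perturbs the realizations of existing
#' streams.
#'
#' @param master master seed (integer).
#' @param stream stream counter (integer).
#' @return a positive integer seed below 2^31.
#' @export
subseed <- function(master, stream) {
  ((master %% 2147483647) * 69069 + stream * 12345 + 1) %% 2147483562 + 1
}

#' Normalized dual-exponential conductance time course
#'
#' `g(t)` proportional to `exp(-t/tau_decay) - exp(-t/tau_rise)`, scaled so
#' the peak equals 1; zero for `t < 0`.
#'
#' @param t_ms time since the presynaptic event (ms); vectorized.
#' @param tau_rise,tau_decay rise and decay time constants (ms),
#'   `tau_rise < tau_decay`.
#' @return normalized conductance (unitless, peak = 1).
#' @export
#' @examples
#' dual_exp_conductance(dual_exp_peak_time(0.2, 1.7), 0.2, 1.7)  # 1
dual_exp_conductance <- function(t_ms, tau_rise, tau_decay) {
  if (tau_rise >= tau_decay) stop("tau_rise must be < tau_decay")
  tp <- dual_exp_peak_time(tau_rise, tau_decay)
  norm <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  out <- (exp(-t_ms / tau_decay) - exp(-t_ms / tau_rise)) / norm
  out[t_ms < 0] <- 0
  out
}

#' @rdname dual_exp_conductance
#' @return `dual_exp_peak_time`: the time to peak (ms).
#' @export
dual_exp_peak_time <- function(tau_rise, tau_decay) {
  if (tau_rise >= tau_decay) stop("tau_rise must be < tau_decay")
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

#' NMDA receptor magnesium-block factor
#'
#' Sigmoidal voltage dependence of the NMDA conductance,
#' `1 / (1 + ([Mg]/3.57) exp(-0.062 Vm))`; approaches 0 when strongly
#' hyperpolarized (blocked) and 1 when depolarized.
#'
#' @param Vm membrane potential (mV).
#' @param mg_mM extracellular magnesium concentration (mM).
#' @return scale factor in (0, 1).
#' @export
nmda_mg_factor <- function(Vm, mg_mM = 1) {
  1 / (1 + (mg_mM / 3.57) * exp(-0.062 * Vm))
}

#' GABA-A receptor open fraction (kinetic scheme)
#'
#' Integrates `ds/dt = alpha [T] (1 - s) - beta s` over one step; the open
#' fraction stays in \[0, 1\].
#'
#' @param s current open fraction.
#' @param transmitter transmitter concentration \[T\] (mM) during the step.
#' @param dt step (ms).
#' @param alpha binding rate (mM^-1 ms^-1).
#' @param beta unbinding rate (ms^-1).
#' @return updated open fraction.
#' @export
gabaa_open_fraction <- function(s, transmitter, dt, alpha = 5, beta = 0.18) {
  rate <- alpha * transmitter + beta
  sinf <- alpha * transmitter / rate
  sinf + (s - sinf) * exp(-rate * dt)
}

#' GABA-A receptor current, split into its ionic components
#'
#' `ICl = (4/5) g (Vm - ECl)` and `IHCO3 = (1/5) g (Vm - EHCO3)`, the 4:1
#' chloride:bicarbonate permeability split.  The total current reverses at
#' `EGABA = (4/5) ECl + (1/5) EHCO3` even though each component is nonzero
#' there.
#'
#' @param g open-channel conductance (nS).
#' @param Vm membrane potential (mV).
#' @param ECl,EHCO3 ionic reversal potentials (mV).
#' @return named vector `ICl`, `IHCO3`, `total` (pA, positive outward).
#' @export
gabaa_current <- function(g, Vm, ECl, EHCO3) {
  if (any(g < 0)) stop("conductance must be >= 0")
  ICl <- 0.8 * g * (Vm - ECl)
  IHCO3 <- 0.2 * g * (Vm - EHCO3)
  c(ICl = ICl, IHCO3 = IHCO3, total = ICl + IHCO3)
}

#' Fluctuating (Ornstein-Uhlenbeck) conductance samples
#'
#' Reference generator for the continuous "gclamp" drive: an OU process with
#' mean `baseline * multiplier`, coefficient of variation `cv` and
#' correlation time `tau_ms`, clipped at zero.  The C++ engine implements
#' the identical update; this R version is the testing oracle.
#'
#' @param n number of samples.
#' @param multiplier relative conductance (multiplies the baseline).
#' @param dt step (ms).
#' @param baseline baseline conductance (uS).
#' @param cv coefficient of variation of the fluctuations.
#' @param tau_ms correlation time (ms).
#' @param seed integer seed.
#' @return numeric vector of conductance samples (uS).
#' @export
fluctuating_conductance <- function(n, multiplier, dt = 0.025,
                                    baseline = 1e-4, cv = 0.1, tau_ms = 10,
                                    seed = 1) {
  if (multiplier < 0) stop("multiplier must be >= 0")
  mu <- baseline * multiplier
  if (mu == 0) return(numeric(n))
  sd <- cv * mu
  rho <- exp(-dt / tau_ms)
  rup <- sqrt(1 - rho^2)
  z <- with_seed(seed, stats::rnorm(n))
  g <- numeric(n)
  cur <- mu
  for (i in seq_len(n)) {
    cur <- mu + (cur - mu) * rho + sd * rup * z[i]
    if (cur < 0) cur <- 0
    g[i] <- cur
  }
  g
}

#' Evenly spaced synapse positions along a section
#'
#' Synapses are placed at the midpoints of `n` equal subdivisions of the
#' section and mapped to the containing compartments.
#'
#' @param model a [neuron_model()].
#' @param section section name.
#' @param n number of synapses.
#' @return integer vector of compartment indices (length `n`).
#' @export
place_synapses <- function(model, section, n) {
  idx <- section_index(model, section)
  if (!length(idx)) stop("unknown section: ", section)
  ncomp <- length(idx)
  pos <- (seq_len(n) - 0.5) / n          # fractional position along section
  idx[pmin(ncomp, floor(pos * ncomp) + 1)]
}
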