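#' Stimulus programs
#'
#' Constructors for the two synaptic drive types and the empty stimulus.
#' `fin_stimulus()` describes populations of event-driven synapses, each
#' receiving an independent Poisson spike train at a mean input frequency;
#' `gclamp_stimulus()` describes continuous fluctuating conductances whose
#' mean is the baseline conductance times a relative-conductance multiplier
#' (distributed evenly over the target section).  Both are realized
#' deterministically from the simulation seed (or their own `seed`).
#'
#' @param n_exc,n_inh numbers of excitatory / inhibitory synapses.
#' @param rate_hz mean input frequency per synapse (Hz).
#' @param exc_section,inh_section target sections.
#' @param seed optional integer seed overriding the simulation seed for the
#'   stimulus realization.
#' @return an object of class `stimulus_program`.
#' @export
fin_stimulus <- function(n_exc = 0, n_inh = 0, rate_hz = 5,
                         exc_section = "distal", inh_section = "distal",
                         seed = NULL) {
  stopifnot(n_exc >= 0, n_inh >= 0, rate_hz >= 0)
  structure(list(kind = "fin", n_exc = n_exc, n_inh = n_inh,
                 rate_hz = rate_hz, exc_section = exc_section,
                 inh_section = inh_section, seed = seed),
            class = "stimulus_program")
}

#' @rdname fin_stimulus
#' @param rel_exc,rel_inh relative conductance multipliers of the baseline
#'   fluctuating conductance.
#' @export
gclamp_stimulus <- function(rel_exc = 0, rel_inh = 0,
                            exc_section = "distal", inh_section = "distal",
                            seed = NULL) {
  stopifnot(rel_exc >= 0, rel_inh >= 0)
  structure(list(kind = "gclamp", rel_exc = rel_exc, rel_inh = rel_inh,
                 exc_section = exc_section, inh_section = inh_section,
                 seed = seed),
            class = "stimulus_program")
}

#' @rdname fin_stimulus
#' @export
no_stimulus <- function() {
  structure(list(kind = "none"), class = "stimulus_program")
}

#' @export
print.stimulus_program <- function(x, ...) {
  switch(x$kind,
    none = cat("stimulus: none\n"),
    fin = cat(sprintf(
      "stimulus: f-in, %d excitatory (%s) : %d inhibitory (%s) at %g Hz\n",
      x$n_exc, x$exc_section, x$n_inh, x$inh_section, x$rate_hz)),
    gclamp = cat(sprintf(
      "stimulus: gclamp, relative conductance E %g (%s) : I %g (%s)\n",
      x$rel_exc, x$exc_section, x$rel_inh, x$inh_section)))
  invisible(x)
}

# resting potential of the passive three-ion membrane (conductance-weighted
# mean of the reversal potentials)
leak_rest_vm <- function(model) {
  g <- leak_densities(model)
  ions <- model$params$ions
  cc <- do.call(phys_constants, model$params$constants)
  EK <- nernst(1, ions$K_i, ions$K_o, cc)
  ENa <- nernst(1, ions$Na_i, ions$Na_o, cc)
  ECl <- nernst(-1, model$params$chloride$cl_i, ions$Cl_o, cc)
  unname((g["gk"] * EK + g["gna"] * ENa + g["gcl"] * ECl) / sum(g))
}

build_events_fin <- function(stim, model, duration, dt, seed, syn) {
  e_comp <- if (stim$n_exc > 0) place_synapses(model, stim$exc_section, stim$n_exc) else integer(0)
  i_comp <- if (stim$n_inh > 0) place_synapses(model, stim$inh_section, stim$n_inh) else integer(0)
  seed0 <- if (!is.null(stim$seed)) stim$seed else subseed(seed, 1000)
  ev_e_step <- integer(0); ev_e_comp <- integer(0)
  for (j in seq_along(e_comp)) {
    tt <- poisson_train(stim$rate_hz, duration, seed = subseed(seed0, j))
    if (length(tt)) {
      ev_e_step <- c(ev_e_step, as.integer(floor(tt / dt)))
      ev_e_comp <- c(ev_e_comp, rep.int(e_comp[j] - 1L, length(tt)))
    }
  }
  ev_i_step <- integer(0); ev_i_syn <- integer(0)
  for (j in seq_along(i_comp)) {
    tt <- poisson_train(stim$rate_hz, duration, seed = subseed(seed0, 50000 + j))
    if (length(tt)) {
      ev_i_step <- c(ev_i_step, as.integer(floor(tt / dt)))
      ev_i_syn <- c(ev_i_syn, rep.int(j - 1L, length(tt)))
    }
  }
  oe <- order(ev_e_step)
  oi <- order(ev_i_step)
  list(
    e_ev_step = ev_e_step[oe], e_ev_comp = ev_e_comp[oe],
    e_ev_wA = rep(syn$gmax_e, length(oe)),
    e_ev_wN = rep(syn$gmax_e * syn$nmda_ratio, length(oe)),
    i_syn_comp = i_comp - 1L,
    i_syn_gmax_uS = rep(syn$gmax_i, length(i_comp)),
    i_ev_step = ev_i_step[oi], i_ev_syn = ev_i_syn[oi]
  )
}

empty_events <- function(syn) {
  list(e_ev_step = integer(0), e_ev_comp = integer(0),
       e_ev_wA = numeric(0), e_ev_wN = numeric(0),
       i_syn_comp = integer(0), i_syn_gmax_uS = numeric(0),
       i_ev_step = integer(0), i_ev_syn = integer(0))
}

#' Simulate the coupled voltage / chloride system
#'
#' Integrates the cable equation (implicit backward-Euler tridiagonal solve
#' per step) coupled to the membrane mechanisms, synapses and the chloride
#' mass balance, recording traces and axon-tip spike times.
#'
#' @param model a [neuron_model()].
#' @param stimulus a `stimulus_program` (see [fin_stimulus()]).
#' @param duration simulation length (ms).
#' @param dt time step (ms), default 0.025.
#' @param chloride `"dynamic"` (the mass balance runs) or `"static"`
#'   (every `[Cl-]i` frozen at its initial value, so EGABA is constant).
#' @param potassium `"fixed"` or `"dynamic"` (see
#'   [enable_dynamic_potassium()]; set automatically if the model is
#'   flagged).
#' @param inh_reversal `"split"` (Cl-/HCO3- components with per-compartment
#'   reversals; default) or `"fixed"` (legacy constant inhibitory reversal
#'   `e_inh_fixed`).
#' @param e_inh_fixed legacy fixed inhibitory reversal (mV), used only when
#'   `inh_reversal = "fixed"`.
#' @param seed integer master seed; expanded deterministically into
#'   per-synapse and noise-stream sub-seeds.
#' @param record compartments to record: `"all"`, a section name, or a
#'   vector of compartment indices.
#' @param record_dt recording interval (ms).
#' @param init optional list with elements `v`, `cl`, `ki` (scalars or
#'   per-compartment vectors) overriding the default initial state.
#' @param inject optional data.frame/list with `comp` (index or section
#'   name), `amp_nA`, `t0`, `t1` describing step current injections.
#' @return An object of class `neuron_sim` with elements `spikes` (ms),
#'   `t`, `vm`, `cl`, `egaba` (recorded traces), `end_state`, and the
#'   resolved `config`.
#' @export
simulate_neuron <- function(model, stimulus = no_stimulus(),
                            duration = 1000, dt = 0.025,
                            chloride = c("dynamic", "static"),
                            potassium = c("fixed", "dynamic"),
                            inh_reversal = c("split", "fixed"),
                            e_inh_fixed = -74,
                            seed = 1,
                            record = "all", record_dt = 1,
                            init = NULL, inject = NULL) {
  stopifnot(inherits(model, "neuron_model"), dt > 0, duration >= dt)
  chloride <- match.arg(chloride)
  potassium <- match.arg(potassium)
  inh_reversal <- match.arg(inh_reversal)
  if (isTRUE(model$dynamic_k)) potassium <- "dynamic"
  p <- model$params
  comp <- model$comp
  n <- model$n
  cc <- do.call(phys_constants, p$constants)
  ions <- p$ions

  g <- leak_densities(model)
  area <- comp$area_cm2
  sec <- comp$section
  is_axon <- as.integer(sec == "axon")
  kscale <- p$kcc2$scale[sec] / 100
  Pc <- p$kcc2$P * kscale

  geom <- list(
    area_cm2 = area, vol_L = comp$vol_L, vol_um3 = comp$vol_um3,
    cm_nF = area * p$membrane$cm * 1e3,
    g_axial_uS = model$interfaces$g_axial_uS,
    g_diff = model$interfaces$g_diff,
    is_axon = is_axon
  )

  v0 <- if (!is.null(init$v)) rep_len(init$v, n) else
    rep(p$init$vm %||% leak_rest_vm(model), n)
  cl0 <- if (!is.null(init$cl)) rep_len(init$cl, n) else rep(p$chloride$cl_i, n)
  ki0 <- if (!is.null(init$ki)) rep_len(init$ki, n) else rep(ions$K_i, n)

  mech <- list(
    gk_leak_uS = g[["gk"]] * area * 1e6,
    gna_leak_uS = g[["gna"]] * area * 1e6,
    gcl_leak_uS = g[["gcl"]] * area * 1e6,
    gna_hh_uS = p$channels$gna * area * 1e6 * is_axon,
    gk_hh_uS = p$channels$gk * area * 1e6 * is_axon,
    gm_uS = p$channels$gm * area * 1e6 * is_axon,
    kcc2_dcl = Pc * area / (cc$F * comp$vol_L) * 1e-3,
    kcc2_inA = Pc * area * 1e6,
    na_shift = p$channels$na_shift, k_shift = p$channels$k_shift,
    m_vhalf = p$channels$m_vhalf, m_k = p$channels$m_k,
    m_tau = p$channels$m_tau,
    k_exponent = as.integer(p$channels$k_exponent),
    kcc2_electrogenic = isTRUE(p$kcc2$electrogenic),
    RTF = cc$RTF, F = cc$F,
    Ko = ions$K_o, Clo = ions$Cl_o,
    ENa = nernst(1, ions$Na_i, ions$Na_o, cc),
    EHCO3 = nernst(-1, ions$HCO3_i, ions$HCO3_o, cc),
    EK = nernst(1, ions$K_i, ions$K_o, cc),
    ki0 = ki0, cl0 = cl0
  )

  syn_par <- p$synapse
  ev <- switch(stimulus$kind,
    fin = build_events_fin(stimulus, model, duration, dt, seed, syn_par),
    empty_events(syn_par))
  syn <- c(ev, list(
    tau_rise_ampa = syn_par$tau_rise_ampa, tau_decay_ampa = syn_par$tau_decay_ampa,
    tau_rise_nmda = syn_par$tau_rise_nmda, tau_decay_nmda = syn_par$tau_decay_nmda,
    mg_mM = syn_par$mg_mM,
    alpha = syn_par$alpha, beta = syn_par$beta, t_conc = syn_par$t_conc,
    pulse_steps = as.integer(round(syn_par$t_pulse / dt))
  ))

  if (stimulus$kind == "gclamp") {
    gp <- p$gclamp
    # a fixed population of gp$n_syn fluctuating-conductance synapses per
    # drive, placed evenly along the target section (independent of the
    # spatial discretization); the relative-conductance multiplier scales
    # each synapse's baseline, and each synapse fluctuates with
    # coefficient of variation gp$cv around its mean (independent streams)
    ce <- place_synapses(model, stimulus$exc_section, gp$n_syn)
    ci <- place_synapses(model, stimulus$inh_section, gp$n_syn)
    allc <- sort(unique(c(ce, ci)))
    ke <- tabulate(match(ce, allc), length(allc))
    ki <- tabulate(match(ci, allc), length(allc))
    me <- gp$baseline * stimulus$rel_exc * ke
    mi <- gp$baseline * stimulus$rel_inh * ki
    gseed <- if (!is.null(stimulus$seed)) stimulus$seed else subseed(seed, 777)
    gclamp <- list(comp = as.integer(allc - 1L),
                   mean_e_uS = me, mean_i_uS = mi,
                   sd_e_uS = gp$cv * gp$baseline * stimulus$rel_exc * sqrt(ke),
                   sd_i_uS = gp$cv * gp$baseline * stimulus$rel_inh * sqrt(ki),
                   tau_ms = gp$tau, seed = as.numeric(gseed))
  } else {
    gclamp <- list(comp = integer(0), mean_e_uS = numeric(0),
                   mean_i_uS = numeric(0), sd_e_uS = numeric(0),
                   sd_i_uS = numeric(0), tau_ms = p$gclamp$tau,
                   seed = as.numeric(subseed(seed, 777)))
  }

  if (is.null(inject)) {
    inj <- list(comp = integer(0), amp_nA = numeric(0),
                t0 = numeric(0), t1 = numeric(0))
  } else {
    inject <- as.data.frame(inject)
    ic <- inject$comp
    if (is.character(ic)) {
      ic <- vapply(ic, function(s) {
        idx <- section_index(model, s)
        idx[ceiling(length(idx) / 2)]
      }, integer(1))
    }
    inj <- list(comp = as.integer(ic - 1L), amp_nA = inject$amp_nA,
                t0 = inject$t0, t1 = inject$t1)
  }

  gpas_uS <- sum(g) * area * 1e6
  modes <- list(
    dynamic_cl = chloride == "dynamic",
    dynamic_k = potassium == "dynamic",
    e_inh_fixed = if (inh_reversal == "fixed") e_inh_fixed else NaN,
    gpas_uS = gpas_uS, e_pas = leak_rest_vm(model)
  )

  rec_idx <- if (identical(record, "all")) seq_len(n)
    else if (is.character(record)) unlist(lapply(record, section_index, model = model))
    else as.integer(record)
  rec_every <- max(1L, as.integer(round(record_dt / dt)))
  nsteps <- as.integer(round(duration / dt))
  simctl <- list(
    dt = dt, nsteps = nsteps, rec_every = rec_every,
    rec_comps = as.integer(rec_idx - 1L),
    spike_comp = as.integer(n - 1L),
    spike_threshold = p$spike$threshold, spike_lockout = p$spike$lockout,
    v_init = v0
  )

  out <- .engine_run(geom, mech, syn, gclamp, inj, modes, simctl)
  if (out$fail_step >= 0) {
    stop(sprintf(
      "numerical failure at step %d (t = %.3f ms), compartment %d (%s)",
      out$fail_step, out$fail_step * dt, out$fail_comp + 1,
      sec[out$fail_comp + 1]))
  }
  structure(list(
    spikes = out$spikes,
    t = out$t, vm = out$vm, cl = out$cl, egaba = out$egaba,
    rec_comps = rec_idx, cl_init = cl0,
    end_state = list(v = out$v_end, cl = out$cl_end, ki = out$ki_end),
    model = model,
    config = list(duration = duration, dt = dt, chloride = chloride,
                  potassium = potassium, inh_reversal = inh_reversal,
                  seed = seed, stimulus = stimulus)
  ), class = "neuron_sim")
}

#' @export
print.neuron_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("neuron simulation: %.0f ms, dt %.3g ms, %s chloride\n",
              cfg$duration, cfg$dt, cfg$chloride))
  print(cfg$stimulus)
  cat(sprintf("  spikes at axon tip: %d (%.2f Hz)\n", length(x$spikes),
              1000 * length(x$spikes) / cfg$duration))
  dcl <- distal_degaba(x)
  cat(sprintf("  distal EGABA shift: %+.2f mV\n", dcl))
  invisible(x)
}

#' @export
plot.neuron_sim <- function(x, which = c("vm", "cl", "egaba"), comp = NULL, ...) {
  which <- match.arg(which)
  tr <- x[[which]]
  if (is.null(comp)) comp <- seq_len(ncol(tr))
  ylab <- switch(which, vm = "Vm (mV)", cl = "[Cl-]i (mM)",
                 egaba = "EGABA (mV)")
  graphics::matplot(x$t, tr[, comp, drop = FALSE], type = "l", lty = 1,
                    xlab = "time (ms)", ylab = ylab, ...)
  invisible(x)
}

#' Change in spatially averaged distal EGABA over a run
#'
#' Volume-weighted spatial average of the distal-dendrite EGABA, end of the
#' run minus start, computed from the exact engine end state.
#'
#' @param sim a `neuron_sim`.
#' @return Delta EGABA (mV).
#' @export
distal_degaba <- function(sim) {
  model <- sim$model
  idx <- section_index(model, "distal")
  cc <- do.call(phys_constants, model$params$constants)
  ions <- model$params$ions
  EHCO3 <- nernst(-1, ions$HCO3_i, ions$HCO3_o, cc)
  w <- model$comp$vol_um3[idx]
  eg <- function(cl) {
    egaba_combine(nernst(-1, cl, ions$Cl_o, cc), EHCO3)
  }
  cl_start <- if (!is.null(sim$cl_init)) sim$cl_init[idx] else
    rep(model$params$chloride$cl_i, length(idx))
  e0 <- sum(eg(cl_start) * w) / sum(w)
  e1 <- sum(eg(sim$end_state$cl[idx]) * w) / sum(w)
  e1 - e0
}

#' Threshold-crossing spike detection
#'
#' Upward crossings of a voltage threshold with a refractory lockout.
#'
#' @param vm voltage trace (mV).
#' @param t sample times (ms), same length.
#' @param threshold detection threshold (mV).
#' @param lockout minimum interval between detected spikes (ms).
#' @return spike times (ms).
#' @export
detect_spikes <- function(vm, t, threshold = -20, lockout = 2) {
  up <- which(vm[-1] >= threshold & vm[-length(vm)] < threshold) + 1L
  if (!length(up)) return(numeric(0))
  times <- t[up]
  keep <- times[1]
  for (tt in times[-1]) {
    if (tt - keep[length(keep)] >= lockout) keep <- c(keep, tt)
  }
  keep
}

#' Settled resting state of a model
#'
#' Runs a short unstimulated settling simulation (static chloride) and
#' returns the per-compartment resting profile.  The membrane settles
#' within a few tens of milliseconds; the axon rests a few millivolts
#' below the soma because of its resting potassium-gate conductance.
#'
#' @param model a [neuron_model()].
#' @param settle_ms settling time (ms).
#' @return list with per-compartment `v`, `cl`, `ki`, usable as the `init`
#'   argument of [simulate_neuron()].
#' @export
rest_state <- function(model, settle_ms = 1000) {
  sim <- simulate_neuron(model, no_stimulus(), duration = settle_ms,
                         chloride = "static", record = model$n,
                         record_dt = settle_ms)
  list(v = sim$end_state$v, cl = sim$end_state$cl, ki = sim$end_state$ki)
}
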