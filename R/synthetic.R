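#' Generate a synthetic chloride-recovery trace
#'
#' Emulates the perforated-patch protocol: a chloride load above baseline
#' followed by recovery governed by the single-compartment mass balance
#' (KCC2 extrusion plus a constant leak influx that holds the baseline
#' steady), sampled sparsely and corrupted with additive Gaussian noise.
#' With those dynamics the noiseless recovery is exactly
#' `Cl(t) = baseline + A exp(-P Ki t)`, so the generator's ground truth is
#' recoverable by [fit_recovery()].
#'
#' @param P_true true pump strength (mM^-1 s^-1).
#' @param load_mM chloride load above baseline at t = 0 (mM).
#' @param baseline_mM resting `[Cl-]i` (mM).
#' @param times_s sample schedule (s after the load ends).
#' @param noise_sd additive measurement noise SD (mM).
#' @param seed integer seed for the noise draw.
#' @param Ki,Ko,Clo fixed concentrations (mM).
#' @return data.frame with columns `time_s`, `cl_mM`; the generating
#'   parameters are attached as the `ground_truth` attribute.
#' @export
generate_recovery <- function(P_true = 0.001, load_mM = 10,
                              baseline_mM = 4.25,
                              times_s = seq(2, 90, by = 5),
                              noise_sd = 0, seed = 1,
                              Ki = 140, Ko = 4, Clo = 135) {
  if (load_mM <= 0) stop("load must be > 0")
  if (any(diff(times_s) <= 0)) stop("sample times must be strictly increasing")
  # leak influx holding the baseline steady: L0 = P (Ki b - Ko Clo), so
  # dCl/dt = -(P Ki)(Cl - b): integrate exactly
  cl <- baseline_mM + load_mM * exp(-P_true * Ki * times_s)
  if (noise_sd > 0) {
    cl <- cl + with_seed(seed, stats::rnorm(length(cl), 0, noise_sd))
  }
  out <- data.frame(time_s = times_s, cl_mM = cl)
  attr(out, "ground_truth") <- list(P = P_true, load = load_mM,
                                    baseline = baseline_mM,
                                    tau_s = 1 / (P_true * Ki),
                                    noise_sd = noise_sd, seed = seed)
  out
}

#' Generate synthetic GABA-puff currents
#'
#' `I = g (Vhold - EGABA) + noise` for each holding potential, the inputs
#' of the resting EGABA / conductance estimation.
#'
#' @param EGABA_true true reversal potential (mV).
#' @param g GABA-A conductance (nS).
#' @param vhold holding potentials (mV), at least 2 for the resting
#'   estimate.
#' @param noise_pA additive current noise SD (pA).
#' @param seed integer seed.
#' @return data.frame with `vhold`, `current_pA`; ground truth attached as
#'   an attribute.
#' @export
generate_puff_currents <- function(EGABA_true, g, vhold, noise_pA = 0,
                                   seed = 1) {
  I <- g * (vhold - EGABA_true)
  if (noise_pA > 0) {
    I <- I + with_seed(seed, stats::rnorm(length(I), 0, noise_pA))
  }
  out <- data.frame(vhold = vhold, current_pA = I)
  attr(out, "ground_truth") <- list(EGABA = EGABA_true, g = g,
                                    noise_pA = noise_pA, seed = seed)
  out
}

fixture_table <- function() {
  list(
    fig2_distal_balanced_5hz = list(
      stimulus = fin_stimulus(250, 300, 5, inh_section = "distal", seed = 21),
      overrides = list(), duration = 1000, trials = 5,
      note = "reference balanced pair, distal inhibition, 5 Hz in/out"),
    fig2_distal_balanced_10hz = list(
      stimulus = fin_stimulus(250, 300, 10, inh_section = "distal", seed = 22),
      overrides = list(), duration = 1000, trials = 5,
      note = "reference pair at 10 Hz balanced input"),
    fig2_distal_balanced_25hz = list(
      stimulus = fin_stimulus(250, 300, 25, inh_section = "distal", seed = 23),
      overrides = list(), duration = 1000, trials = 5,
      note = "reference pair at 25 Hz balanced input"),
    fig2_distal_balanced_50hz = list(
      stimulus = fin_stimulus(250, 300, 50, inh_section = "distal", seed = 24),
      overrides = list(), duration = 1000, trials = 5,
      note = "reference pair at 50 Hz balanced input"),
    fig2_proximal_balanced_5hz = list(
      stimulus = fin_stimulus(780, 330, 5, inh_section = "proximal", seed = 25),
      overrides = list(), duration = 1000, trials = 5,
      note = "proximal-inhibition balanced pair, 5 Hz in/out"),
    fig3_distal_rate_series = list(
      stimulus = fin_stimulus(250, 300, 20, inh_section = "distal", seed = 31),
      overrides = list(), duration = 1000, trials = 3,
      note = "balanced-rate series point at 20 Hz, distal inhibition"),
    fig4_io_distal = list(
      stimulus = fin_stimulus(300, 100, 5, inh_section = "distal", seed = 41),
      overrides = list(), duration = 1000, trials = 3,
      note = "synapse-count input-output protocol, distal inhibition"),
    fig5_heatmap = list(
      stimulus = gclamp_stimulus(8, 4, inh_section = "distal", seed = 51),
      overrides = list(sections = list(distal = list(diam = 1.0))),
      duration = 1000, trials = 5,
      note = "fluctuating-conductance heatmap cell, distal diameter 1.0 um"),
    fig6_index_reference = list(
      stimulus = gclamp_stimulus(8, 4, inh_section = "distal", seed = 61),
      overrides = list(), duration = 1000, trials = 2,
      note = "chloride-index protocol reference drive")
  )
}

#' Named stimulus fixtures for the figure protocols
#'
#' Returns the exact seeded stimulus program and model overrides used by
#' each canned protocol; the same name always yields an identical program.
#'
#' @param name fixture identifier; call [list_fixtures()] for the catalogue.
#' @return list with `stimulus`, `overrides`, `duration`, `trials`, `note`.
#' @export
#' @examples
#' fixture("fig2_distal_balanced_5hz")$stimulus
fixture <- function(name) {
  tab <- fixture_table()
  if (!name %in% names(tab)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  }
  tab[[name]]
}

#' @rdname fixture
#' @export
list_fixtures <- function() {
  tab <- fixture_table()
  data.frame(name = names(tab),
             note = vapply(tab, `[[`, character(1), "note"),
             row.names = NULL)
}
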