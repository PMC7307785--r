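#' Ohmic leak currents for the three major ions
#'
#' @param Vm membrane potential (mV).
#' @param reversal named vector with `EK`, `ENa`, `ECl` (mV).
#' @param g named vector of leak conductance densities `gk`, `gna`, `gcl`
#'   (S/cm^2), e.g. from [leak_densities()].
#' @return named vector of current densities (mA/cm^2); positive = outward.
#' @export
leak_currents <- function(Vm, reversal, g) {
  c(IK = g[["gk"]] * (Vm - reversal[["EK"]]),
    INa = g[["gna"]] * (Vm - reversal[["ENa"]]),
    ICl = g[["gcl"]] * (Vm - reversal[["ECl"]]))
}

vtrap <- function(x, y) {
  ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2), x / (1 - exp(-x / y)))
}

#' Voltage-dependent rate functions of the axonal channels
#'
#' Standard squid-derived alpha/beta rate functions for the Na (m, h) and
#' delayed-rectifier K (n) gates, with voltage shifts that place the
#' activation range appropriately for an axon initial segment.  The shifts
#' are calibration parameters (see the package vignette).
#'
#' @param Vm membrane potential (mV).
#' @param na_shift,k_shift depolarizing shifts (mV) applied to the Na and K
#'   gate rate functions.
#' @return list of rates (1/ms): `am, bm, ah, bh, an, bn`.
#' @export
hh_rate_functions <- function(Vm, na_shift = 0, k_shift = 0) {
  vn <- Vm - na_shift
  vk <- Vm - k_shift
  list(
    am = 0.1 * vtrap(vn + 40, 10),
    bm = 4 * exp(-(vn + 65) / 18),
    ah = 0.07 * exp(-(vn + 65) / 20),
    bh = 1 / (1 + exp(-(vn + 35) / 10)),
    an = 0.01 * vtrap(vk + 55, 10),
    bn = 0.125 * exp(-(vk + 65) / 80)
  )
}

#' Steady-state activation of the axonal gates at a clamped voltage
#' @inheritParams hh_rate_functions
#' @param m_vhalf,m_k M-current activation midpoint and slope (mV).
#' @return named vector `m, h, n, mM` in \[0, 1\].
#' @export
gating_steady_state <- function(Vm, na_shift = 0, k_shift = 0,
                                m_vhalf = -35, m_k = 10) {
  r <- hh_rate_functions(Vm, na_shift, k_shift)
  c(m = r$am / (r$am + r$bm), h = r$ah / (r$ah + r$bh),
    n = r$an / (r$an + r$bn),
    mM = 1 / (1 + exp(-(Vm - m_vhalf) / m_k)))
}

#' Hodgkin-Huxley style axonal currents, advancing the gates one step
#'
#' Currents follow the printed forms INa = m^3 h gNa (Vm - ENa),
#' IK = n gK (Vm - EK) (single-exponent K gate by default; set
#' `k_exponent = 4` for the classical n^4 form) and IM = mM gM (Vm - EK).
#'
#' @param Vm membrane potential (mV), held fixed over the step.
#' @param state named vector `m, h, n, mM` of gating variables.
#' @param EK,ENa reversal potentials (mV).
#' @param dt time step (ms).
#' @param g named vector `gna, gk, gm` of maximal conductance densities
#'   (S/cm^2).
#' @param na_shift,k_shift,m_vhalf,m_k,m_tau kinetics parameters.
#' @param k_exponent 1 (default) or 4.
#' @return list with `currents` (named, mA/cm^2, positive outward) and the
#'   advanced `state`.
#' @export
hh_currents <- function(Vm, state, EK, ENa, dt,
                        g = c(gna = 0.12, gk = 0.01, gm = 5e-4),
                        na_shift = 0, k_shift = 0,
                        m_vhalf = -35, m_k = 10, m_tau = 200,
                        k_exponent = 1) {
  if (any(!is.finite(state))) stop("non-finite gating state")
  nk <- if (k_exponent == 4) state[["n"]]^4 else state[["n"]]
  cur <- c(
    INa = g[["gna"]] * state[["m"]]^3 * state[["h"]] * (Vm - ENa),
    IK = g[["gk"]] * nk * (Vm - EK),
    IM = g[["gm"]] * state[["mM"]] * (Vm - EK)
  )
  r <- hh_rate_functions(Vm, na_shift, k_shift)
  adv <- function(x, a, b) {
    tau <- 1 / (a + b)
    xinf <- a * tau
    xinf + (x - xinf) * exp(-dt / tau)
  }
  minf <- 1 / (1 + exp(-(Vm - m_vhalf) / m_k))
  state_new <- c(
    m = adv(state[["m"]], r$am, r$bm),
    h = adv(state[["h"]], r$ah, r$bh),
    n = adv(state[["n"]], r$an, r$bn),
    mM = minf + (state[["mM"]] - minf) * exp(-dt / m_tau)
  )
  list(currents = cur, state = pmin(pmax(state_new, 0), 1))
}

#' KCC2 extrusion rate
#'
#' The cotransporter rate law `V = P ([K+]i [Cl-]i - [K+]o [Cl-]o)`;
#' positive values are net Cl- extrusion, zero at thermodynamic equilibrium
#' `[Cl-]i = [K+]o [Cl-]o / [K+]i`.
#'
#' @param P pump strength (mM^-1 s^-1).
#' @param Ki,Cli,Ko,Clo ion concentrations (mM).
#' @return extrusion rate (mM/s).
#' @export
#' @examples
#' kcc2_rate(0.001, 140, 4.25, 4, 135)  # 0.055 mM/s
kcc2_rate <- function(P, Ki, Cli, Ko, Clo) {
  if (any(c(Ki, Cli, Ko, Clo) <= 0)) stop("concentrations must be > 0")
  P * (Ki * Cli - Ko * Clo)
}

#' Convert KCC2 pump strength between unit systems
#'
#' The concentration form (mM^-1 s^-1) describes a whole-cell rate; the
#' current-density form (mA mM^-2 cm^-2) scales with each compartment's
#' surface area, so a single constant serves every compartment size:
#' `P_current = P_conc * F * volume / area`.
#'
#' @param P_conc pump strength (mM^-1 s^-1).
#' @param volume_L cell or compartment volume (L).
#' @param area_cm2 membrane area (cm^2).
#' @param F Faraday constant (C/mol).
#' @return pump strength in mA mM^-2 cm^-2.
#' @export
#' @examples
#' convert_pump_strength(0.001, 1.058e-12, 529e-8)  # 1.9297e-5
convert_pump_strength <- function(P_conc, volume_L, area_cm2,
                                  F = phys_constants()$F) {
  if (any(volume_L <= 0) || any(area_cm2 <= 0)) {
    stop("volume and area must be > 0")
  }
  P_conc * F * volume_L / area_cm2
}

#' @rdname convert_pump_strength
#' @param P_current pump strength (mA mM^-2 cm^-2).
#' @export
convert_pump_strength_inverse <- function(P_current, volume_L, area_cm2,
                                          F = phys_constants()$F) {
  if (any(volume_L <= 0) || any(area_cm2 <= 0)) {
    stop("volume and area must be > 0")
  }
  P_current * area_cm2 / (F * volume_L)
}
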