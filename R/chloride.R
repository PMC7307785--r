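#' One step of the per-compartment chloride mass balance (reference)
#'
#' Advances the three-term mass balance
#' `d[Cl-]i/dt = ICl/(F Vol) - P ([K+]i[Cl-]i - [K+]o[Cl-]o) + diffusion`
#' explicitly over one step.  Sign conventions: outward-positive chloride
#' current means anion influx and raises `[Cl-]i`; a positive KCC2 bracket
#' (extrusion) lowers it; diffusion is conservative.  This R implementation
#' is the module-level reference used to validate the compiled engine; the
#' engine performs the identical update.
#'
#' @param cl per-compartment `[Cl-]i` (mM).
#' @param icl_out_nA per-compartment total chloride current (nA, positive
#'   outward = influx of Cl-).
#' @param P_current KCC2 pump strength (mA mM^-2 cm^-2), scalar or
#'   per-compartment.
#' @param geometry list with `area_cm2`, `vol_L`, `vol_um3` vectors.
#' @param g_diff interface diffusion couplings (um^3/ms per mM), length
#'   `length(cl) - 1`; sealed ends.  Use `numeric(0)` for one compartment.
#' @param dt step (ms).
#' @param Ki,Ko,Clo fixed concentrations (mM).
#' @param F Faraday constant (C/mol).
#' @return updated `[Cl-]i` vector (mM).
#' @export
chloride_step <- function(cl, icl_out_nA, P_current, geometry, g_diff, dt,
                          Ki = 140, Ko = 4, Clo = 135,
                          F = phys_constants()$F) {
  if (dt <= 0) stop("dt must be > 0")
  if (any(cl <= 0)) stop("concentrations must be > 0")
  n <- length(cl)
  dcl <- icl_out_nA * 1e-9 / (F * geometry$vol_L)          # mM/ms
  # KCC2 extrusion (current-density form scales with area/volume)
  dcl <- dcl - P_current * (Ki * cl - Ko * Clo) *
    geometry$area_cm2 / (F * geometry$vol_L) * 1e-3        # mM/s -> mM/ms
  if (n > 1) {
    q <- g_diff * (cl[-1] - cl[-n])                        # mM um^3 / ms
    dcl[-n] <- dcl[-n] + q / geometry$vol_um3[-n]
    dcl[-1] <- dcl[-1] - q / geometry$vol_um3[-1]
  }
  out <- cl + dt * dcl
  if (any(out < 1e-3)) {
    stop("chloride underflow (< 1e-3 mM) at compartment ",
         which.min(out), " during chloride_step")
  }
  out
}

#' Interface diffusion couplings for a chain of compartments
#'
#' Series-resistance finite-volume coupling between compartment midpoints,
#' which conserves mass exactly and handles diameter jumps at section
#' junctions.
#'
#' @param L_um compartment lengths (um).
#' @param diam_um compartment diameters (um).
#' @param D diffusion coefficient (um^2/ms).
#' @return vector of couplings (um^3/ms per mM), length `n - 1`.
#' @export
diffusion_couplings <- function(L_um, diam_um, D = 2.03) {
  if (D <= 0) stop("D must be > 0")
  n <- length(L_um)
  cross <- pi * (diam_um / 2)^2
  r <- (L_um / 2) / (D * cross)
  1 / (r[-n] + r[-1])
}

#' Enable the dynamic-potassium mode on a model
#'
#' In this mode `[K+]i` becomes a per-compartment state with its own mass
#' balance (KCC2 potassium efflux balanced by a tonic influx at rest), the
#' KCC2 potassium current is set opposite to its chloride current so the
#' transporter carries no net charge, and the ionic leak channels are
#' replaced by a passive conductance plus tonic fluxes that hold the
#' initial `[Cl-]i` and `[K+]i` at rest.
#'
#' @param model a [neuron_model()].
#' @return the model, flagged for dynamic potassium.
#' @export
enable_dynamic_potassium <- function(model) {
  stopifnot(inherits(model, "neuron_model"))
  model$dynamic_k <- TRUE
  model
}
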