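#' Physical constants
#'
#' Faraday constant, gas constant and absolute temperature used throughout
#' the model.  Defaults correspond to 37 degrees C.
#'
#' @param F Faraday constant (C mol^-1).
#' @param R gas constant (J K^-1 mol^-1).
#' @param T absolute temperature (K).
#' @return A list with elements `F`, `R`, `T` and the derived `RTF` (mV),
#'   the thermal voltage R*T/F expressed in millivolts.
#' @export
#' @examples
#' phys_constants()$RTF   # ~26.73 mV at 37 C
phys_constants <- function(F = 96485.33, R = 8.31446, T = 310.15) {
  stopifnot(F > 0, R > 0, T > 0)
  list(F = F, R = R, T = T, RTF = 1000 * R * T / F)
}

#' Default ion concentration table
#'
#' Intra- and extracellular concentrations (mM) of the four modelled ions.
#' Intracellular chloride is the only concentration that varies per
#' compartment during a simulation; the others are held fixed (unless the
#' dynamic-potassium mode is enabled, in which case `K_i` becomes a state
#' variable as well).
#'
#' @param ... named overrides, e.g. `ion_table(Cl_i = 10)`.
#' @return Named list of concentrations with valences attached as the
#'   `valence` attribute.
#' @export
ion_table <- function(...) {
  tab <- list(
    K_i = 140, K_o = 4, Na_i = 10, Na_o = 140,
    Cl_i = 4.25, Cl_o = 135, HCO3_i = 12, HCO3_o = 23
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(tab))
  if (length(unknown)) {
    stop("unknown ion table entries: ", paste(unknown, collapse = ", "))
  }
  tab[names(ov)] <- ov
  if (any(unlist(tab) <= 0)) stop("all concentrations must be > 0")
  attr(tab, "valence") <- c(K = 1, Na = 1, Cl = -1, HCO3 = -1)
  tab
}

#' Nernst reversal potential
#'
#' @param z ion valence (+1 for cations, -1 for anions).
#' @param Ci,Co intra- and extracellular concentrations (mM).
#' @param constants physical constants, see [phys_constants()].
#' @return Reversal potential in mV.
#' @export
#' @examples
#' nernst(-1, 4.25, 135)   # chloride, ~ -92.4 mV
nernst <- function(z, Ci, Co, constants = phys_constants()) {
  if (any(Ci <= 0) || any(Co <= 0)) stop("concentrations must be > 0")
  constants$RTF / z * log(Co / Ci)
}

#' GABA-A reversal potential from its two ionic components
#'
#' The receptor is permeable to chloride and bicarbonate in a 4:1 ratio, so
#' its reversal potential is the weighted mean (4/5) ECl + (1/5) EHCO3.
#'
#' @param ECl chloride reversal potential (mV).
#' @param EHCO3 bicarbonate reversal potential (mV).
#' @return EGABA in mV.
#' @export
egaba_combine <- function(ECl, EHCO3) {
  0.8 * ECl + 0.2 * EHCO3
}

#' Reversal potentials for a given ion table
#'
#' @param ions an [ion_table()].
#' @param constants physical constants.
#' @return Named vector with `EK`, `ENa`, `ECl`, `EHCO3`, `EGABA` (mV).
#' @export
reversal_potentials <- function(ions = ion_table(), constants = phys_constants()) {
  EK <- nernst(1, ions$K_i, ions$K_o, constants)
  ENa <- nernst(1, ions$Na_i, ions$Na_o, constants)
  ECl <- nernst(-1, ions$Cl_i, ions$Cl_o, constants)
  EHCO3 <- nernst(-1, ions$HCO3_i, ions$HCO3_o, constants)
  c(EK = EK, ENa = ENa, ECl = ECl, EHCO3 = EHCO3,
    EGABA = egaba_combine(ECl, EHCO3))
}
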