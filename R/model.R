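#' Cylinder geometry of a compartment slice
#'
#' Open-cylinder lateral surface area and cylinder volume, the quantities the
#' chloride mass balance needs (`Vol` in the d[Cl-]i/dt volume term).
#'
#' @param length_um cylinder length (um).
#' @param diam_um cylinder diameter (um).
#' @return list with `area_cm2` (lateral area, cm^2), `vol_L` (volume, L) and
#'   `vol_um3` (volume, um^3).
#' @export
#' @examples
#' cyl_geometry(100, 1)$vol_L  # ~7.854e-14 L
cyl_geometry <- function(length_um, diam_um) {
  if (any(length_um <= 0) || any(diam_um <= 0)) {
    stop("compartment length and diameter must be > 0")
  }
  area_um2 <- pi * diam_um * length_um
  vol_um3 <- pi * (diam_um / 2)^2 * length_um
  list(
    area_cm2 = area_um2 * 1e-8,   # 1 um^2 = 1e-8 cm^2
    vol_L = vol_um3 * 1e-15,      # 1 um^3 = 1e-15 L
    vol_um3 = vol_um3
  )
}

default_parameters <- function() {
  list(
    sections = list(
      # soma dimensions are a model choice (typical pyramidal scale); the
      # dendrite/axon dimensions follow the reference morphology
      soma = list(length = 13, diam = 13, n = 10),
      proximal = list(length = 50, diam = 2, n = 10),
      distal = list(length = 500, diam = 0.5, n = 20),
      axon = list(length = 500, diam = 0.1, n = 10)
    ),
    membrane = list(cm = 1, Ra = 100),      # uF/cm^2, Ohm cm
    # leak densities (S/cm^2) in the fixed K:Na:Cl ratio 1:0.23:0.4;
    # magnitude tuned for a 365 MOhm input resistance (see tune_leaks)
    leak = list(gk = 1.351e-4, ratio = c(K = 1, Na = 0.23, Cl = 0.4)),
    channels = list(
      # axonal spike machinery; rate-function shifts are calibration
      # parameters fixed against the behavioural anchors (see vignette)
      gna = 0.12, gk = 0.01, gm = 5e-4,     # S/cm^2
      na_shift = 8, k_shift = 45,
      m_vhalf = -35, m_k = 10, m_tau = 200, # ms
      k_exponent = 1
    ),
    kcc2 = list(
      P = 1.9297e-5,                        # mA mM^-2 cm^-2 (= 100%)
      scale = c(soma = 100, proximal = 100, distal = 100, axon = 100),
      electrogenic = FALSE
    ),
    chloride = list(D = 2.03, cl_i = 4.25), # um^2/ms, mM
    ions = unclass(ion_table()),
    constants = list(F = 96485.33, R = 8.31446, T = 310.15),
    synapse = list(
      tau_rise_ampa = 0.2, tau_decay_ampa = 1.7,
      tau_rise_nmda = 2.04, tau_decay_nmda = 75.2,
      alpha = 5, beta = 0.18,               # mM^-1 ms^-1, ms^-1
      t_conc = 1, t_pulse = 1,              # mM, ms transmitter pulse
      gmax_e = 1e-3, gmax_i = 3.5e-4,       # uS (1 nS, 350 pS)
      nmda_ratio = 0.22, mg_mM = 1
    ),
    gclamp = list(baseline = 1e-4, cv = 0.1, tau = 10, n_syn = 20), # uS, -, ms, count
    init = list(vm = -71.15),                            # default start Vm (mV)
    spike = list(threshold = -20, lockout = 2)          # mV, ms
  )
}

merge_overrides <- function(defaults, overrides, path = "") {
  if (!length(overrides)) return(defaults)
  if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
    stop("overrides must be a fully named list (at ", path, ")")
  }
  for (nm in names(overrides)) {
    if (!nm %in% names(defaults)) {
      stop("unknown override key: ", paste0(path, nm))
    }
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]] <- merge_overrides(defaults[[nm]], overrides[[nm]],
                                        paste0(path, nm, "$"))
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

#' Build the default multi-compartment neuron model
#'
#' Constructs the four-section model (soma, short thick proximal dendrite,
#' long thin distal dendrite, axon) discretized into cylindrical
#' compartments arranged as a single unbranched chain:
#' distal tip -> proximal -> soma -> axon tip.
#'
#' @param overrides nested named list of parameter overrides; unknown keys
#'   raise an error.  E.g. `list(sections = list(distal = list(diam = 1)))`.
#' @return An object of class `neuron_model`: the resolved parameter set plus
#'   a compartment table (`$comp`) and inter-compartment coupling
#'   coefficients (`$interfaces`).
#' @export
#' @examples
#' m <- neuron_model()
#' m$params$sections$distal$diam   # 0.5 um
neuron_model <- function(overrides = list()) {
  params <- merge_overrides(default_parameters(), overrides)
  secs <- params$sections
  for (nm in names(secs)) {
    s <- secs[[nm]]
    if (s$length <= 0 || s$diam <= 0 || s$n < 1) {
      stop("invalid geometry for section '", nm, "'")
    }
  }
  # chain order: distal tip first, then proximal, soma, axon tip last
  order_secs <- c("distal", "proximal", "soma", "axon")
  rows <- list()
  for (nm in order_secs) {
    s <- secs[[nm]]
    dl <- s$length / s$n
    g <- cyl_geometry(dl, s$diam)
    # within-section order: distal stored tip->base; others base->tip
    idx <- seq_len(s$n)
    rows[[nm]] <- data.frame(
      section = nm, idx = idx, L_um = dl, diam_um = s$diam,
      area_cm2 = g$area_cm2, vol_L = g$vol_L, vol_um3 = g$vol_um3,
      stringsAsFactors = FALSE
    )
  }
  # flip the distal section so the chain runs tip -> junction
  rows$distal <- rows$distal[rev(seq_len(nrow(rows$distal))), ]
  rows$proximal <- rows$proximal[rev(seq_len(nrow(rows$proximal))), ]
  comp <- do.call(rbind, rows[order_secs])
  rownames(comp) <- NULL
  n <- nrow(comp)

  # path distance of each compartment midpoint from the soma centre (um);
  # positive towards the dendrites, negative along the axon
  soma_rows <- which(comp$section == "soma")
  mid_soma <- soma_rows[ceiling(length(soma_rows) / 2)]
  cum <- cumsum(comp$L_um) - comp$L_um / 2
  comp$dist_um <- cum[mid_soma] - cum
  comp$dist_um[comp$section == "axon"] <- -abs(comp$dist_um[comp$section == "axon"])

  # interface couplings between consecutive compartments
  Ra <- params$membrane$Ra
  D <- params$chloride$D
  cross_cm2 <- pi * (comp$diam_um / 2 * 1e-4)^2
  half_cm <- comp$L_um / 2 * 1e-4
  r_ohm <- Ra * half_cm / cross_cm2          # half-compartment axial resistance
  g_ax <- 1e6 / (r_ohm[-n] + r_ohm[-1])      # uS between i and i+1
  cross_um2 <- pi * (comp$diam_um / 2)^2
  r_diff <- (comp$L_um / 2) / (D * cross_um2)
  g_diff <- 1 / (r_diff[-n] + r_diff[-1])    # um^3/ms per mM gradient

  structure(list(
    params = params,
    comp = comp,
    interfaces = list(g_axial_uS = g_ax, g_diff = g_diff),
    n = n
  ), class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  secs <- x$params$sections
  cat("Multi-compartment neuron model (", x$n, " compartments)\n", sep = "")
  for (nm in c("soma", "proximal", "distal", "axon")) {
    s <- secs[[nm]]
    cat(sprintf("  %-8s %6.1f um x %4.2f um in %d compartments\n",
                nm, s$length, s$diam, s$n))
  }
  lk <- x$params$leak
  cat(sprintf("  leak gK = %.3g S/cm^2 (K:Na:Cl = %s)\n", lk$gk,
              paste(lk$ratio, collapse = ":")))
  cat(sprintf("  KCC2 P = %.4g mA mM^-2 cm^-2 (scales %s%%)\n",
              x$params$kcc2$P, paste(x$params$kcc2$scale, collapse = "/")))
  invisible(x)
}

#' Compartment indices of a section
#' @param model a [neuron_model()].
#' @param section section name.
#' @return integer vector of compartment row indices (chain order).
#' @export
section_index <- function(model, section) {
  which(model$comp$section == section)
}

#' Leak conductance densities honouring the fixed ratio
#' @param model a [neuron_model()].
#' @return named vector gk, gna, gcl (S/cm^2).
#' @export
leak_densities <- function(model) {
  lk <- model$params$leak
  c(gk = lk$gk, gna = lk$gk * lk$ratio[["Na"]], gcl = lk$gk * lk$ratio[["Cl"]])
}
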