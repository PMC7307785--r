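#' Read / write model configuration files
#'
#' The full resolved parameter set of a model round-trips through a plain
#' hierarchical YAML file, so every result can be regenerated from the
#' config written next to it.
#'
#' @param model a [neuron_model()].
#' @param path file path.
#' @return `write_model_config` returns the path invisibly;
#'   `read_model_config` returns a rebuilt [neuron_model()].
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "neuron_model"))
  p <- model$params
  p$kcc2$scale <- as.list(p$kcc2$scale)
  p$leak$ratio <- as.list(p$leak$ratio)
  yaml::write_yaml(p, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  p <- yaml::read_yaml(path)
  p$kcc2$scale <- unlist(p$kcc2$scale)
  p$leak$ratio <- unlist(p$leak$ratio)
  neuron_model(p)
}

#' Read / write recovery traces as two-column text
#'
#' Tab-separated text with a header naming the units
#' (`time_s`, `cl_mM`).
#'
#' @param trace data.frame with `time_s`, `cl_mM` (e.g. from
#'   [generate_recovery()]).
#' @param path file path.
#' @export
write_recovery_trace <- function(trace, path) {
  utils::write.table(trace[, c("time_s", "cl_mM")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recovery_trace
#' @export
read_recovery_trace <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Run a named figure-level protocol end to end
#'
#' Orchestrates the pipelines behind the headline analyses at configurable
#' (default, reduced) problem sizes.  Every stage is seeded from the single
#' `seed`, and a manifest describing the run (resolved sizes, seed,
#' package version, timing) is returned with the results and, if `out` is
#' given, written alongside them.
#'
#' @param name one of `"calibration_demo"`, `"fig2_profiles"`,
#'   `"fig3_rates"`, `"fig4_io"`, `"fig5_heatmaps"`, `"fig6_index_sweep"`,
#'   `"s1_sweeps"`.
#' @param overrides named list of protocol-size overrides (e.g.
#'   `list(trials = 2)`); unknown keys raise an error.
#' @param out optional output directory; results are written as tabular
#'   text plus a YAML manifest.
#' @param seed master seed.
#' @param model optional pre-built (tuned) model; the default model is used
#'   otherwise.
#' @return list with `manifest` and `result` (protocol-specific).
#' @export
run_protocol <- function(name, overrides = list(), out = NULL, seed = 1,
                         model = NULL) {
  known <- c("calibration_demo", "fig2_profiles", "fig3_rates", "fig4_io",
             "fig5_heatmaps", "fig6_index_sweep", "s1_sweeps")
  if (!name %in% known) {
    stop("unknown protocol '", name, "'; available: ",
         paste(known, collapse = ", "))
  }
  t0 <- proc.time()[["elapsed"]]
  if (is.null(model)) model <- neuron_model()
  result <- switch(name,
    calibration_demo = protocol_calibration_demo(overrides, seed),
    fig2_profiles = protocol_fig2_profiles(model, overrides, seed),
    fig3_rates = protocol_fig3_rates(model, overrides, seed),
    fig4_io = protocol_fig4_io(model, overrides, seed),
    fig5_heatmaps = protocol_fig5_heatmaps(overrides, seed),
    fig6_index_sweep = protocol_fig6_sweep(model, overrides, seed),
    s1_sweeps = protocol_s1_sweeps(model, overrides, seed))
  manifest <- list(
    protocol = name, seed = seed,
    overrides = overrides,
    package_version = as.character(utils::packageVersion("cldyn")),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
    write_model_config(model, file.path(out, "model_config.yaml"))
    for (nm in names(result)) {
      if (is.data.frame(result[[nm]])) {
        utils::write.table(result[[nm]],
                           file.path(out, paste0(nm, ".tsv")), sep = "\t",
                           row.names = FALSE, quote = FALSE)
      }
    }
  }
  list(manifest = manifest, result = result)
}

opt <- function(overrides, name, default) {
  if (name %in% names(overrides)) overrides[[name]] else default
}

protocol_calibration_demo <- function(overrides, seed) {
  noise <- opt(overrides, "noise_sd", 0.3)
  trace <- generate_recovery(noise_sd = noise, seed = seed)
  fit <- fit_recovery(trace$time_s, trace$cl_mM)
  list(trace = trace,
       estimate = data.frame(P_conc = fit$P_conc, P_current = fit$P_current,
                             tau_s = fit$tau_s, baseline = fit$baseline),
       fit = fit)
}

protocol_fig2_profiles <- function(model, overrides, seed) {
  n_exc <- opt(overrides, "n_exc", 250)
  n_inh <- opt(overrides, "n_inh", 300)
  rate <- opt(overrides, "rate_hz", 5)
  duration <- opt(overrides, "duration", 1000)
  modes <- list(excitatory = c(n_exc, 0), inhibitory = c(0, n_inh),
                balanced = c(n_exc, n_inh))
  prof <- lapply(names(modes), function(nm) {
    v <- modes[[nm]]
    sim <- simulate_neuron(model, fin_stimulus(v[1], v[2], rate),
                           duration = duration, seed = seed)
    data.frame(drive = nm, dist_um = model$comp$dist_um,
               section = model$comp$section, cl_mM = sim$end_state$cl)
  })
  list(profiles = do.call(rbind, prof))
}

protocol_fig3_rates <- function(model, overrides, seed) {
  freqs <- opt(overrides, "freqs", c(5, 10, 20))
  n_exc <- opt(overrides, "n_exc", 250)
  n_inh <- opt(overrides, "n_inh", 300)
  trials <- opt(overrides, "trials", 3)
  duration <- opt(overrides, "duration", 1000)
  rows <- list()
  for (f in freqs) {
    for (mode in c("dynamic", "static")) {
      rr <- vapply(seq_len(trials), function(k) {
        sim <- simulate_neuron(model, fin_stimulus(n_exc, n_inh, f),
                               duration = duration, chloride = mode,
                               seed = subseed(seed, f * 100 + k),
                               record = model$n, record_dt = duration)
        mean_rate(sim$spikes, duration)
      }, numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        input_hz = f, chloride = mode, rate_hz = mean(rr))
    }
  }
  list(rates = do.call(rbind, rows))
}

protocol_fig4_io <- function(model, overrides, seed) {
  grid <- opt(overrides, "grid", seq(50, 400, by = 50))
  n_inh <- opt(overrides, "n_inh", c(0, 100))
  trials <- opt(overrides, "trials", 3)
  rows <- list()
  for (ni in n_inh) {
    for (mode in c("dynamic", "static")) {
      cv <- io_curve(model, grid, ni, "synapses", mode, trials = trials,
                     seed = subseed(seed, ni + (mode == "static")))
      rows[[length(rows) + 1]] <- cbind(cv$curve, n_inh = ni,
                                        chloride = mode)
    }
  }
  list(io = do.call(rbind, rows))
}

protocol_fig5_heatmaps <- function(overrides, seed) {
  model <- neuron_model(list(sections = list(distal = list(diam = 1.0))))
  exc <- opt(overrides, "exc_grid", c(4, 8, 12, 16, 20))
  inh <- opt(overrides, "inh_grid", c(0, 4, 8))
  times <- opt(overrides, "times_ms", c(20, 100, 500, 1000))
  K <- opt(overrides, "trials", 5)
  duration <- max(times)
  rows <- list()
  for (e in exc) for (i in inh) for (mode in c("dynamic", "static")) {
    trains <- lapply(seq_len(K), function(k) {
      sim <- simulate_neuron(model, gclamp_stimulus(e, i),
                             duration = duration, chloride = mode,
                             seed = subseed(seed, e * 1000 + i * 10 + k),
                             record = model$n, record_dt = duration)
      sim$spikes
    })
    rows[[length(rows) + 1]] <- data.frame(
      rel_exc = e, rel_inh = i, chloride = mode, t_ms = times,
      ifr_hz = ifr(trains, times))
  }
  list(ifr = do.call(rbind, rows))
}

protocol_fig6_sweep <- function(model, overrides, seed) {
  points <- opt(overrides, "points", NULL)
  sweep <- if (!is.null(points)) {
    utils::head(default_index_sweep(), points)
  } else {
    default_index_sweep()
  }
  grid <- opt(overrides, "grid", seq(0, 14, by = 1))
  trials <- opt(overrides, "trials", 2)
  sw <- index_egaba_sweep(sweep, model, grid = grid, trials = trials,
                          seed = seed)
  list(sweep = sw$table,
       correlation = data.frame(r = sw$r, n = sum(is.finite(sw$table$index))),
       object = sw)
}

protocol_s1_sweeps <- function(model, overrides, seed) {
  trials <- opt(overrides, "trials", 3)
  grid <- opt(overrides, "grid", seq(0, 14, by = 1))
  sweep <- rbind(
    data.frame(rin_scale = c(0.5, 1, 2), distal_kcc2_pct = NA,
               duration = 1000, dynamic_k = FALSE, inhibition = 4),
    data.frame(rin_scale = 1, distal_kcc2_pct = c(200, 400),
               duration = 1000, dynamic_k = FALSE, inhibition = 4),
    data.frame(rin_scale = 1, distal_kcc2_pct = NA,
               duration = c(500, 2000), dynamic_k = FALSE, inhibition = 4),
    data.frame(rin_scale = 1, distal_kcc2_pct = NA, duration = 1000,
               dynamic_k = TRUE, inhibition = 4))
  sw <- index_egaba_sweep(sweep, model, grid = grid, trials = trials,
                          seed = seed)
  list(sweep = sw$table,
       correlation = data.frame(r = sw$r, n = sum(is.finite(sw$table$index))))
}

#' Default sweep grid of the chloride-index protocol
#'
#' KCC2 pump strength 25-200% crossed with distal diameters 0.5-2 um and
#' three inhibition levels.
#'
#' @return data.frame of sweep points.
#' @export
default_index_sweep <- function() {
  expand.grid(pkcc2_pct = c(25, 50, 100, 200),
              distal_diam = c(0.5, 1.0, 2.0),
              inhibition = c(2, 4, 8))
}
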