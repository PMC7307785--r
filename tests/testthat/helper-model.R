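# small, fast model variants used across the suite
small_model <- function(overrides = list()) {
  base <- list(sections = list(
    soma = list(n = 4), proximal = list(n = 4),
    distal = list(n = 8), axon = list(n = 10)))
  neuron_model(utils::modifyList(base, overrides))
}

# model with every chloride flux disabled (no Cl leak, no KCC2)
no_cl_flux_model <- function() {
  m <- small_model(list(leak = list(ratio = c(K = 1, Na = 0.23, Cl = 0))))
  m$params$kcc2$scale[] <- 0
  m
}
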