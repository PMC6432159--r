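# Reduced-scale study ensembles shared across test files, computed once.
# Conditions: N = 32 chain, M = 32 runs, screened (implicit-salt)
# electrostatics, weak (E = 0.2) and strong (E = 32) driving.

.ens_cache <- new.env(parent = emptyenv())

reduced_cfg <- function(E) {
  system_config(N = 32, E = E, electrostatics = "screened",
                frame_stride = if (E >= 8) 5L else 200L,
                seed = 2024L)
}

reduced_ensemble <- function(E) {
  key <- paste0("E", E)
  if (is.null(.ens_cache[[key]])) {
    cfg <- reduced_cfg(E)
    .ens_cache[[key]] <- run_ensemble(cfg, M = 32L, seed = 5000L + round(E))
  }
  .ens_cache[[key]]
}
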