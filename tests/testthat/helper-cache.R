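# Shared cache of expensive steady states: computed on first use, reused
# across test files within one test run.
.lj_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .lj_cache)) {
    assign(name, force(expr), envir = .lj_cache)
  }
  get(name, envir = .lj_cache)
}

steady <- function(K_S, K_adh, ...) {
  key <- paste0("st_", K_S, "_", K_adh)
  cached(key, simulate_condition(K_S, K_adh, ...))
}

mean_L <- function(m) (m$L_psm_nt_L + m$L_psm_nt_R) / 2
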