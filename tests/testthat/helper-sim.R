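## Shared simulation cache: the full-precision butyrate 7% run is used by
## several test files; compute it once per test session.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

sim_butyrate7 <- function() {
  cached("b7", run_simulation(treatment_config("butyrate", 7),
                              kinetic_params("butyrate")))
}

## coarser settings for calibration tests: shorter horizon, looser
## tolerances -- plenty for range-scaled least squares on sampled series
fit_config <- function(cSource = "butyrate", o2 = 7) {
  treatment_config(cSource, o2, tEnd = 80, rtol = 1e-6, atol = 1e-13)
}
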