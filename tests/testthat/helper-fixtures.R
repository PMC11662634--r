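# Shared fixtures. Everything is generated in code; the model is fully
# deterministic, seeds only pin down the random probe states.

baseline_params <- function(D = 2.5) {
  p <- fontan_params()
  p$fenestration$D <- D
  p
}

# coarse-but-converged settings for tests that only need a valid cycle
fast_settings <- function() integrator_settings(dt = 0.1, max_beats = 200)

# random plausible state vectors for property checks
random_states <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    s <- c(V_SV = runif(1, 5, 60), V_SA = runif(1, 1, 12),
           V_Ca_s = runif(1, 15, 60), V_Cv_s = runif(1, 150, 450),
           V_Ca_p = runif(1, 15, 70), V_Cv_p = runif(1, 10, 40))
    s
  })
}

state_names6 <- function() c("V_SV", "V_SA", "V_Ca_s", "V_Cv_s",
                             "V_Ca_p", "V_Cv_p")

# cache one converged baseline beat across tests (computed on first use)
.cache <- new.env(parent = emptyenv())
baseline_beat <- function() {
  if (is.null(.cache$beat))
    .cache$beat <- run_to_steady_state(baseline_params(), SBV = 450)
  .cache$beat
}
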