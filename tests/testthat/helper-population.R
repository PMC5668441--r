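# Shared, lazily built simulation fixtures. Population-level objects use a
# deliberately scaled-down protocol (short pre-run, small n) so the whole
# suite stays inside a desktop-minutes budget; every consumer of these
# fixtures tests relative/structural properties, not absolute steady-state
# values.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!exists(name, .fixture_env)) {
    val <- switch(
      name,
      settings_small = solver_settings(duration_s = 100, window_s = 25),
      control_candidates = {
        samples <- sample_population(40, interval = c(0.5, 2), seed = 42)
        simulate_candidates(samples, settings = fixture("settings_small"))
      },
      control_pop = calibrate(fixture("control_candidates"),
                              default_control_ranges()),
      mutant_pop = transfect(fixture("control_pop"),
                             settings = fixture("settings_small")),
      mutant_classified = classify(fixture("mutant_pop")),
      baseline_control_sim = run_to_steady_state(
        cell_parameters(), settings = solver_settings(duration_s = 300)),
      stop("unknown fixture: ", name)
    )
    assign(name, val, .fixture_env)
  }
  get(name, .fixture_env)
}

# a valid mid-AP state for current/derivative checks (diastolic baseline
# pushed to a depolarised voltage with plausible gate values)
depolarised_state <- function(Vm_V = 0.01) {
  st <- initial_state()
  st[["Vm"]] <- Vm_V
  st[["d"]] <- 0.6; st[["f1"]] <- 0.2; st[["f2"]] <- 0.4
  st[["Xr1"]] <- 0.8; st[["Xr2"]] <- 0.2; st[["Xs"]] <- 0.1
  st[["m"]] <- 0.95; st[["h"]] <- 0.05; st[["j"]] <- 0.05
  st[["mL"]] <- 0.8; st[["hL"]] <- 0.1
  st
}
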