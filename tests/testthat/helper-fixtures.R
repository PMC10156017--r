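suppressPackageStartupMessages(library(dplyr))

# Shared fixtures, computed once per test run and cached.
# Everything is generated in code; sizes are reduced relative to the
# package defaults where noted so the whole suite stays fast.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, fixture_env)) assign(name, expr, fixture_env)
  get(name, fixture_env)
}

# F-I curve on a reduced grid (60 points, 2 s per point); the full-grid
# defaults are exercised once in the acceptance tests
fi_small <- function() {
  cached("fi_small", fi_curve(current_grid = seq(0, 80, length.out = 60),
                              sim_time = 2, discard = 0.5))
}

ref_waveform <- function() cached("ref_waveform", reference_staircase())

ref_identity <- function() {
  cached("ref_identity", odorant_identity("reference", 0.005, 1))
}

ref_osn <- function() {
  cached("ref_osn",
         osn_frontend(aldnp:::drive_matrix(ref_identity(), ref_waveform())))
}

# reduced-trial reference recording (8 trials instead of 20)
ref_recording <- function() {
  cached("ref_recording",
         generate_reference(waveform = ref_waveform(), n_trials = 8,
                            seed = 1, fi = fi_small()))
}

ref_traces <- function() {
  cached("ref_traces",
         simulate_single_channel(default_circuit_params(), ref_osn(),
                                 seed = 1))
}

# 6-channel probe identity whose strongest channel matches the recorded one
probe_identity6 <- function() {
  cached("probe_identity6",
         odorant_identity("probe",
                          c(0.005, 0.002, 8e-4, 3e-4, 1e-4, 0), rep(1, 6)))
}

expect_within <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%.6g - %.6g| <= %g", actual, expected, tol))
}
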