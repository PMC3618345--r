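# Shared fixtures: the calibrated default model and the scaled-down
# combined-ischemia reference run are built once per test session.

.fixtures <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.fixtures$model)) .fixtures$model <- calibrate_model()
  .fixtures$model
}

# tuned combined-ischemia configuration for the half-length strand
test_ischemia <- function() {
  if (is.null(.fixtures$ischemia))
    .fixtures$ischemia <- tune_ischemia(test_model(), midpoint = 8)
  .fixtures$ischemia
}

# reference combined-ischemia run: half-length strand at the resolution the
# self-convergence comparison supports
reference_run <- function() {
  if (is.null(.fixtures$ref)) {
    .fixtures$ref <- run_simulation(
      test_model(), mesh_1d(16, 0.25), test_ischemia(),
      duration = 5 * 60 * 1e3, settings = solver_settings(dt = 500),
      snapshot_every = 60e3)
  }
  .fixtures$ref
}

# the same experiment with dx and dt coarsened by a factor of two
coarse_reference_run <- function() {
  if (is.null(.fixtures$coarse)) {
    .fixtures$coarse <- run_simulation(
      test_model(), mesh_1d(16, 0.5), test_ischemia(),
      duration = 5 * 60 * 1e3, settings = solver_settings(dt = 1000),
      snapshot_every = 5 * 60 * 1e3)
  }
  .fixtures$coarse
}

# independent brute-force inversion of the buffering map
bisect_free <- function(c_total, buffer) {
  vapply(c_total, function(t1) {
    if (t1 <= 0) return(t1)
    lo <- 0; hi <- t1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (mid + buffer_bound(mid, buffer) > t1) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

# forward buffering + SR map used as the independent oracle for the calcium
# cubic inversion
ca_total_from_free_oracle <- function(free, buffer, ca, geometry) {
  q <- if (ca$p_leak > 0) ca$v_max / ca$p_leak else 0
  sr <- free + q * free / (free + ca$k_serca)
  free + buffer_bound(free, buffer) + (geometry$f_sr / geometry$f_cyt) * sr
}
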