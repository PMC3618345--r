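# Sizing the ischemic component intensities.
#
# The level of pump inhibition, K-channel activation and metabolic/
# respiratory source rates in early ischemia are not directly measurable, so
# each component intensity is sized against a representative physiological
# target after 5 minutes, following the calibration order respiratory
# acidosis -> metabolic acidosis -> NaK inhibition -> IKb activation (the
# potassium channel last, in the presence of the other three). The targets
# are end-of-run values in the ischemic core, evaluated on the closed 0D
# cell, which the deep core of the strand approximates.

#' Physiological targets for the combined-ischemia reference run
#'
#' Representative consensus values after 5 minutes of ischemia: extracellular
#' CO2 doubled, intracellular pH fallen by half a unit, intracellular Na+ up
#' by half (the level the mid-range pump-inhibition sweep produces on its
#' own), and extracellular K+ risen to about 9 mM.
#'
#' @return named list of targets: `co2_e`, `ph_i`, `na_i`, `k_e`.
#' @export
ischemia_targets <- function() {
  list(co2_e = 2.34, ph_i = 6.6, na_i = 6, k_e = 9)
}

tune_bisect <- function(f, lo, hi, target, increasing = TRUE, iters = 18) {
  flo <- f(lo); fhi <- f(hi)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    hit_hi <- xor(fm < target, !increasing)
    if (hit_hi) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Size the four ischemic component intensities to their targets
#'
#' Sequential one-dimensional root finding on the closed 0D core cell:
#' the CO2 source is sized to the extracellular CO2 target, the H+/lactate
#' source (with respiratory acidosis active) to the intracellular pH target,
#' the NaK inhibition (with both acidoses active) to the intracellular Na+
#' target, and finally the K-background activation (with all three active)
#' to the extracellular K+ target. Deterministic; about forty short 0D
#' integrations.
#'
#' @param model calibrated model.
#' @param targets list from [ischemia_targets()].
#' @param duration evaluation horizon (ms; default 5 minutes).
#' @param settings [solver_settings()] for the 0D runs.
#' @param midpoint,steepness severity-profile parameters to carry into the
#'   returned configuration.
#' @param iters bisection iterations per component.
#' @return an [ischemia_config()] with the tuned intensities.
#' @export
tune_ischemia <- function(model, targets = ischemia_targets(),
                          duration = 5 * 60 * 1e3,
                          settings = solver_settings(dt = 5000),
                          midpoint = 16, steepness = 60, iters = 12) {
  core <- function(cfg, what) {
    tr <- run_cell(model, duration = duration, settings = settings,
                   ischemia = cfg)
    nt <- length(tr$times)
    switch(what,
           co2_e = tr$free["CO2", 1, 2, nt],
           ph_i = h_to_ph(tr$free["H", 1, 1, nt]),
           na_i = tr$free["Na", 1, 1, nt],
           k_e = tr$free["K", 1, 2, nt])
  }
  mk <- function(nak = 0, ikb = 1, co2 = 0, h = 0)
    ischemia_config(nak_inhibition = nak, ikb_activation = ikb,
                    co2_source = co2, h_source = h,
                    midpoint = midpoint, steepness = steepness)
  # respiratory source sized alone against the CO2 rise
  co2_src <- tune_bisect(function(v) core(mk(co2 = v), "co2_e"),
                         0, 1e-4, targets$co2_e, TRUE, iters)
  # metabolic source sized with respiratory acidosis present (combined pH drop)
  h_src <- tune_bisect(function(v) core(mk(co2 = co2_src, h = v), "ph_i"),
                       0, 5e-4, targets$ph_i, FALSE, iters)
  # pump inhibition sized alone against the Na+ rise (acid-activated NHE
  # already loads the cell with Na+, so the component is sized in isolation)
  nak <- tune_bisect(function(v) core(mk(nak = v), "na_i"),
                     0, 1, targets$na_i, TRUE, iters)
  # K background activation last, with the other three components active
  ikb <- tune_bisect(function(v) core(mk(nak = nak, ikb = v, co2 = co2_src,
                                         h = h_src), "k_e"),
                     1, 30, targets$k_e, TRUE, iters)
  mk(nak = nak, ikb = ikb, co2 = co2_src, h = h_src)
}

#' Combined-ischemia reference experiment
#'
#' Runs the reference simulation with all four ischemic components at their
#' tuned (or supplied) intensities. This is the run the border-zone and flux
#' analyses consume.
#'
#' @param model calibrated model.
#' @param mesh a [mesh_1d()].
#' @param ischemia an [ischemia_config()]; if NULL, [tune_ischemia()] is run
#'   first with the severity profile centred on the strand.
#' @param duration simulated time (ms; default 5 minutes).
#' @param settings [solver_settings()].
#' @param ... passed to [run_simulation()].
#' @return an `ionbz_trajectory`.
#' @export
combined_ischemia <- function(model, mesh, ischemia = NULL,
                              duration = 5 * 60 * 1e3,
                              settings = solver_settings(), ...) {
  if (is.null(ischemia))
    ischemia <- tune_ischemia(model, midpoint = mesh$length / 2)
  run_simulation(model, mesh, ischemia, duration, settings, ...)
}
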