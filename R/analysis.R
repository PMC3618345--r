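# Border-zone quantification, flux decomposition, the clamped-potential
# counterfactual and the qualitative validation grid.

#' Closed-form width of a Hill transition
#'
#' For a profile s(x) = 1/(1 + (x/mid)^n), the distance between the two
#' fractional levels of the transition.
#'
#' @param midpoint transition midpoint (mm).
#' @param n Hill steepness.
#' @param levels fractional levels (default 10% and 90% of the change).
#' @return width (mm).
#' @export
hill_width <- function(midpoint, n, levels = c(0.1, 0.9)) {
  x_at <- function(p) midpoint * ((1 - p) / p)^(1 / n)
  abs(x_at(levels[1]) - x_at(levels[2]))
}

#' Fit a Hill transition to an ionic profile
#'
#' Least-squares fit of c(x) = base + amp / (1 + (x/mid)^n) with
#' deterministic initial guesses derived from profile quantiles (no random
#' restarts). Profiles whose amplitude is below the noise floor yield the
#' "no BZ" sentinel (`no_bz = TRUE`, `bz_width = NA`) rather than a width of
#' zero.
#'
#' @param x node positions (mm), at least 10 spanning the transition.
#' @param conc end-state concentrations at those positions.
#' @param levels fractional levels defining the width.
#' @param noise_floor minimum |amplitude| relative to the baseline magnitude
#'   for a profile to count as a border zone.
#' @return object of class `bz_fit`: `baseline`, `amplitude`, `midpoint`,
#'   `steepness`, `bz_width`, `gof` (residual standard deviation), `no_bz`.
#' @export
fit_bz_profile <- function(x, conc, levels = c(0.1, 0.9),
                           noise_floor = 1e-3) {
  stopifnot(length(x) == length(conc))
  if (length(x) < 10) stop("fit_bz_profile: need at least 10 nodes")
  ord <- order(x); x <- x[ord]; conc <- conc[ord]
  n_pts <- length(x)
  base0 <- conc[n_pts]          # viable end
  amp0 <- conc[1] - base0       # core minus viable
  scale0 <- max(abs(conc), 1e-12)
  if (abs(amp0) < noise_floor * scale0 + 1e-9) {
    return(structure(list(baseline = base0, amplitude = amp0,
                          midpoint = NA_real_, steepness = NA_real_,
                          bz_width = NA_real_, gof = NA_real_, no_bz = TRUE),
                     class = "bz_fit"))
  }
  # midpoint guess: position where the profile crosses half its change
  half <- base0 + amp0 / 2
  cross <- which(diff(sign(conc - half)) != 0)
  mid0 <- if (length(cross)) x[cross[1]] else stats::median(x)
  fit <- NULL
  for (n0 in c(10, 3, 40, 100)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        conc ~ base + amp / (1 + (x / mid)^n),
        start = list(base = base0, amp = amp0, mid = mid0, n = n0),
        lower = c(-Inf, -Inf, 1e-6, 1),
        upper = c(Inf, Inf, max(x) * 10, 1e4),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # deterministic fallback for profiles a Hill curve cannot start on:
    # interpolated positions of the fractional levels of the end-to-end change
    lev <- base0 + amp0 * (1 - levels)
    xs <- vapply(lev, function(l) {
      cr <- which(diff(sign(conc - l)) != 0)
      if (!length(cr)) return(NA_real_)
      i <- cr[1]
      x[i] + (l - conc[i]) * (x[i + 1] - x[i]) / (conc[i + 1] - conc[i])
    }, numeric(1))
    return(structure(list(baseline = base0, amplitude = amp0,
                          midpoint = mean(xs), steepness = NA_real_,
                          bz_width = abs(diff(xs)), gof = NA_real_,
                          no_bz = FALSE),
                     class = "bz_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(baseline = unname(cf["base"]), amplitude = unname(cf["amp"]),
                 midpoint = unname(cf["mid"]), steepness = unname(cf["n"]),
                 bz_width = unname(hill_width(cf["mid"], cf["n"], levels)),
                 gof = stats::sd(stats::resid(fit)), no_bz = FALSE),
            class = "bz_fit")
}

#' @export
print.bz_fit <- function(x, ...) {
  if (x$no_bz) cat("no border zone (amplitude below noise floor)\n")
  else cat(sprintf(
    "BZ fit: base %.4g, amp %.4g, midpoint %.3g mm, n %.3g, width %.3g mm\n",
    x$baseline, x$amplitude, x$midpoint, x$steepness, x$bz_width))
  invisible(x)
}

#' Border-zone width table for a trajectory
#'
#' Fits the end-state spatial profile of every species in both domains and
#' tabulates widths with the relative gradient magnitude (change over the
#' initial concentration).
#'
#' @param traj an `ionbz_trajectory` from [run_simulation()].
#' @param levels fractional levels defining the width.
#' @return data.frame with columns `species`, `domain`, `width`,
#'   `amplitude`, `rel_change`, `no_bz`.
#' @export
bz_width_table <- function(traj, levels = c(0.1, 0.9)) {
  nt <- length(traj$times)
  x <- traj$mesh$x
  rows <- list()
  for (k in 1:8) {
    for (d in 1:2) {
      prof <- traj$free[k, , d, nt]
      init <- traj$free[k, 1, d, 1]
      fit <- fit_bz_profile(x, prof, levels)
      rows[[length(rows) + 1]] <- data.frame(
        species = SPECIES[k], domain = c("i", "e")[d],
        width = fit$bz_width, amplitude = fit$amplitude,
        rel_change = fit$amplitude / init, no_bz = fit$no_bz,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Flux-ledger decomposition of a trajectory
#'
#' Formats the cumulative per-node transmembrane / diffusion / drift / source
#' tallies accumulated during the run and reports the closure defect against
#' the total concentration change (the conservation audit).
#'
#' @param traj an `ionbz_trajectory` with a ledger (from [run_simulation()]).
#' @return list with `ledger` (long data.frame: species, domain, x, and the
#'   four cumulative contributions in mM plus `delta` and `closure`) and
#'   `max_closure_defect` (mM).
#' @export
flux_decomposition <- function(traj) {
  if (is.null(traj$ledger)) stop("flux_decomposition: trajectory has no ledger")
  nt <- length(traj$times)
  n <- traj$mesh$n
  out <- list()
  max_def <- 0
  for (d in 1:2) {
    dc <- traj$conc[, , d, nt] - traj$conc[, , d, 1]
    if (n == 1) dc <- matrix(dc, 8, 1)
    led <- traj$ledger$trans[, , d] + traj$ledger$diff[, , d] +
      traj$ledger$drift[, , d] + traj$ledger$src[, , d]
    max_def <- max(max_def, max(abs(dc - led)))
    for (k in 1:8) {
      out[[length(out) + 1]] <- data.frame(
        species = SPECIES[k], domain = c("i", "e")[d], x = traj$mesh$x,
        transmembrane = traj$ledger$trans[k, , d],
        diffusion = traj$ledger$diff[k, , d],
        drift = traj$ledger$drift[k, , d],
        source = traj$ledger$src[k, , d],
        delta = dc[k, ],
        stringsAsFactors = FALSE)
    }
  }
  ledger <- do.call(rbind, out)
  ledger$closure <- with(ledger, transmembrane + diffusion + drift + source - delta)
  list(ledger = ledger, max_closure_defect = max_def)
}

#' Clamped-potential counterfactual
#'
#' Repeats the reference ischemia simulation while exposing one pathway (the
#' K background channel or the NaK pump) to a sharp-transition surrogate
#' membrane potential that preserves the true field's extrema at every step,
#' isolating the role of the smooth potential gradient in widening the
#' extracellular potassium border zone.
#'
#' @param model calibrated model.
#' @param mesh a [mesh_1d()].
#' @param ischemia an [ischemia_config()].
#' @param duration simulated time (ms).
#' @param settings [solver_settings()].
#' @param pathways pathways to clamp (default "Kb").
#' @param reference optional precomputed reference trajectory.
#' @return list with `reference`, per-pathway `clamped` trajectories, and a
#'   `widths` data.frame comparing the extracellular K+ BZ width.
#' @export
clamped_potential_experiment <- function(model, mesh, ischemia,
                                         duration = 5 * 60 * 1e3,
                                         settings = solver_settings(),
                                         pathways = "Kb",
                                         reference = NULL) {
  if (is.null(reference))
    reference <- run_simulation(model, mesh, ischemia, duration, settings)
  clamped <- list()
  widths <- list()
  nt <- length(reference$times)
  wref <- fit_bz_profile(mesh$x, reference$free["K", , 2, nt])$bz_width
  widths[[1]] <- data.frame(run = "reference", k_e_width = wref)
  for (p in pathways) {
    tr <- run_simulation(model, mesh, ischemia, duration, settings,
                         clamp_pathway = p)
    clamped[[p]] <- tr
    wp <- fit_bz_profile(mesh$x, tr$free["K", , 2, length(tr$times)])$bz_width
    widths[[length(widths) + 1]] <- data.frame(
      run = paste0("clamped_", p), k_e_width = wp)
  }
  list(reference = reference, clamped = clamped,
       widths = do.call(rbind, widths))
}

#' Severity sweep of one ischemic component
#'
#' Runs the 1D simulation with a single ischemia component active at several
#' severity levels and summarises the change in the key observables across
#' the strand (the band plots of the component analysis).
#'
#' @param model calibrated model.
#' @param mesh a [mesh_1d()].
#' @param component one of "nak", "ikb", "co2", "h".
#' @param levels component intensities; defaults: NaK inhibition 20-100%,
#'   K-background activation +50-250%, sources 20-100% of the maximum
#'   (5/3 of the combined-run default, whose value is the 60% mid level).
#' @param duration simulated time (ms).
#' @param settings [solver_settings()].
#' @param midpoint,steepness severity-profile parameters.
#' @return list with per-level trajectories and a `summary` data.frame of
#'   end-state changes (level, species, domain, node, delta).
#' @export
component_sweep <- function(model, mesh, component = c("nak", "ikb", "co2", "h"),
                            levels = NULL, duration = 5 * 60 * 1e3,
                            settings = solver_settings(),
                            midpoint = 16, steepness = 60) {
  component <- match.arg(component)
  base <- default_config()$ischemia
  if (is.null(levels)) {
    levels <- switch(component,
      nak = seq(0.2, 1, by = 0.2),
      ikb = 1 + seq(0.5, 2.5, by = 0.5),
      co2 = seq(0.2, 1, by = 0.2) * base$co2_source / 0.6,
      h = seq(0.2, 1, by = 0.2) * base$h_source / 0.6)
  }
  runs <- list(); summ <- list()
  for (lv in levels) {
    cfgargs <- list(nak_inhibition = 0, ikb_activation = 1, co2_source = 0,
                    h_source = 0, midpoint = midpoint, steepness = steepness)
    cfgargs[[switch(component, nak = "nak_inhibition",
                    ikb = "ikb_activation", co2 = "co2_source",
                    h = "h_source")]] <- lv
    isc <- do.call(ischemia_config, cfgargs)
    tr <- run_simulation(model, mesh, isc, duration, settings)
    runs[[length(runs) + 1]] <- tr
    nt <- length(tr$times)
    for (k in c(iNA, iK, iH)) {
      for (d in 1:2) {
        summ[[length(summ) + 1]] <- data.frame(
          level = lv, species = SPECIES[k], domain = c("i", "e")[d],
          node = seq_len(mesh$n), x = tr$mesh$x,
          delta = tr$free[k, , d, nt] - tr$free[k, , d, 1],
          stringsAsFactors = FALSE)
      }
    }
    summ[[length(summ) + 1]] <- data.frame(
      level = lv, species = "Vm", domain = "m", node = seq_len(mesh$n),
      x = tr$mesh$x, delta = tr$vm[, nt] - tr$vm[, 1],
      stringsAsFactors = FALSE)
  }
  list(levels = levels, component = component, runs = runs,
       summary = do.call(rbind, summ))
}

# ---------------------------------------------------------------------------
# Qualitative validation grid
# ---------------------------------------------------------------------------

#' Expected qualitative responses of the quiescent myocyte
#'
#' The 12-protocol x 6-observable grid of experimentally reported directions
#' of change in intracellular Na+, K+, Cl-, Ca2+, pH and membrane potential
#' following extracellular perturbations or transporter inhibition,
#' reconstructed from the cited experimental literature. Entries: "U" / "D"
#' (reported increase / decrease), "N" (no or missing data), "I"
#' (inconsistent reports), "Z" (no change observed).
#'
#' Row-by-row basis, in brief: low Na+e lowers a_Nai, reverses NCX (Ca2+
#' rise), slows NHE (acidifies), with an anomalous reported K+i rise
#' attributed to transporters absent here; Ca2+ steps move Ca2+i with the
#' gradient and shift Na+i/pH_i through NCX and buffer competition; acid pH_e
#' acid-loads the cell, activating NHE (Na+i rise) while cells lose K+;
#' alkaline pH_e mirrors; K+-depolarization stimulates the pump (Na+i falls),
#' depolarizes, raises Ca2+i and modestly acidifies; Cl- steps move a_Cli
#' through CHE/AE with a reported Na+i rise in both directions; hypercapnia
#' acid-loads, raising Na+i, Cl-i and Ca2+i; pump inhibition raises
#' Na+i/Cl-i/Ca2+i, lowers K+i/pH_i and depolarizes; NCX inhibition raises
#' Ca2+i, lowers Na+i and acidifies. Cells without consistent reports are
#' "N"/"I"; cells where studies explicitly found no change are "Z".
#'
#' @return data.frame: one row per protocol, expectation columns per
#'   observable plus the protocol definition used by [validation_grid()].
#' @export
expected_response_table <- function() {
  tab <- data.frame(
    protocol = c("na_down", "na_up", "ca_down", "ca_up", "ph_down", "ph_up",
                 "k_up", "cl_down", "cl_up", "co2_up", "nak_inh", "ncx_inh"),
    label = c("lower [Na]e", "raise [Na]e", "lower [Ca]e", "raise [Ca]e",
              "lower pHe", "raise pHe", "raise [K]e", "lower [Cl]e",
              "raise [Cl]e", "raise CO2 (hypercapnia)", "inhibit NaK",
              "inhibit NCX"),
    na_i = c("D", "U", "U", "D", "U", "D", "D", "U", "U", "U", "U", "D"),
    k_i  = c("U", "N", "N", "N", "D", "N", "U", "N", "N", "I", "D", "N"),
    cl_i = c("N", "N", "N", "N", "N", "N", "U", "D", "U", "U", "U", "N"),
    ca_i = c("U", "D", "D", "U", "I", "D", "U", "N", "N", "U", "U", "U"),
    ph_i = c("D", "U", "U", "D", "D", "U", "D", "U", "D", "D", "D", "D"),
    vm   = c("I", "N", "I", "Z", "Z", "Z", "U", "I", "Z", "Z", "U", "N"),
    stringsAsFactors = FALSE
  )
  tab
}

# protocol -> run_cell() arguments
grid_protocol_args <- function(protocol, model) {
  keq <- model$co2$kf / model$co2$kb
  sp <- model$species
  co2_0 <- sp$c_e0[iCO2]; hco3_0 <- sp$c_e0[iHCO3]
  switch(protocol,
    na_down = list(clamp_e = c(Na = 70)),
    na_up = list(clamp_e = c(Na = 210)),
    ca_down = list(clamp_e = c(Ca = 0.12)),
    ca_up = list(clamp_e = c(Ca = 3.6)),
    # metabolic pH steps: CO2 held, HCO3 follows the hydration equilibrium
    ph_down = list(clamp_e = c(H = ph_to_h(6.8),
                               HCO3 = keq * co2_0 / ph_to_h(6.8))),
    ph_up = list(clamp_e = c(H = ph_to_h(7.8),
                             HCO3 = keq * co2_0 / ph_to_h(7.8))),
    k_up = list(clamp_e = c(K = 12)),
    cl_down = list(clamp_e = c(Cl = 11)),
    cl_up = list(clamp_e = c(Cl = 165)),
    # respiratory step: CO2 doubled, HCO3 held, pH_e follows
    co2_up = list(clamp_e = c(CO2 = 2 * co2_0,
                              H = keq * 2 * co2_0 / hco3_0)),
    nak_inh = list(density_scale = list(nak = 0)),
    ncx_inh = list(density_scale = list(ncx = 0)),
    stop("unknown protocol: ", protocol))
}

#' Qualitative validation grid of the 0D membrane model
#'
#' Runs each perturbation / inhibition protocol on the calibrated 0D cell
#' (extracellular bath clamped for concentration steps), records the sign of
#' the change in the six observables after the holding interval, and scores
#' agreement against the experimentally reported directions: cells with
#' reported directions score match/mismatch, cells without consistent data
#' score "no data", and cells where experiments observed no change score
#' "too small" (the continuous model always produces some change). Model
#' changes below `rel_tol` of baseline are additionally flagged.
#'
#' @param model calibrated model.
#' @param duration holding time per protocol (ms; default 10 simulated
#'   minutes).
#' @param settings [solver_settings()] for the 0D runs.
#' @param rel_tol relative-change threshold for flagging tiny model responses.
#' @return list of class `ionbz_validation`: `table` (one row per cell with
#'   expected entry, model direction and outcome), `counts` (match, no_data,
#'   too_small, mismatch), and the active kinetic `variant`.
#' @export
validation_grid <- function(model, duration = 10 * 60 * 1e3,
                            settings = solver_settings(dt = 2000),
                            rel_tol = 1e-3) {
  exp_tab <- expected_response_table()
  obs_names <- c("na_i", "k_i", "cl_i", "ca_i", "ph_i", "vm")
  base <- observables_0d(NULL, model)
  rows <- list()
  for (i in seq_len(nrow(exp_tab))) {
    args <- grid_protocol_args(exp_tab$protocol[i], model)
    tr <- do.call(run_cell, c(list(model = model, duration = duration,
                                   settings = settings), args))
    obs <- observables_0d(tr, model)
    for (ob in obs_names) {
      delta <- obs[[ob]] - base[[ob]]
      scale <- max(abs(base[[ob]]), 1e-6)
      model_sign <- if (delta > 0) "U" else "D"
      expd <- exp_tab[[ob]][i]
      outcome <- switch(expd,
                        U = , D = if (model_sign == expd) "match" else "mismatch",
                        N = , I = "no_data",
                        Z = "too_small")
      rows[[length(rows) + 1]] <- data.frame(
        protocol = exp_tab$protocol[i], label = exp_tab$label[i],
        observable = ob, expected = expd, model = model_sign,
        delta = delta, tiny = abs(delta) < rel_tol * scale,
        outcome = outcome, stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  counts <- c(match = sum(table$outcome == "match"),
              no_data = sum(table$outcome == "no_data"),
              too_small = sum(table$outcome == "too_small"),
              mismatch = sum(table$outcome == "mismatch"))
  structure(list(table = table, counts = counts,
                 variant = "reduced thermodynamically consistent kinetics"),
            class = "ionbz_validation")
}

observables_0d <- function(traj, model) {
  if (is.null(traj)) {
    free_i <- model$species$c_i0
    vm <- model$vm_rest
  } else {
    nt <- length(traj$times)
    free_i <- traj$free[, 1, 1, nt]
    vm <- traj$vm[1, nt]
  }
  list(na_i = free_i[iNA], k_i = free_i[iK], cl_i = free_i[iCL],
       ca_i = free_i[iCA], ph_i = h_to_ph(free_i[iH]), vm = vm)
}

#' @export
print.ionbz_validation <- function(x, ...) {
  cat("0D membrane-model validation grid (", x$variant, ")\n", sep = "")
  cat(sprintf("  %d cells: %d match, %d no data, %d too small, %d mismatch\n",
              nrow(x$table), x$counts["match"], x$counts["no_data"],
              x$counts["too_small"], x$counts["mismatch"]))
  invisible(x)
}
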