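# Zero-net-flux calibration.
#
# Every pathway density, the unknown bicarbonate concentrations, the
# extracellular proton-buffer concentration, the Na/K/Cl diffusivities and
# the SR constants are derived from the reference resting state plus a small
# set of measured anchors, following a triangular dependency chain: the
# resting state is then an exact fixed point of the dynamics.

#' Extracellular CO2 concentration from Henry's law
#'
#' @param alpha CO2 solubility (mM/mmHg).
#' @param co2_fraction fraction of gas that is CO2.
#' @param pressure total pressure (mmHg).
#' @return dissolved CO2 (mM) = alpha * co2_fraction * pressure.
#' @export
co2_from_henry <- function(alpha, co2_fraction, pressure) {
  stopifnot(alpha >= 0, co2_fraction >= 0, pressure >= 0)
  alpha * co2_fraction * pressure
}

#' Bicarbonate concentration at hydration equilibrium
#'
#' With CO2 exchange across the membrane Fickian and hydration the only other
#' CO2 pathway, the resting constraint pins each domain's HCO3- at
#' (kf/kb) CO2 / H.
#'
#' @param co2,h concentrations (mM).
#' @param kf,kb hydration/dehydration rate constants (1/ms, 1/(mM ms)).
#' @return HCO3- concentration (mM).
#' @export
equilibrium_bicarbonate <- function(co2, h, kf, kb) {
  stopifnot(kb > 0, all(h > 0))
  (kf / kb) * co2 / h
}

#' Extracellular proton-buffer concentration from a bound-proton anchor
#'
#' Inverts the single-site mass-action relation bound = B H / (H + K) for B,
#' using the measured amount of buffered extracellular protons, the
#' extracellular pH and the binding affinity of the intracellular fit.
#'
#' @param bound_h buffered proton concentration (mM).
#' @param ph_e extracellular pH.
#' @param K dissociation constant (mM).
#' @return buffer site concentration B (mM).
#' @export
derive_proton_buffer_extracellular <- function(bound_h, ph_e, K) {
  stopifnot(bound_h >= 0, K > 0)
  h <- ph_to_h(ph_e)
  bound_h * (h + K) / h
}

#' Na/K/Cl diffusivities from tissue conductivity
#'
#' Inverts the conductivity definition sigma_s = (F^2/RT) f_s sum_k z_k^2
#' D_k c_k (free concentrations) for the single diffusivity shared by Na+,
#' K+ and Cl-, after fixing the Ca2+, H+ and HCO3- diffusivities at their
#' literature values (CO2 carries no charge; nominal lactate is excluded).
#' The intracellular sum is referenced to the cytosolic volume fraction.
#'
#' @param sigma conductivity of the domain (S/m).
#' @param f volume fraction of the domain.
#' @param conc named list/vector of free concentrations (mM) with entries
#'   `na`, `k`, `cl`, `ca`, `h`, `hco3`.
#' @param d_fixed named list of fixed diffusivities (mm^2/ms): `ca`, `h`,
#'   `hco3`.
#' @param constants [phys_constants()].
#' @return shared Na/K/Cl diffusivity (mm^2/ms).
#' @export
derive_diffusivities <- function(sigma, f, conc, d_fixed,
                                 constants = phys_constants()) {
  stopifnot(sigma > 0, f > 0)
  # S/m with D in m^2/s and c in mol/m^3 (= mM); mm^2/ms = 1e-3 m^2/s
  pref <- constants$F^2 / (constants$R * constants$temperature)
  fixed <- 4 * d_fixed$ca * conc$ca + d_fixed$h * conc$h + d_fixed$hco3 * conc$hco3
  need <- sigma / (pref * f * 1e-3)  # total sum z^2 D c in mm^2/ms * mM
  carriers <- conc$na + conc$k + conc$cl
  d <- (need - fixed) / carriers
  if (d <= 0)
    stop("derive_diffusivities: fixed-diffusivity species already exceed sigma")
  d
}

# conductivity implied by a diffusivity assignment (round-trip check)
conductivity_from_d <- function(d_nakcl, f, conc, d_fixed,
                                constants = phys_constants()) {
  pref <- constants$F^2 / (constants$R * constants$temperature)
  s <- d_nakcl * (conc$na + conc$k + conc$cl) +
    4 * d_fixed$ca * conc$ca + d_fixed$h * conc$h + d_fixed$hco3 * conc$hco3
  pref * f * 1e-3 * s
}

#' SR calcium calibration
#'
#' Enforces zero net SR flux at rest: the SERCA maximum flux is solved from
#' v_max Ca/(Ca + K) = resting uptake, and the leak permeability from
#' leak = uptake at the resting SR gradient.
#'
#' @param resting_free_ca resting free cytosolic Ca2+.
#' @param k_serca SERCA binding constant (same units as `resting_free_ca`).
#' @param resting_uptake resting SR uptake flux (concentration/ms).
#' @param sr_ca resting SR Ca2+ load.
#' @return list with `v_max` (units of `resting_uptake`) and `p_leak` (1/ms).
#' @export
calibrate_sr <- function(resting_free_ca, k_serca, resting_uptake, sr_ca) {
  stopifnot(resting_free_ca > 0, k_serca > 0, resting_uptake >= 0,
            sr_ca > resting_free_ca)
  if (resting_uptake == 0) return(list(v_max = 0, p_leak = 0))
  list(
    v_max = resting_uptake * (resting_free_ca + k_serca) / resting_free_ca,
    p_leak = resting_uptake / (sr_ca - resting_free_ca)
  )
}

#' Calibrate the full model
#'
#' Executes the parameter-derivation chain on a configuration: Henry's-law
#' CO2, hydration-equilibrium bicarbonate in both domains, the extracellular
#' proton buffer from the bound-H anchor, conductivity-derived Na/K/Cl
#' diffusivities, SR constants, every pathway density from the zero-net-flux
#' constraint, and the static charges that pin the resting membrane potential.
#' The chain is triangular, deterministic and recorded in the manifest.
#'
#' @param config an `ionbz_config` (default [default_config()]).
#' @return an object of class `ionbz_model`.
#' @export
calibrate_model <- function(config = default_config()) {
  validate_config(config)
  cst <- phys_constants(config$constants$temperature)
  geo <- do.call(tissue_geometry, config$geometry)
  cc <- config$concentrations
  man <- character()
  note <- function(...) man <<- c(man, sprintf(...))

  # --- derived concentrations -------------------------------------------
  co2_e <- co2_from_henry(config$co2$alpha, config$co2$fraction,
                          config$co2$pressure)
  co2_i <- co2_e  # zero resting Fickian flux
  note("CO2_e = %.6g mM from Henry's law (alpha * F_CO2 * P); CO2_i set equal (zero Fickian flux)", co2_e)
  h_i <- ph_to_h(cc$ph_i); h_e <- ph_to_h(cc$ph_e)
  hco3_i <- equilibrium_bicarbonate(co2_i, h_i, config$co2$kf, config$co2$kb)
  hco3_e <- equilibrium_bicarbonate(co2_e, h_e, config$co2$kf, config$co2$kb)
  note("HCO3_i = %.6g, HCO3_e = %.6g mM from hydration equilibrium (kf/kb) CO2/H", hco3_i, hco3_e)

  # --- buffers -----------------------------------------------------------
  buf_hi <- buffer_spec(config$buffers$h_i$B, ph_to_h(config$buffers$h_i$pk),
                        config$buffers$h_i$n)
  b_he <- config$buffers$h_e$B
  if (is.na(b_he)) {
    b_he <- derive_proton_buffer_extracellular(config$buffers$bound_h_e,
                                               cc$ph_e, ph_to_h(config$buffers$h_e$pk))
    note("extracellular H buffer B = %.6g mM from %g mM bound-H anchor at pH_e %.2f", b_he, config$buffers$bound_h_e, cc$ph_e)
  }
  buf_he <- buffer_spec(b_he, ph_to_h(config$buffers$h_e$pk),
                        config$buffers$h_e$n)
  buf_cai <- buffer_spec(config$buffers$ca_i$B, config$buffers$ca_i$K,
                         config$buffers$ca_i$n)
  buf_cae <- buffer_spec(config$buffers$ca_e$B, config$buffers$ca_e$K,
                         config$buffers$ca_e$n)

  # --- diffusivities -----------------------------------------------------
  dfx <- config$diffusivities
  d_fixed <- list(ca = dfx$ca, h = dfx$h, hco3 = dfx$hco3)
  d_i <- derive_diffusivities(config$conductivity$sigma_i, geo$f_cyt,
                              list(na = cc$na_i, k = cc$k_i, cl = cc$cl_i,
                                   ca = cc$ca_i, h = h_i, hco3 = hco3_i),
                              d_fixed, cst)
  d_e <- derive_diffusivities(config$conductivity$sigma_e, geo$f_e,
                              list(na = cc$na_e, k = cc$k_e, cl = cc$cl_e,
                                   ca = cc$ca_e, h = h_e, hco3 = hco3_e),
                              d_fixed, cst)
  note("shared Na/K/Cl diffusivity: D_i = %.6g, D_e = %.6g mm^2/ms from sigma = %.3g / %.3g S/m", d_i, d_e, config$conductivity$sigma_i, config$conductivity$sigma_e)

  species <- ion_species()
  species$d_i <- c(d_i, d_i, d_i, dfx$ca, dfx$h, dfx$hco3, dfx$co2, dfx$lac)
  species$d_e <- c(d_e, d_e, d_e, dfx$ca, dfx$h, dfx$hco3, dfx$co2, dfx$lac)
  lac_i <- cc$lac_e * h_e / h_i  # MCT1 equilibrium at rest
  species$c_i0 <- c(cc$na_i, cc$k_i, cc$cl_i, cc$ca_i, h_i, hco3_i, co2_i, lac_i)
  species$c_e0 <- c(cc$na_e, cc$k_e, cc$cl_e, cc$ca_e, h_e, hco3_e, co2_e, cc$lac_e)

  # --- SR ---------------------------------------------------------------
  sr <- calibrate_sr(cc$ca_i, config$calcium$k_serca,
                     config$calcium$resting_uptake, config$calcium$sr)
  note("SERCA v_max = %.6g mM/ms, SR leak = %.6g 1/ms from zero net SR flux", sr$v_max, sr$p_leak)
  ca_par <- list(v_max = sr$v_max, p_leak = sr$p_leak,
                 k_serca = config$calcium$k_serca, resting = cc$ca_i,
                 sr0 = config$calcium$sr, buffer = buf_cai)

  model <- list(
    config = config, constants = cst, geometry = geo, species = species,
    buffers = list(h_i = buf_hi, h_e = buf_he, ca_e = buf_cae),
    ca = ca_par,
    co2 = list(p_m = config$co2$p_m, kf = config$co2$kf, kb = config$co2$kb),
    kinetics = config$membrane$kinetics,
    gap_junction = config$membrane$gap_junction,
    cm = config$membrane$cm,
    vm_rest = config$membrane$vm_rest
  )
  model$vm_slope <- vm_slope_mV_per_mM(cst, geo, model$cm)

  # --- densities ---------------------------------------------------------
  model <- calibrate_densities(model, config$membrane$anchors, note)

  # --- resting totals and static charges --------------------------------
  c_i_tot <- free_i_to_tot(species$c_i0, model)
  c_e_tot <- free_e_to_tot(species$c_e0, model)
  names(c_i_tot) <- names(c_e_tot) <- SPECIES
  z <- Z_SPECIES
  model$q_static_i <- model$vm_rest / model$vm_slope - sum(z * c_i_tot)
  model$q_static_e <- -sum(z * c_e_tot) -
    (geo$f_cyt / geo$f_e) * (sum(z * c_i_tot) + model$q_static_i)
  note("static charges Q_i = %.8g, Q_e = %.8g mM-equivalents pin Vm = %g mV with equal-and-opposite membrane charge", model$q_static_i, model$q_static_e, model$vm_rest)
  model$state0 <- list(c_i_tot = c_i_tot, c_e_tot = c_e_tot, vm = model$vm_rest)
  model$manifest <- man
  class(model) <- c("ionbz_model", "list")
  model
}

free_i_to_tot <- function(free, model) {
  tot <- free
  tot[iCA] <- ca_total_from_free(free[iCA], model$ca$buffer, model$ca,
                                 model$geometry)
  tot[iH] <- total_from_free(free[iH], model$buffers$h_i)
  tot
}

free_e_to_tot <- function(free, model) {
  tot <- free
  tot[iCA] <- total_from_free(free[iCA], model$buffers$ca_e)
  tot[iH] <- total_from_free(free[iH], model$buffers$h_e)
  tot
}

# Pathway densities from the zero-net-flux chain at the reference state.
calibrate_densities <- function(model, anchors, note = function(...) NULL) {
  sp <- model$species
  free_i <- sp$c_i0; free_e <- sp$c_e0
  vm <- model$vm_rest
  cst <- model$constants
  kin <- model$kinetics
  e_na <- nernst_potential(free_i[iNA], free_e[iNA], 1, cst)
  e_k <- nernst_potential(free_i[iK], free_e[iK], 1, cst)
  e_cl <- nernst_potential(free_i[iCL], free_e[iCL], -1, cst)
  e_ca <- nernst_potential(free_i[iCA], free_e[iCA], 2, cst)

  x <- list()
  fail <- function(nm) stop("calibrate_densities: solved density for '", nm,
                            "' is negative")
  # (1) Na-entry pathways from anchors
  x$nab <- anchors$j_nab / (e_na - vm); if (x$nab < 0) fail("Na background")
  k_nhe <- nhe_kinetic(free_i[iNA], free_e[iNA], free_i[iH], free_e[iH],
                       kin$nhe)
  x$nhe <- anchors$j_nhe / k_nhe; if (x$nhe < 0) fail("NHE")
  # (3) NBC at the measured NBC:NHE flux ratio
  j_nbc <- anchors$nbc_nhe_ratio * anchors$j_nhe
  q_nbc <- free_e[iNA] * free_e[iHCO3] - free_i[iNA] * free_i[iHCO3]
  x$nbc <- j_nbc / q_nbc; if (x$nbc < 0) fail("NBC")
  r_ncx <- -anchors$j_ncx_na / 3
  k_ncx <- ncx_cycle(free_i[iNA], free_e[iNA], free_i[iCA], free_e[iCA],
                     vm, 1, kin$ncx, cst)
  x$ncx <- r_ncx / k_ncx; if (x$ncx < 0) fail("NCX")
  # (2) NaK balances total Na influx
  j_na_in <- anchors$j_ncx_na + anchors$j_nhe + anchors$j_nab + j_nbc
  u <- j_na_in / 3
  k_nak <- nak_cycle(free_i[iNA], free_e[iNA], free_e[iK], vm, 1, kin$nak, cst)
  x$nak <- u / k_nak; if (x$nak < 0) fail("NaK")
  # (5) CHE balances the NHE proton extrusion
  q_che <- free_e[iCL] * free_e[iH] - free_i[iCL] * free_i[iH]
  x$che <- anchors$j_nhe / q_che; if (x$che < 0) fail("CHE")
  # (6) AE balances the NBC bicarbonate influx
  q_ae <- free_e[iCL] * free_i[iHCO3] - free_i[iCL] * free_e[iHCO3]
  x$ae <- j_nbc / q_ae; if (x$ae < 0) fail("AE")
  # (7) Cl- background balances the CHE + AE chloride influx
  j_clb <- -(anchors$j_nhe + j_nbc)
  x$clb <- j_clb / (vm - e_cl); if (x$clb < 0) fail("Cl background")
  # (8) K+ background balances the NaK potassium influx
  x$kb <- 2 * u / (vm - e_k); if (x$kb < 0) fail("K background")
  # (9) Ca2+ background balances the NCX extrusion
  x$cab <- (anchors$j_ncx_na / 3) / (e_ca - vm); if (x$cab < 0) fail("Ca background")
  x$mct1 <- anchors$x_mct1; if (x$mct1 < 0) fail("MCT1")
  model$densities <- x
  model$anchors <- anchors
  for (nm in names(x))
    note("density X_%s = %.8g (zero-net-flux chain)", nm, x[[nm]])
  model
}

#' @export
print.ionbz_model <- function(x, ...) {
  cat("ionbz two-domain electrodiffusion model\n")
  cat(sprintf("  T = %g K, Vm_rest = %g mV, %d species\n",
              x$constants$temperature, x$vm_rest, nrow(x$species)))
  cat(sprintf("  D(Na/K/Cl): intra %.4g, extra %.4g mm^2/ms\n",
              x$species$d_i[1], x$species$d_e[1]))
  cat(sprintf("  %d calibrated densities; manifest has %d entries\n",
              length(x$densities), length(x$manifest)))
  invisible(x)
}

#' Resting-state zero-net-flux residual
#'
#' Evaluates the net membrane flux at the calibrated resting state; the
#' calibration post-condition is that every component vanishes.
#'
#' @param model calibrated model.
#' @return named vector of per-species fluxes (mM mm/ms).
#' @export
resting_flux_residual <- function(model) {
  sp <- model$species
  out <- net_membrane_flux(matrix(sp$c_i0, 8), matrix(sp$c_e0, 8),
                           model$vm_rest, model)
  stats::setNames(drop(out$J), SPECIES)
}
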