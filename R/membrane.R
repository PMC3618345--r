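# Passive (diastolic) cell-membrane model.
#
# Sign convention used for every pathway: positive flux moves the species INTO
# the intracellular domain. Fluxes are in mM mm/ms referenced to membrane
# area; chi/f_s converts to volumetric concentration rates. Each pathway is a
# reduced, thermodynamically consistent kinetic form: zero at its reversal /
# equilibrium, exact stoichiometry, saturating where the carrier saturates.
# Densities (the X scalars) are set by the zero-net-flux calibration, so the
# resting state is an exact fixed point regardless of the kinetic details.

SPECIES <- c("Na", "K", "Cl", "Ca", "H", "HCO3", "CO2", "Lac")
Z_SPECIES <- c(Na = 1, K = 1, Cl = -1, Ca = 2, H = 1, HCO3 = -1, CO2 = 0, Lac = -1)
iNA <- 1L; iK <- 2L; iCL <- 3L; iCA <- 4L; iH <- 5L; iHCO3 <- 6L; iCO2 <- 7L; iLAC <- 8L

new_flux_matrix <- function(n) {
  matrix(0, nrow = 8L, ncol = n, dimnames = list(SPECIES, NULL))
}

#' Lumped background channel flux
#'
#' Linear electrochemical driving force: the flux is proportional to the
#' channel density and to (Vm - E_ion), directed so that a cation above its
#' reversal potential leaves the cell. Positive return value = influx.
#'
#' @param vm membrane potential (mV).
#' @param c_in,c_out free concentrations (mM).
#' @param z valence (non-zero).
#' @param x density scalar (>= 0).
#' @param constants [phys_constants()].
#' @return flux, mM mm/ms, positive into the cell.
#' @export
j_background <- function(vm, c_in, c_out, z, x, constants = phys_constants()) {
  e_rev <- nernst_potential(c_in, c_out, z, constants)
  -sign(z) * x * (vm - e_rev)
}

# NaK pump cycle rate (> 0 = forward: 3 Na out, 2 K in).
nak_cycle <- function(na_i, na_e, k_e, vm, x, kin, constants, inhibition = 0) {
  fna <- na_i^kin$n_nai / (na_i^kin$n_nai + kin$km_nai^kin$n_nai)
  fk <- (k_e / (k_e + kin$km_ke))^2
  sig <- (exp(na_e / 67.3) - 1) / 7
  vfrt <- vm / constants$rtf
  fv <- 1 / (1 + 0.1245 * exp(-0.1 * vfrt) + 0.0365 * sig * exp(-vfrt))
  x * fna * fk * fv * (1 - inhibition)
}

#' Na+/K+-ATPase fluxes
#'
#' Voltage- and substrate-dependent pump with exact 3:2 Na:K stoichiometry
#' (one net positive charge extruded per cycle). `inhibition` scales the
#' maximal turnover, the ischemic NaK component.
#'
#' @param na_i,na_e,k_e free concentrations (mM); `vm` in mV.
#' @param x density scalar; `kin` kinetic constants (see [default_config()]).
#' @param inhibition fraction of flux removed, in [0, 1].
#' @param constants [phys_constants()].
#' @return list with `na` and `k` fluxes (mM mm/ms, positive into the cell)
#'   and the cycle rate `cycle`.
#' @export
j_nak <- function(na_i, na_e, k_e, vm, x, kin, inhibition = 0,
                  constants = phys_constants()) {
  if (any(inhibition < 0) || any(inhibition > 1))
    stop("j_nak: inhibition must lie in [0, 1]")
  if (is.null(kin$km_nai) || is.null(kin$km_ke))
    stop("j_nak: missing kinetic constants")
  u <- nak_cycle(na_i, na_e, k_e, vm, x, kin, constants, inhibition)
  list(na = -3 * u, k = 2 * u, cycle = u)
}

# NCX cycle rate r (> 0 = reverse mode: 3 Na out, 1 Ca in).
ncx_cycle <- function(na_i, na_e, ca_i, ca_e, vm, x, kin, constants) {
  vfrt <- vm / constants$rtf
  num <- exp(kin$eta * vfrt) * na_i^3 * ca_e -
    exp((kin$eta - 1) * vfrt) * na_e^3 * ca_i
  den <- (kin$km_na^3 + na_e^3) * (kin$km_ca + ca_e) *
    (1 + kin$ksat * exp((kin$eta - 1) * vfrt))
  x * num / den
}

#' Na+/Ca2+ exchanger fluxes
#'
#' Electrogenic 3:1 exchange, zero exactly at its thermodynamic reversal
#' (3 E_Na - 2 E_Ca = Vm), with voltage partitioning and saturation constants
#' of the standard ventricular formulation.
#'
#' @inheritParams j_nak
#' @param ca_i,ca_e free Ca2+ (mM).
#' @return list with `na` and `ca` fluxes (positive into the cell) and the
#'   cycle rate `cycle` (> 0 = Ca2+ entry mode).
#' @export
j_ncx <- function(na_i, na_e, ca_i, ca_e, vm, x, kin,
                  constants = phys_constants()) {
  r <- ncx_cycle(na_i, na_e, ca_i, ca_e, vm, x, kin, constants)
  list(na = -3 * r, ca = r, cycle = r)
}

#' Electroneutral acid-base transporter fluxes
#'
#' NHE (Na+ in / H+ out) with a steep intracellular-proton activation and
#' kinetic inhibition by extracellular protons; CHE
#' (Cl- in / OH- out, a net acid load with Cl- influx, the OH- leg carried as
#' an equal H+ influx); AE (Cl- in / HCO3- out); NBC (Na+ + HCO3- in,
#' modelled electroneutral). Each flux is zero exactly at the transporter's
#' equilibrium concentration ratio and each pathway's z-weighted flux is zero
#' by construction.
#'
#' @param free_i,free_e 8 x n free-concentration matrices (rows as in
#'   [ion_species()]).
#' @param x named list of density scalars `nhe`, `che`, `ae`, `nbc`.
#' @param kin kinetic constants (`nhe$pk`, `nhe$n`).
#' @return list of per-pathway lists of species fluxes (mM mm/ms).
#' @export
# NHE kinetic factor: intracellular-H Hill activation, extracellular-H
# binding inhibition, and the 1:1 exchange driving term (zero at equilibrium)
nhe_kinetic <- function(na_i, na_e, h_i, h_e, kin) {
  kh <- ph_to_h(kin$pk)
  sat <- h_i^kin$n / (h_i^kin$n + kh^kin$n)
  inh <- ph_to_h(kin$pk_e) / (ph_to_h(kin$pk_e) + h_e)
  sat * inh * (1 - (na_i * h_e) / (na_e * h_i))
}

j_acid_transporters <- function(free_i, free_e, x, kin) {
  na_i <- free_i[iNA, ]; na_e <- free_e[iNA, ]
  cl_i <- free_i[iCL, ]; cl_e <- free_e[iCL, ]
  h_i <- free_i[iH, ]; h_e <- free_e[iH, ]
  b_i <- free_i[iHCO3, ]; b_e <- free_e[iHCO3, ]
  j_nhe <- x$nhe * nhe_kinetic(na_i, na_e, h_i, h_e, kin$nhe)
  j_che <- x$che * (cl_e * h_e - cl_i * h_i)
  j_ae <- x$ae * (cl_e * b_i - cl_i * b_e)
  j_nbc <- x$nbc * (na_e * b_e - na_i * b_i)
  list(
    nhe = list(na = j_nhe, h = -j_nhe),
    che = list(cl = j_che, h = j_che),
    ae = list(cl = j_ae, hco3 = -j_ae),
    nbc = list(na = j_nbc, hco3 = j_nbc)
  )
}

#' Lactate:H+ cotransporter (MCT1) flux
#'
#' Ordered 1:1 lactate-/H+ cotransport, electroneutral, saturating in the
#' bound cosubstrate pair on either face; zero when the transmembrane
#' lactate x H products match.
#'
#' @param lac_i,lac_e,h_i,h_e free concentrations (mM).
#' @param x maximum flux scalar (mM mm/ms).
#' @param kin constants `k_lac`, `k_h` (mM).
#' @return common lactate and H+ flux (positive into the cell).
#' @export
j_mct1 <- function(lac_i, lac_e, h_i, h_e, x, kin) {
  b_i <- (lac_i / kin$k_lac) * (h_i / kin$k_h)
  b_e <- (lac_e / kin$k_lac) * (h_e / kin$k_h)
  x * (b_e / (1 + b_e) - b_i / (1 + b_i))
}

#' Fickian membrane CO2 flux
#' @param co2_i,co2_e CO2 concentrations (mM).
#' @param p membrane permeability (mm/ms).
#' @return flux, positive into the cell (mM mm/ms).
#' @export
j_co2 <- function(co2_i, co2_e, p) p * (co2_e - co2_i)

#' pH-dependent gap-junction scaling of intracellular diffusivities
#'
#' Biphasic proton dependence: the product of an activating and a
#' deactivating Hill term in free H+, normalized to 1 at the resting
#' intracellular pH so that the calibrated diffusivities are the resting-state
#' effective values.
#'
#' @param ph_i intracellular pH, in (4, 10).
#' @param gj constants `pk_a`, `n_a`, `pk_b`, `n_b`, `ph_ref` (see
#'   [default_config()]).
#' @return dimensionless multiplicative factor (1 at `ph_ref`).
#' @export
gap_junction_scale <- function(ph_i, gj) {
  if (any(ph_i <= 4) || any(ph_i >= 10))
    stop("gap_junction_scale: pH out of range (4, 10)")
  raw <- function(ph) {
    h <- ph_to_h(ph)
    ka <- ph_to_h(gj$pk_a); kb <- ph_to_h(gj$pk_b)
    act <- h^gj$n_a / (h^gj$n_a + ka^gj$n_a)
    deact <- kb^gj$n_b / (h^gj$n_b + kb^gj$n_b)
    act * deact
  }
  raw(ph_i) / raw(gj$ph_ref)
}

#' Positive root of the cytosolic calcium cubic
#'
#' Closed-form (trigonometric) solution of x^3 + a2 x^2 + a1 x + a0 = 0 used
#' for the equilibrium free-calcium inversion; a0 < 0 guarantees at least one
#' positive real root, and the largest real root is the physical one for
#' these coefficients. Falls back to the real Cardano branch when only one
#' real root exists.
#'
#' @param a2,a1,a0 cubic coefficients (leading coefficient 1); vectorised.
#' @return the positive real root.
#' @export
cubic_pos_root <- function(a2, a1, a0) {
  q <- (a2^2 - 3 * a1) / 9
  r <- (2 * a2^3 - 9 * a2 * a1 + 27 * a0) / 54
  out <- numeric(length(r))
  trig <- r^2 < q^3
  if (any(trig)) {
    th <- acos(pmin(1, pmax(-1, r[trig] / sqrt(q[trig]^3))))
    # all three real roots; the physical root is the largest
    k <- rbind(th / 3, (th + 2 * pi) / 3, (th - 2 * pi) / 3)
    roots <- -2 * rep(sqrt(q[trig]), each = 3) * cos(k) -
      rep(a2[trig] / 3, each = 3)
    dim(roots) <- c(3L, sum(trig))
    out[trig] <- apply(roots, 2, max)
  }
  if (any(!trig)) {
    rr <- r[!trig]; qq <- q[!trig]
    a <- -sign(rr) * (abs(rr) + sqrt(pmax(rr^2 - qq^3, 0)))^(1 / 3)
    b <- ifelse(a == 0, 0, qq / a)
    out[!trig] <- (a + b) - a2[!trig] / 3
  }
  # two Newton polishing passes recover the digits the trigonometric form
  # loses to cancellation when the root is far below the coefficient scale
  for (pass in 1:2) {
    p <- ((out + a2) * out + a1) * out + a0
    dp <- (3 * out + 2 * a2) * out + a1
    step <- ifelse(dp != 0, p / dp, 0)
    out <- out - step
  }
  out
}

#' Equilibrium intracellular calcium subsystem
#'
#' Splits total intracellular calcium (referenced to cytosol volume,
#' SR content included via the SR/cytosol volume ratio) between free
#' cytosolic Ca2+, buffer-bound Ca2+ and the SR, under instantaneous
#' SERCA-uptake / leak balance with SERCA Hill coefficient 1. The inversion
#' reduces to a cubic whose constant coefficient is always negative; the
#' positive real root is evaluated in closed form.
#'
#' @param total_ca total intracellular calcium (mM, cytosol-referenced);
#'   vectorised, must be non-negative.
#' @param buffer cytosolic [buffer_spec()] with n = 1.
#' @param ca calcium parameters: `v_max` (mM/ms), `p_leak` (1/ms),
#'   `k_serca` (mM).
#' @param geometry [tissue_geometry()].
#' @return list with `free`, `sr` and `bound` concentrations (mM).
#' @export
ca_equilibrium <- function(total_ca, buffer, ca, geometry) {
  if (any(total_ca < 0)) stop("ca_equilibrium: total calcium must be >= 0")
  if (buffer$n != 1) stop("ca_equilibrium: buffer Hill coefficient must be 1")
  r <- geometry$f_sr / geometry$f_cyt
  q <- if (ca$p_leak > 0) ca$v_max / ca$p_leak else 0
  s <- 1 + r
  kb <- buffer$K; ks <- ca$k_serca; B <- buffer$B
  a2 <- (s * (kb + ks) + B + r * q - total_ca) / s
  a1 <- (s * kb * ks + B * ks + r * q * kb - total_ca * (kb + ks)) / s
  a0 <- -total_ca * kb * ks / s
  free <- cubic_pos_root(a2, a1, a0)
  free[total_ca == 0] <- 0
  sr <- free + q * free / (free + ks)
  bound <- buffer_bound(free, buffer)
  list(free = free, sr = sr, bound = bound)
}

# total intracellular Ca (cytosol-referenced) from free
ca_total_from_free <- function(free, buffer, ca, geometry) {
  r <- geometry$f_sr / geometry$f_cyt
  q <- if (ca$p_leak > 0) ca$v_max / ca$p_leak else 0
  sr <- free + q * free / (free + ca$k_serca)
  free + buffer_bound(free, buffer) + r * sr
}

#' Algebraic membrane potential from intracellular charge
#'
#' Vm scales linearly with the z-weighted total intracellular concentrations
#' plus a static charge offset: Vm = (F f_cyt / (chi Cm)) (sum_k z_k c_k + Q).
#'
#' @param c_i_tot 8 x n matrix (or 8-vector) of total intracellular
#'   concentrations (mM, cytosol-referenced).
#' @param q_static static intracellular charge offset (mM equivalents).
#' @param model a calibrated model (for geometry, Cm and constants).
#' @return membrane potential(s), mV.
#' @export
vm_from_charge <- function(c_i_tot, q_static, model) {
  z <- Z_SPECIES
  zsum <- if (is.matrix(c_i_tot)) colSums(c_i_tot * z) else sum(c_i_tot * z)
  model$vm_slope * (zsum + q_static)
}

# mV per mM of unbalanced monovalent intracellular charge:
# 1000 [mV/V] * F [C/mol] * (f_cyt/chi) [mm] * 1e-9 [mol/mm^3 per mM] / Cm [F/mm^2]
vm_slope_mV_per_mM <- function(constants, geometry, cm) {
  1000 * constants$F * (geometry$f_cyt / geometry$chi) * 1e-9 / cm
}

#' Net transmembrane flux for every species
#'
#' Sums all pathway contributions per species at the given state, together
#' with the z-weighted total (the membrane current density in charge-flux
#' units). Positive = into the intracellular domain.
#'
#' @param free_i,free_e 8 x n free-concentration matrices (mM).
#' @param vm membrane potential vector (mV).
#' @param model calibrated model from [calibrate_model()].
#' @param nak_scale,kb_scale per-node multiplicative scales applied to the
#'   NaK pump and K background densities (the ischemic components).
#' @param vm_override optional list `(pathway =, vm =)` exposing a single
#'   pathway ("Kb" or "NaK") to a surrogate potential field.
#' @param by_pathway if TRUE also return per-pathway flux lists.
#' @return list with `J` (8 x n matrix, mM mm/ms), `current` (z-weighted sum)
#'   and optionally `pathways`.
#' @export
net_membrane_flux <- function(free_i, free_e, vm, model, nak_scale = 1,
                              kb_scale = 1, vm_override = NULL,
                              by_pathway = FALSE) {
  if (!is.matrix(free_i)) free_i <- matrix(free_i, nrow = 8L)
  if (!is.matrix(free_e)) free_e <- matrix(free_e, nrow = 8L)
  # floor protects kinetic evaluation on infeasible Newton trial states only
  free_i <- pmax(free_i, 1e-12)
  free_e <- pmax(free_e, 1e-12)
  n <- ncol(free_i)
  x <- model$densities; kin <- model$kinetics; cst <- model$constants
  vm_for <- function(pathway) {
    if (!is.null(vm_override) && identical(vm_override$pathway, pathway))
      vm_override$vm else vm
  }
  J <- new_flux_matrix(n)
  path <- list()

  pump <- j_nak(free_i[iNA, ], free_e[iNA, ], free_e[iK, ], vm_for("NaK"),
                x$nak * nak_scale, kin$nak, inhibition = 0, constants = cst)
  J[iNA, ] <- J[iNA, ] + pump$na; J[iK, ] <- J[iK, ] + pump$k
  path$nak <- pump

  ncx <- j_ncx(free_i[iNA, ], free_e[iNA, ], free_i[iCA, ], free_e[iCA, ],
               vm, x$ncx, kin$ncx, constants = cst)
  J[iNA, ] <- J[iNA, ] + ncx$na; J[iCA, ] <- J[iCA, ] + ncx$ca
  path$ncx <- ncx

  acid <- j_acid_transporters(free_i, free_e, x, kin)
  J[iNA, ] <- J[iNA, ] + acid$nhe$na + acid$nbc$na
  J[iH, ] <- J[iH, ] + acid$nhe$h + acid$che$h
  J[iCL, ] <- J[iCL, ] + acid$che$cl + acid$ae$cl
  J[iHCO3, ] <- J[iHCO3, ] + acid$ae$hco3 + acid$nbc$hco3
  path <- c(path, acid)

  mct <- j_mct1(free_i[iLAC, ], free_e[iLAC, ], free_i[iH, ], free_e[iH, ],
                x$mct1, kin$mct1)
  J[iLAC, ] <- J[iLAC, ] + mct; J[iH, ] <- J[iH, ] + mct
  path$mct1 <- list(lac = mct, h = mct)

  jnab <- j_background(vm, free_i[iNA, ], free_e[iNA, ], 1, x$nab, cst)
  jkb <- j_background(vm_for("Kb"), free_i[iK, ], free_e[iK, ], 1,
                      x$kb * kb_scale, cst)
  # Ca2+-sensitive Cl- background: linear free-Ca dependence, 1 at rest
  ca_fac <- free_i[iCA, ] / model$ca$resting
  jclb <- j_background(vm, free_i[iCL, ], free_e[iCL, ], -1, x$clb * ca_fac, cst)
  jcab <- j_background(vm, free_i[iCA, ], free_e[iCA, ], 2, x$cab, cst)
  J[iNA, ] <- J[iNA, ] + jnab; J[iK, ] <- J[iK, ] + jkb
  J[iCL, ] <- J[iCL, ] + jclb; J[iCA, ] <- J[iCA, ] + jcab
  path$nab <- list(na = jnab); path$kb <- list(k = jkb)
  path$clb <- list(cl = jclb); path$cab <- list(ca = jcab)

  jc <- j_co2(free_i[iCO2, ], free_e[iCO2, ], model$co2$p_m)
  J[iCO2, ] <- J[iCO2, ] + jc
  path$co2 <- list(co2 = jc)

  out <- list(J = J, current = colSums(J * Z_SPECIES))
  if (by_pathway) out$pathways <- path
  out
}
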