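#' Physical constants
#'
#' Fixed unit system used throughout the package: concentrations in mM,
#' potentials in mV, time in ms, length in mm. Conductivities entering or
#' leaving the package are in S/m and converted internally.
#'
#' @param temperature Absolute temperature in K. Defaults to body temperature
#'   (310 K), matching the 37 C data the membrane model is parameterized from.
#' @return A list with Faraday's constant `F` (C/mol), the gas constant `R`
#'   (J/mol/K), `temperature` (K) and the derived thermal voltage `rtf` =
#'   RT/F in mV (about 26.7 mV at 310 K).
#' @export
phys_constants <- function(temperature = 310) {
  stopifnot(is.numeric(temperature), temperature > 0)
  faraday <- 96485.33212     # C/mol
  gas <- 8.314462618         # J/mol/K
  list(
    F = faraday,
    R = gas,
    temperature = temperature,
    rtf = 1000 * gas * temperature / faraday  # mV
  )
}

#' Tissue geometry
#'
#' Volume fractions of the two-domain continuum and the membrane surface area
#' per unit myocardium volume. The intracellular volume fraction subdivides
#' into cytosol, sarcoplasmic reticulum and mitochondria; ionic balances in
#' the intracellular domain are referenced to the cytosolic fraction, so that
#' mitochondrial volume is inaccessible to the modelled ions and the SR enters
#' only through the equilibrium calcium subsystem.
#'
#' @param f_i,f_e intra/extracellular volume fractions (dimensionless).
#' @param f_cyt,f_sr,f_mito cytosolic, SR and mitochondrial fractions of
#'   myocardium volume (subdivision of `f_i`).
#' @param chi membrane surface area per unit myocardium volume (1/mm).
#' @return A validated list of the six geometric parameters.
#' @export
tissue_geometry <- function(f_i = 0.8, f_e = 0.2, f_cyt = 0.536,
                            f_sr = 0.024, f_mito = 0.24, chi = 264) {
  g <- list(f_i = f_i, f_e = f_e, f_cyt = f_cyt, f_sr = f_sr,
            f_mito = f_mito, chi = chi)
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  num <- vapply(g, function(x) is.numeric(x) && length(x) == 1L, logical(1))
  if (!all(num)) stop("geometry entries must be numeric scalars")
  frac <- c("f_i", "f_e", "f_cyt", "f_sr", "f_mito")
  for (nm in frac) {
    if (g[[nm]] <= 0 || g[[nm]] >= 1)
      stop("geometry: ", nm, " must lie in (0, 1)")
  }
  if (g$chi <= 0) stop("geometry: chi must be positive")
  if (g$f_i + g$f_e > 1 + 1e-12)
    stop("geometry: f_i + f_e must not exceed 1")
  if (g$f_cyt + g$f_sr + g$f_mito > g$f_i + 1e-12)
    stop("geometry: f_cyt + f_sr + f_mito must not exceed f_i")
  invisible(g)
}

#' Species registry
#'
#' The eight transported species: charge, buffering flag, per-domain
#' effective diffusivity and per-domain reference free concentration.
#' CO2 is carried as an uncharged species so the same transport and
#' conservation machinery applies to it; lactate is the matched anion of the
#' metabolic-acidosis proton source. Na+/K+/Cl- diffusivities are derived
#' from tissue conductivity by [derive_diffusivities()]; the values here are
#' the derived defaults.
#'
#' @return A data.frame with columns `name`, `z`, `buffered`, `d_i`, `d_e`
#'   (mm^2/ms) and `c_i0`, `c_e0` (reference free concentrations, mM).
#' @export
ion_species <- function() {
  data.frame(
    name = c("Na", "K", "Cl", "Ca", "H", "HCO3", "CO2", "Lac"),
    z = c(1L, 1L, -1L, 2L, 1L, -1L, 0L, -1L),
    buffered = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    d_i = c(7.651e-7, 7.651e-7, 7.651e-7, 1.5e-7, 1.52e-7, 7.7e-7, 11.3e-7, 7.7e-7),
    d_e = c(12.888e-7, 12.888e-7, 12.888e-7, 1.5e-7, 1.52e-7, 7.7e-7, 11.3e-7, 7.7e-7),
    c_i0 = c(4, 135, 18, 1e-4, 10^(-7.1) * 1e3, 11.70, 1.17, 0.5012),
    c_e0 = c(140, 4, 110, 1.2, 10^(-7.4) * 1e3, 23.35, 1.17, 1.0),
    stringsAsFactors = FALSE
  )
}

#' Nernst equilibrium potential
#'
#' @param c_in,c_out free concentrations on the intracellular and
#'   extracellular side (mM), strictly positive.
#' @param z integer valence, non-zero.
#' @param constants as returned by [phys_constants()].
#' @return Reversal potential in mV: (RT/zF) log(c_out/c_in).
#' @export
nernst_potential <- function(c_in, c_out, z, constants = phys_constants()) {
  if (any(c_in <= 0) || any(c_out <= 0))
    stop("nernst_potential: concentrations must be strictly positive")
  if (any(z == 0))
    stop("nernst_potential: z must be non-zero")
  constants$rtf / z * log(c_out / c_in)
}

#' Rapid-buffer description
#'
#' A single immobile buffer population in instantaneous equilibrium:
#' bound = B c^n / (c^n + K^n).
#'
#' @param B buffer site concentration (mM), non-negative.
#' @param K dissociation constant (mM), positive.
#' @param n Hill coefficient, >= 1.
#' @return An object of class `buffer_spec`.
#' @export
buffer_spec <- function(B, K, n = 1) {
  stopifnot(B >= 0, K > 0, n >= 1)
  structure(list(B = B, K = K, n = n), class = "buffer_spec")
}

#' @export
print.buffer_spec <- function(x, ...) {
  cat(sprintf("rapid buffer: B = %g mM, K = %g mM, n = %g\n", x$B, x$K, x$n))
  invisible(x)
}

#' Buffer-bound concentration at a given free concentration
#' @param c_free free concentration (mM).
#' @param buffer a [buffer_spec()].
#' @return bound concentration (mM).
#' @export
buffer_bound <- function(c_free, buffer) {
  if (buffer$B == 0) return(0 * c_free)
  cn <- c_free^buffer$n
  buffer$B * cn / (cn + buffer$K^buffer$n)
}

#' Total concentration from free (forward buffering map)
#' @inheritParams buffer_bound
#' @export
total_from_free <- function(c_free, buffer) c_free + buffer_bound(c_free, buffer)

#' Free concentration from total (inverse buffering map)
#'
#' Inverts c_total = c + B c^n/(c^n + K^n) for the unique non-negative root.
#' The n = 1 case uses the closed-form positive root of the quadratic; general
#' n uses safeguarded bracketed root finding on [0, c_total] with relative
#' tolerance 1e-12. Negative totals (transient Newton iterates) are passed
#' through linearly so the map stays continuous.
#'
#' @param c_total total concentration (mM); vectorised.
#' @param buffer a [buffer_spec()].
#' @return free concentration (mM).
#' @export
free_from_total <- function(c_total, buffer) {
  if (buffer$B == 0) return(c_total)
  if (buffer$n == 1) return(free_quad(c_total, buffer$B, buffer$K))
  vapply(c_total, function(t1) {
    if (t1 <= 0) return(t1)
    f <- function(c) c + buffer_bound(c, buffer) - t1
    stats::uniroot(f, c(0, t1), tol = 1e-12 * max(t1, 1e-12))$root
  }, numeric(1))
}

# closed-form positive root of c^2 + (B + K - t) c - t K = 0 (n = 1),
# written to avoid cancellation for t << B
free_quad <- function(t1, B, K) {
  b <- B + K - t1
  disc <- sqrt(b * b + 4 * t1 * K)
  out <- ifelse(b >= 0, 2 * t1 * K / (b + disc), (disc - b) / 2)
  ifelse(t1 <= 0, t1, out)
}

#' CO2 hydration source rate
#'
#' Net rate of the reaction CO2 + H2O <-> H+ + HCO3-: positive values produce
#' H+ and HCO3- and consume CO2.
#'
#' @param co2,h,hco3 free concentrations (mM).
#' @param kf forward (hydration) rate constant, 1/ms.
#' @param kb reverse (dehydration) rate constant, 1/(mM ms).
#' @return net production rate of H+ and HCO3- (mM/ms).
#' @export
hydrolysis_rate <- function(co2, h, hco3, kf, kb) {
  kf * co2 - kb * h * hco3
}

#' pH to free proton concentration (mM)
#' @param ph pH units.
#' @export
ph_to_h <- function(ph) 10^(-ph) * 1e3

#' Free proton concentration (mM) to pH
#' @param h free H+ in mM.
#' @export
h_to_ph <- function(h) -log10(h / 1e3)
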