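# Configuration: defaults, validation, (de)serialization.
#
# Every number a simulation depends on lives in this one nested list so the
# calibration chain can re-derive all densities for any perturbed target state.

#' Default configuration
#'
#' Returns the full nested parameter list: reference geometry, resting free
#' concentrations, buffer parameters, CO2/Henry constants, conductivities used
#' to derive Na/K/Cl diffusivities, fixed literature diffusivities, membrane
#' anchors and kinetic constants, SR calcium targets, ischemia intensities and
#' solver/mesh settings. All units are mM, mV, ms, mm unless stated.
#'
#' @return A nested list of class `ionbz_config`.
#' @export
default_config <- function() {
  cfg <- list(
    constants = list(temperature = 310),
    geometry = list(f_i = 0.8, f_e = 0.2, f_cyt = 0.536, f_sr = 0.024,
                    f_mito = 0.24, chi = 264),
    concentrations = list(
      na_i = 4, na_e = 140,
      k_i = 135, k_e = 4,
      cl_i = 18, cl_e = 110,
      ca_i = 1e-4, ca_e = 1.2,
      ph_i = 7.1, ph_e = 7.4,
      lac_e = 1.0
    ),
    buffers = list(
      # intracellular proton buffer: single-site fit across the measured
      # fixed + mobile populations
      h_i = list(B = 65, pk = 6.5, n = 1),
      # extracellular proton buffer concentration is derived from the bound-H
      # anchor below (B = NA means "derive")
      h_e = list(B = NA_real_, pk = 6.5, n = 1),
      bound_h_e = 39,
      ca_i = list(B = 0.209, K = 6e-4, n = 1),
      ca_e = list(B = 2.3, K = 1.1, n = 1)
    ),
    co2 = list(
      alpha = 0.0308,     # Henry solubility, mM/mmHg at 37 C
      fraction = 0.05,    # fraction of gas that is CO2 at baseline
      pressure = 760,     # mmHg
      kf = 3.02e-5,       # hydration rate, 1/ms (0.0302 1/s)
      kb = 3.02e-5 / (10^(-6.1) * 1e3),  # dehydration, 1/(mM ms); pK' = 6.1
      p_m = 0.058         # membrane CO2 permeability, mm/ms
    ),
    conductivity = list(sigma_i = 0.25, sigma_e = 0.25),  # S/m per domain
    diffusivities = list(  # fixed literature values, mm^2/ms
      ca = 1.5e-7, h = 1.52e-7, hco3 = 7.7e-7, co2 = 11.3e-7, lac = 7.7e-7
    ),
    membrane = list(
      cm = 1e-8,          # F/mm^2 (1 uF/cm^2)
      vm_rest = -80,      # mV
      anchors = list(
        # resting transmembrane Na+ influx carried by each pathway,
        # mM mm/ms referenced to membrane area
        j_ncx_na = 2.0e-8,
        j_nhe = 1.2e-8,
        j_nab = 1.13e-8,
        nbc_nhe_ratio = 0.16,
        x_mct1 = 1.6e-7   # MCT1 maximum flux scalar, mM mm/ms
      ),
      kinetics = list(
        nak = list(km_nai = 15, n_nai = 1.5, km_ke = 1.5),
        ncx = list(eta = 0.35, ksat = 0.27, km_na = 87.5, km_ca = 1.38),
        nhe = list(pk = 6.9, n = 2, pk_e = 7.0),
        mct1 = list(k_lac = 0.4, k_h = 1e-4)
      ),
      gap_junction = list(pk_a = 7.9, n_a = 1.5, pk_b = 6.4, n_b = 4,
                          ph_ref = 7.1)
    ),
    calcium = list(
      sr = 0.1,               # resting SR load, mM
      k_serca = 3e-4,         # SERCA binding constant, mM (0.3 uM)
      resting_uptake = 1e-5   # resting SR uptake flux, mM/ms (0.01 uM/ms)
    ),
    ischemia = list(
      # tuned component intensities (see tune_ischemia(); regenerable)
      nak_inhibition = 0.71,
      ikb_activation = 30,    # multiplicative factor on the K background
      co2_source = 2.3e-5,    # mM/ms, intracellular, ischemic core
      h_source = 6.5e-5,      # mM/ms, paired with an equal lactate source
      midpoint = 16,          # mm
      steepness = 60          # Hill coefficient of the severity profile
    ),
    mesh = list(length = 32, dx = 0.25),
    solver = list(dt = 100, newton_atol = 1e-11, max_iter = 12,
                  max_linesearch = 10, dt_min = 1e-3, fd_eps = 1e-7)
  )
  class(cfg) <- c("ionbz_config", "list")
  cfg
}

#' Validate a configuration
#'
#' Checks structure against [default_config()] (unknown keys are rejected,
#' naming the key), numeric types, and physical invariants (volume fractions,
#' positivity, severity bounds).
#'
#' @param cfg a configuration list.
#' @return the validated configuration, invisibly.
#' @export
validate_config <- function(cfg) {
  ref <- unclass(default_config())
  check_keys(cfg, ref, "config")
  validate_geometry(cfg$geometry)
  cc <- cfg$concentrations
  pos <- c("na_i", "na_e", "k_i", "k_e", "cl_i", "cl_e", "ca_i", "ca_e", "lac_e")
  for (nm in pos) {
    if (!is.numeric(cc[[nm]]) || cc[[nm]] <= 0)
      stop("config: concentrations$", nm, " must be a positive number")
  }
  if (cc$ph_i < 4 || cc$ph_i > 10 || cc$ph_e < 4 || cc$ph_e > 10)
    stop("config: pH values must lie in (4, 10)")
  for (nm in c("h_i", "h_e", "ca_i", "ca_e")) {
    b <- cfg$buffers[[nm]]
    if (!is.na(b$B %||% NA_real_) && b$B < 0)
      stop("config: buffers$", nm, "$B must be non-negative")
  }
  if (cfg$co2$kf < 0 || cfg$co2$kb < 0)
    stop("config: hydration rate constants must be non-negative")
  if (cfg$membrane$cm <= 0) stop("config: membrane$cm must be positive")
  isc <- cfg$ischemia
  if (isc$nak_inhibition < 0 || isc$nak_inhibition > 1)
    stop("config: ischemia$nak_inhibition must lie in [0, 1]")
  if (isc$ikb_activation < 1)
    stop("config: ischemia$ikb_activation must be >= 1")
  if (isc$co2_source < 0 || isc$h_source < 0)
    stop("config: ischemic source rates must be non-negative")
  if (cfg$mesh$dx <= 0 || cfg$mesh$length <= 0)
    stop("config: mesh length and dx must be positive")
  if (cfg$solver$dt <= 0 || cfg$solver$newton_atol <= 0)
    stop("config: solver dt and tolerances must be positive")
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(x, ref, path) {
  if (!is.list(ref)) return(invisible(TRUE))
  unknown <- setdiff(names(x), names(ref))
  if (length(unknown))
    stop("config: unknown key '", path, "$", unknown[1], "'")
  for (nm in names(x)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      check_keys(x[[nm]], ref[[nm]], paste0(path, "$", nm))
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a configuration from a YAML file
#'
#' Keys present in the file override [default_config()]; everything else keeps
#' its default, so an empty file yields the full reference parameterization.
#' Unknown keys and invariant violations are rejected with the offending key
#' named.
#'
#' @param path path to a YAML file (may be empty).
#' @return a validated `ionbz_config`.
#' @export
load_config <- function(path) {
  over <- yaml::read_yaml(path)
  if (is.null(over)) over <- list()
  cfg <- default_config()
  check_keys(over, unclass(cfg), "config")
  cfg2 <- merge_config(unclass(cfg), over)
  class(cfg2) <- class(cfg)
  validate_config(cfg2)
  cfg2
}

#' Save a configuration to YAML
#' @param cfg a configuration list.
#' @param path output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 12)
  invisible(path)
}
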