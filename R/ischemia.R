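# 1D strand geometry and the four-component ischemia protocol.

#' One-dimensional strand mesh
#'
#' Cell-centered finite-volume mesh with zero-flux ends. Node coordinates are
#' the cell centers, 0-based spacing from the strand origin.
#'
#' @param length strand length (mm).
#' @param dx node spacing (mm); must divide `length`.
#' @return list with `n`, `dx`, `length` and node coordinates `x`.
#' @export
mesh_1d <- function(length = 32, dx = 0.25) {
  stopifnot(length > 0, dx > 0)
  n <- round(length / dx)
  if (abs(n * dx - length) > 1e-9)
    stop("mesh_1d: dx must divide the strand length")
  structure(list(n = as.integer(n), dx = dx, length = length,
                 x = (seq_len(n) - 0.5) * dx),
            class = "ionbz_mesh")
}

#' @export
print.ionbz_mesh <- function(x, ...) {
  cat(sprintf("1D strand: %g mm, dx = %g mm, %d nodes\n", x$length, x$dx, x$n))
  invisible(x)
}

#' Ischemia configuration
#'
#' The four instantaneous ischemic components and their shared spatial
#' severity profile: NaK inhibition (fraction of pump flux removed), K
#' background activation (multiplicative factor >= 1), an intracellular CO2
#' source (respiratory acidosis; CO2 cannot be vented from the extracellular
#' space) and an intracellular H+ source with a matched lactate (anion)
#' source (metabolic acidosis, electroneutral by construction).
#'
#' @param nak_inhibition fraction in [0, 1].
#' @param ikb_activation factor >= 1 multiplying the K background density.
#' @param co2_source,h_source core source rates (mM/ms, cytosol-referenced).
#' @param midpoint transition midpoint (mm).
#' @param steepness Hill coefficient of the severity profile.
#' @return list of class `ionbz_ischemia`.
#' @export
ischemia_config <- function(nak_inhibition = 0.71, ikb_activation = 30,
                            co2_source = 2.3e-5, h_source = 6.5e-5,
                            midpoint = 16, steepness = 60) {
  stopifnot(nak_inhibition >= 0, nak_inhibition <= 1, ikb_activation >= 1,
            co2_source >= 0, h_source >= 0, midpoint > 0, steepness > 0)
  structure(list(nak_inhibition = nak_inhibition,
                 ikb_activation = ikb_activation,
                 co2_source = co2_source, h_source = h_source,
                 midpoint = midpoint, steepness = steepness),
            class = "ionbz_ischemia")
}

#' No-ischemia control configuration
#' @export
no_ischemia <- function() {
  ischemia_config(nak_inhibition = 0, ikb_activation = 1,
                  co2_source = 0, h_source = 0)
}

#' Spatial severity profile
#'
#' Hill-shaped ramp along the strand: ~1 deep in the ischemic region
#' (x << midpoint), 0.5 exactly at the midpoint, ~0 in viable tissue, with
#' the steepness chosen for a transition of about a millimetre.
#'
#' @param x positions (mm).
#' @param config an [ischemia_config()].
#' @return severity fraction in [0, 1] per position.
#' @export
severity_profile <- function(x, config) {
  stopifnot(all(x >= 0))
  1 / (1 + (x / config$midpoint)^config$steepness)
}

#' Node-local effective ischemic parameters
#'
#' Multiplies each component intensity by the local severity: NaK density
#' scaled by (1 - severity * inhibition), K background by
#' (1 + severity * (activation - 1)), sources scaled linearly. The combined
#' H+ + lactate source carries zero net charge at every node.
#'
#' @param severity severity fractions per node.
#' @param config an [ischemia_config()].
#' @return list of per-node vectors `nak_scale`, `kb_scale`, `co2_source`,
#'   `h_source`.
#' @export
apply_ischemia <- function(severity, config) {
  stopifnot(all(severity >= 0), all(severity <= 1))
  list(
    nak_scale = 1 - severity * config$nak_inhibition,
    kb_scale = 1 + severity * (config$ikb_activation - 1),
    co2_source = severity * config$co2_source,
    h_source = severity * config$h_source
  )
}
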