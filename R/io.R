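# Serialization and synthetic fixtures.

#' Write a trajectory to long-format CSV
#'
#' One row per (time, node, domain, species); deterministic ordering; units
#' carried in the column names. Time is written in seconds, positions in mm,
#' concentrations in mM, potentials in mV.
#'
#' @param traj an `ionbz_trajectory`.
#' @param path output file.
#' @return the written data.frame, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  nt <- length(traj$times)
  n <- traj$mesh$n
  grid <- expand.grid(species = SPECIES, node = seq_len(n), domain = c("i", "e"),
                      t = seq_len(nt), stringsAsFactors = FALSE)
  df <- data.frame(
    time_s = traj$times[grid$t] / 1e3,
    x_mm = traj$mesh$x[grid$node],
    domain = grid$domain,
    species = grid$species,
    total_mM = traj$conc[cbind(match(grid$species, SPECIES), grid$node,
                               match(grid$domain, c("i", "e")), grid$t)],
    free_mM = traj$free[cbind(match(grid$species, SPECIES), grid$node,
                              match(grid$domain, c("i", "e")), grid$t)],
    phi_mV = ifelse(grid$domain == "e", traj$phi_e[cbind(grid$node, grid$t)],
                    traj$phi_e[cbind(grid$node, grid$t)] +
                      traj$vm[cbind(grid$node, grid$t)]),
    vm_mV = traj$vm[cbind(grid$node, grid$t)],
    stringsAsFactors = FALSE
  )
  ord <- order(df$time_s, df$x_mm, df$domain, match(df$species, SPECIES))
  df <- df[ord, ]
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a long-format trajectory CSV
#' @param path file written by [write_trajectory()].
#' @return the trajectory data.frame.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "x_mm", "domain", "species", "total_mM", "free_mM",
            "phi_mV", "vm_mV")
  if (!all(need %in% names(df)))
    stop("read_trajectory: file is not an ionbz trajectory CSV")
  df
}

#' Write the run manifest
#'
#' JSON record of a calibrated model: a hash of the configuration, every
#' derived parameter with its provenance string, solver settings and the
#' package version. Re-running from the same manifest configuration
#' reproduces outputs bit-for-bit (the pipeline has no hidden randomness).
#'
#' @param model calibrated model.
#' @param path output file.
#' @param settings optional [solver_settings()].
#' @param extra optional named list of additional diagnostics.
#' @return path, invisibly.
#' @export
write_manifest <- function(model, path, settings = NULL, extra = NULL) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  saveRDS(unclass(model$config), tmp)
  hash <- unname(tools::md5sum(tmp))
  manifest <- list(
    package = "ionbz",
    version = as.character(utils::packageVersion("ionbz")),
    config_hash = hash,
    provenance = model$manifest,
    densities = model$densities,
    q_static = list(i = model$q_static_i, e = model$q_static_e),
    diffusivities = list(species = model$species$name,
                         d_i = model$species$d_i, d_e = model$species$d_e),
    settings = if (!is.null(settings)) unclass(settings) else NULL,
    extra = extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Synthetic test inputs
#'
#' Seeded, reproducible fixtures: (a) Hill-shaped spatial profiles with known
#' analytic widths for the border-zone fitting tests; (b) small 1D meshes;
#' (c) randomized membrane states inside physiological boxes for the
#' flux-oracle tests.
#'
#' @param kind one of "hill_profile", "mesh", "membrane_states".
#' @param seed integer seed.
#' @param n number of profile points / nodes / states.
#' @param ... kind-specific overrides: `base`, `amp`, `midpoint`,
#'   `steepness`, `noise` for profiles.
#' @return kind-specific list; `hill_profile` carries the analytic `width`.
#' @export
generate_fixtures <- function(kind = c("hill_profile", "mesh", "membrane_states"),
                              seed = 1, n = NULL, ...) {
  kind <- match.arg(kind)
  set.seed(seed)
  dots <- list(...)
  if (kind == "hill_profile") {
    n <- n %||% 64
    base <- dots$base %||% stats::runif(1, 1, 10)
    amp <- dots$amp %||% stats::runif(1, 0.5, 5)
    midpoint <- dots$midpoint %||% stats::runif(1, 6, 10)
    steepness <- dots$steepness %||% stats::runif(1, 5, 40)
    noise <- dots$noise %||% 0
    x <- seq(0.25, 16, length.out = n)
    y <- base + amp / (1 + (x / midpoint)^steepness) +
      stats::rnorm(n, 0, noise)
    return(list(x = x, y = y, base = base, amp = amp, midpoint = midpoint,
                steepness = steepness,
                width = hill_width(midpoint, steepness)))
  }
  if (kind == "mesh") {
    n <- n %||% sample(5:20, 1)
    dx <- dots$dx %||% sample(c(0.25, 0.5, 1), 1)
    return(mesh_1d(n * dx, dx))
  }
  # membrane_states: free concentrations inside physiological boxes
  n <- n %||% 20
  box <- list(
    Na = c(2, 20, 100, 160), K = c(80, 160, 2, 12), Cl = c(5, 40, 80, 140),
    Ca = c(5e-5, 1e-3, 0.5, 3), H = c(ph_to_h(7.6), ph_to_h(6.4),
                                      ph_to_h(7.8), ph_to_h(6.8)),
    HCO3 = c(4, 25, 10, 35), CO2 = c(0.5, 3, 0.5, 3), Lac = c(0.1, 15, 0.1, 15)
  )
  free_i <- matrix(0, 8, n, dimnames = list(SPECIES, NULL))
  free_e <- matrix(0, 8, n, dimnames = list(SPECIES, NULL))
  for (k in 1:8) {
    b <- box[[SPECIES[k]]]
    free_i[k, ] <- stats::runif(n, min(b[1], b[2]), max(b[1], b[2]))
    free_e[k, ] <- stats::runif(n, min(b[3], b[4]), max(b[3], b[4]))
  }
  list(free_i = free_i, free_e = free_e,
       vm = stats::runif(n, -95, -20))
}
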