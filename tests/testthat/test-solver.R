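# The spatial discretization and the implicit Newton solver.

test_that("interface fluxes: uniform fields, linear potential, pure diffusion decay", {
  cst <- phys_constants()
  # uniform concentration and potential: all interface fluxes vanish
  tf <- transport_flux(rep(5, 8), rep(-3, 8), 1e-6, 1, 0.5, 0.2, cst$rtf)
  expect_equal(tf$diff, rep(0, 7))
  expect_equal(tf$drift, rep(0, 7))
  # uniform concentration, linear potential: drift = -f D (z/rtf) c slope
  phi <- seq(0, 7) * 2          # slope 2 mV per node, dx 0.5 -> 4 mV/mm
  tf <- transport_flux(rep(5, 8), phi, 1e-6, -1, 0.5, 0.2, cst$rtf)
  expect_equal(tf$drift,
               rep(-0.2 * 1e-6 * (-1 / cst$rtf) * 5 * 4, 7))
  expect_equal(tf$diff, rep(0, 7))

  # neutral species: cosine mode decays at the analytic Fourier rate under
  # zero-flux ends (explicit integration of the discrete operator)
  n <- 32; dx <- 0.5; L <- n * dx; D <- 1e-3
  x <- (seq_len(n) - 0.5) * dx
  c0 <- 1 + 0.1 * cos(pi * x / L)
  cc <- c0; dt <- 10
  for (s in 1:200) {
    tf <- transport_flux(cc, rep(0, n), D, 0, dx, 1, cst$rtf)
    div <- ionbz:::flux_divergence(tf$diff + tf$drift, n, dx)
    cc <- cc - dt * div
  }
  k_mode <- (2 / dx) * sin(pi * dx / (2 * L))  # discrete wavenumber
  expected <- 1 + 0.1 * cos(pi * x / L) * exp(-D * k_mode^2 * 2000)
  expect_equal(cc, expected, tolerance = 1e-4)
})

test_that("calibrated uniform strand is a discrete steady state", {
  m <- test_model()
  mesh <- mesh_1d(8, 0.5)
  ctx <- ionbz:::make_context(m, mesh, no_ischemia())
  u <- ionbz:::initial_state(m, mesh$n)
  R <- assemble_residual(u, u, 100, ctx)
  expect_lt(max(abs(R)), 1e-12)
})

test_that("z-weighted species rows reproduce the charge row", {
  # the elliptic constraint is the z-weighted sum of both domains' transport
  # divergences; summing the species rows of a sourceless residual recovers it
  m <- test_model()
  mesh <- mesh_1d(8, 0.5)
  ctx <- ionbz:::make_context(m, mesh, no_ischemia())
  u <- ionbz:::initial_state(m, mesh$n)
  # perturb to a non-trivial state
  set.seed(2)
  up <- u * (1 + 1e-4 * rnorm(length(u)))
  dt <- 50
  out <- ionbz:::assemble_residual_ctx(up, u, dt, ctx, want_fields = TRUE)
  st_new <- ionbz:::unpack_state(up, mesh$n)
  st_old <- ionbz:::unpack_state(u, mesh$n)
  R <- matrix(out$R, 17, mesh$n)
  z <- m$species$z
  geo <- m$geometry
  # remove the time-derivative and source parts: what remains of the
  # z-weighted species rows is the charge row (membrane fluxes cancel)
  acc <- colSums(z * (geo$f_cyt * (st_new$c_i - st_old$c_i) +
                        geo$f_e * (st_new$c_e - st_old$c_e)))
  hyd_src <- 0  # hydration and ischemic sources are charge-neutral
  lhs <- colSums(z * R[1:8, , drop = FALSE]) +
    colSums(z * R[9:16, , drop = FALSE]) - acc - hyd_src
  charge_row <- R[17, ]
  charge_row[ctx$gauge] <- lhs[ctx$gauge]  # gauge row replaced the constraint
  expect_equal(lhs, charge_row, tolerance = 1e-12)
})

test_that("discrete operators reduce to the bidomain pair for a single carrier", {
  # uniform concentrations, no membrane flux: the charge row equals the
  # discrete divergence of sigma_i grad(phi_i) + sigma_e grad(phi_e), and the
  # z-weighted intracellular rows equal the capacitive form of the first
  # bidomain equation evaluated with sigma_i.
  m <- test_model()
  mesh <- mesh_1d(8, 0.5)
  n <- mesh$n
  ctx <- ionbz:::make_context(m, mesh, no_ischemia())
  u0 <- ionbz:::initial_state(m, n)
  cst <- m$constants
  geo <- m$geometry
  z <- m$species$z

  # impose a potential perturbation at uniform concentrations via phi_e
  phi_e <- 0.5 * sin(seq_len(n))
  st <- ionbz:::unpack_state(u0, n)
  u1 <- ionbz:::pack_state(st$c_i, st$c_e, phi_e)
  dt <- 1
  out <- ionbz:::assemble_residual_ctx(u1, u1, dt, ctx, want_fields = TRUE)
  R <- matrix(out$R, 17, n)

  # per-species conductivity sums (the Eq. 21 bundle), mm^2/ms * mM * f
  lap <- function(v) {
    flx <- -diff(v) / mesh$dx
    ionbz:::flux_divergence(flx, n, mesh$dx)
  }
  free_i <- out$fields$free_i[, 1]
  free_e <- out$fields$free_e[, 1]
  sig_i <- geo$f_cyt * sum(z^2 * m$species$d_i * free_i) / cst$rtf
  sig_e <- geo$f_e * sum(z^2 * m$species$d_e * free_e) / cst$rtf
  phi_i <- out$fields$phi_i
  # charge row = -div(sigma_i grad phi_i) - div(sigma_e grad phi_e) = 0 form
  expect_equal(R[17, -ctx$gauge] / dt,
               (sig_i * lap(phi_i) + sig_e * lap(phi_e))[-ctx$gauge],
               tolerance = 1e-10)
  # z-weighted intracellular rows: capacitive charging = intracellular current
  # divergence (the first bidomain equation; Vm unchanged here so the
  # time-derivative term is zero and the flux term carries everything)
  lhs <- colSums(z * R[1:8, , drop = FALSE]) / dt
  expect_equal(lhs, sig_i * lap(phi_i), tolerance = 1e-10)
})

test_that("implicit solution matches a tiny-dt explicit integrator", {
  # de-stiffened configuration (small CO2 permeability, slow hydration) so a
  # forward-Euler oracle is stable, on a 5-node strand over 100 ms
  cfg <- default_config()
  cfg$co2$p_m <- 1e-4
  cfg$co2$kf <- 1e-7
  cfg$co2$kb <- 1e-7 / (10^(-6.1) * 1e3)
  m <- calibrate_model(cfg)
  mesh <- mesh_1d(5, 1)
  isc <- ischemia_config(nak_inhibition = 0.5, ikb_activation = 1,
                         co2_source = 0, h_source = 0, midpoint = 2.5,
                         steepness = 8)
  ctx <- ionbz:::make_context(m, mesh, isc)
  u0 <- ionbz:::initial_state(m, mesh$n)

  # implicit: backward Euler at dt = 1 ms
  tr <- run_simulation(m, mesh, isc, duration = 100,
                       settings = solver_settings(dt = 1),
                       snapshot_every = 100)
  # explicit oracle: forward Euler at dt = 0.01 ms with a direct linear
  # solve of the elliptic constraint each step
  u_exp <- ionbz:::integrate_explicit(u0, ctx, duration = 100, dt = 0.01)
  st_imp <- ionbz:::unpack_state(tr$state, mesh$n)
  st_exp <- ionbz:::unpack_state(u_exp, mesh$n)
  rel <- abs(st_imp$c_i - st_exp$c_i) / pmax(abs(st_exp$c_i), 1e-8)
  expect_lt(max(rel), 1e-4)
  rel_e <- abs(st_imp$c_e - st_exp$c_e) / pmax(abs(st_exp$c_e), 1e-8)
  expect_lt(max(rel_e), 1e-4)
})

test_that("Newton converges quadratically near the solution", {
  m <- test_model()
  mesh <- mesh_1d(8, 1)
  isc <- ischemia_config(midpoint = 4)
  ctx <- ionbz:::make_context(m, mesh, isc)
  u_old <- ionbz:::initial_state(m, mesh$n)
  set <- solver_settings(dt = 500)
  je <- new.env(); je$fac <- NULL; je$builds <- 0L
  je$typ <- ionbz:::typical_scale(m)
  sol <- ionbz:::newton_solve(u_old, 500, ctx, set, je)
  expect_true(sol$converged)
  # walk in from a perturbed iterate with a fresh Jacobian each step
  u <- sol$u * (1 + 1e-5)
  errs <- numeric(4)
  for (it in 1:4) {
    R <- assemble_residual(u, u_old, 500, ctx)
    J <- ionbz:::build_jacobian(u, u_old, 500, ctx, R, 1e-7, je$typ)
    u <- u - as.numeric(Matrix::solve(Matrix::lu(J), R))
    errs[it] <- max(abs(u - sol$u) / pmax(abs(sol$u), 1e-8))
  }
  ratios <- errs[-1] / errs[-4]
  # strong contraction per iteration down to the finite-difference floor
  expect_lt(ratios[1], 0.2)
  expect_lt(errs[3], 1e-6)
})

test_that("no-ischemia strand holds its state for five minutes", {
  m <- test_model()
  tr <- run_simulation(m, mesh_1d(16, 1), no_ischemia(),
                       duration = 5 * 60 * 1e3,
                       settings = solver_settings(dt = 5000),
                       snapshot_every = 5 * 60 * 1e3)
  nt <- length(tr$times)
  drift <- abs(tr$conc[, , , nt] - tr$conc[, , , 1]) /
    pmax(abs(tr$conc[, , , 1]), 1e-12)
  expect_lt(max(drift), 1e-3)
})

test_that("closed-system species content is conserved without sources", {
  m <- test_model()
  mesh <- mesh_1d(8, 0.5)
  isc <- ischemia_config(nak_inhibition = 0.7, ikb_activation = 2,
                         co2_source = 0, h_source = 0, midpoint = 4)
  tr <- run_simulation(m, mesh, isc, duration = 60e3,
                       settings = solver_settings(dt = 1000),
                       snapshot_every = 60e3)
  nt <- length(tr$times)
  geo <- m$geometry
  for (k in 1:8) {
    tot0 <- sum(geo$f_cyt * tr$conc[k, , 1, 1] + geo$f_e * tr$conc[k, , 2, 1])
    tot1 <- sum(geo$f_cyt * tr$conc[k, , 1, nt] + geo$f_e * tr$conc[k, , 2, nt])
    if (k %in% c(5, 6, 7)) next  # H, HCO3, CO2 exchange through hydration
    expect_lt(abs(tot1 - tot0) / max(abs(tot0), 1e-9), 1e-8)
  }
  # the hydration-coupled triple conserves the two reaction invariants
  inv1 <- function(s) {
    sum(geo$f_cyt * (tr$conc[5, , 1, s] + tr$conc[7, , 1, s]) +
          geo$f_e * (tr$conc[5, , 2, s] + tr$conc[7, , 2, s]))
  }
  inv2 <- function(s) {
    sum(geo$f_cyt * (tr$conc[6, , 1, s] + tr$conc[7, , 1, s]) +
          geo$f_e * (tr$conc[6, , 2, s] + tr$conc[7, , 2, s]))
  }
  expect_lt(abs(inv1(nt) - inv1(1)) / abs(inv1(1)), 1e-8)
  expect_lt(abs(inv2(nt) - inv2(1)) / abs(inv2(1)), 1e-8)
})

test_that("the extracellular potential gauge does not affect the physics", {
  m <- test_model()
  mesh <- mesh_1d(8, 1)
  isc <- ischemia_config(midpoint = 4)
  # same step solved with the gauge pinned at each end of the strand
  run_gauge <- function(node) {
    ctx <- ionbz:::make_context(m, mesh, isc)
    ctx$gauge <- node
    set <- solver_settings(dt = 500)
    je <- new.env(); je$fac <- NULL; je$builds <- 0L
    je$typ <- ionbz:::typical_scale(m)
    u <- ionbz:::initial_state(m, mesh$n)
    for (s in 1:10) u <- ionbz:::newton_solve(u, 500, ctx, set, je)$u
    ionbz:::unpack_state(u, mesh$n)
  }
  a <- run_gauge(1L)
  b <- run_gauge(8L)
  expect_equal(a$c_i, b$c_i, tolerance = 1e-9)
  expect_equal(a$c_e, b$c_e, tolerance = 1e-9)
  # potentials agree up to the constant reference shift
  expect_equal(a$phi_e - a$phi_e[1], b$phi_e - b$phi_e[1], tolerance = 1e-8)
})
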