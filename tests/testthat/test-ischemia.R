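test_that("severity profile: midpoint, viable tail, monotonicity", {
  isc <- ischemia_config(midpoint = 16, steepness = 60)
  expect_equal(severity_profile(16, isc), 0.5)
  expect_lt(severity_profile(24, isc), 0.01)
  expect_gt(severity_profile(8, isc), 0.99)
  x <- seq(0.25, 32, by = 0.25)
  expect_true(all(diff(severity_profile(x, isc)) <= 0))
})

test_that("node-local ischemic parameters scale with severity", {
  isc <- ischemia_config(nak_inhibition = 1, ikb_activation = 3,
                         co2_source = 1e-5, h_source = 2e-5)
  sc0 <- apply_ischemia(0, isc)
  expect_equal(sc0$nak_scale, 1)
  expect_equal(sc0$kb_scale, 1)
  expect_equal(sc0$co2_source, 0)
  expect_equal(sc0$h_source, 0)
  sc1 <- apply_ischemia(1, isc)
  expect_equal(sc1$nak_scale, 0)  # full inhibition at severity 1
  expect_equal(sc1$kb_scale, 3)
  sc <- apply_ischemia(c(0.25, 0.5), isc)
  expect_equal(sc$nak_scale, c(0.75, 0.5))
  expect_equal(sc$h_source, c(0.5e-5, 1e-5))
})

test_that("ischemic sourcing conserves charge exactly", {
  # H+ is paired 1:1 with the lactate anion and hydration moves H+ and HCO3-
  # together, so the total charge density of each node is invariant
  m <- test_model()
  mesh <- mesh_1d(8, 1)
  isc <- ischemia_config(nak_inhibition = 0.6, ikb_activation = 2,
                         co2_source = 1e-5, h_source = 4e-5, midpoint = 4)
  tr <- run_simulation(m, mesh, isc, duration = 30e3,
                       settings = solver_settings(dt = 1000),
                       snapshot_every = 30e3)
  nt <- length(tr$times)
  z <- m$species$z
  geo <- m$geometry
  q0 <- colSums(z * (geo$f_cyt * tr$conc[, , 1, 1] + geo$f_e * tr$conc[, , 2, 1]))
  q1 <- colSums(z * (geo$f_cyt * tr$conc[, , 1, nt] + geo$f_e * tr$conc[, , 2, nt]))
  expect_lt(max(abs(q1 - q0)), 1e-8)
})

test_that("all components off reproduces the control exactly", {
  m <- test_model()
  mesh <- mesh_1d(8, 1)
  off <- ischemia_config(nak_inhibition = 0, ikb_activation = 1,
                         co2_source = 0, h_source = 0)
  a <- run_simulation(m, mesh, off, duration = 30e3,
                      settings = solver_settings(dt = 5000),
                      snapshot_every = 30e3)
  b <- run_simulation(m, mesh, no_ischemia(), duration = 30e3,
                      settings = solver_settings(dt = 5000),
                      snapshot_every = 30e3)
  expect_identical(a$conc, b$conc)
  expect_identical(a$vm, b$vm)
})

test_that("pump-inhibition sweep: monotone Na_i response; acidosis leaves Na_i nearly flat", {
  m <- test_model()
  mesh <- mesh_1d(4, 1)
  sw <- component_sweep(m, mesh, "nak", levels = c(0, 0.3, 0.6, 0.9),
                        duration = 60e3,
                        settings = solver_settings(dt = 2000),
                        midpoint = 2, steepness = 20)
  core_dna <- vapply(sw$runs, function(tr) {
    nt <- length(tr$times)
    tr$free["Na", 1, 1, nt] - tr$free["Na", 1, 1, 1]
  }, numeric(1))
  expect_equal(core_dna[1], 0, tolerance = 1e-9)  # level 0: no change
  expect_true(all(diff(core_dna) > 0))
  # metabolic acidosis at its reference intensity moves Na_i far less than
  # mid-level pump inhibition does
  isc_h <- ischemia_config(nak_inhibition = 0, ikb_activation = 1,
                           co2_source = 0, h_source = test_ischemia()$h_source,
                           midpoint = 2, steepness = 20)
  tr_h <- run_simulation(m, mesh, isc_h, duration = 60e3,
                         settings = solver_settings(dt = 2000),
                         snapshot_every = 60e3)
  nt <- length(tr_h$times)
  dna_h <- abs(tr_h$free["Na", 1, 1, nt] - tr_h$free["Na", 1, 1, 1])
  expect_lt(dna_h, 0.5 * core_dna[3])
})

test_that("combined ischemia: K_e rises early and plateaus while Na_i keeps rising", {
  m <- test_model()
  isc <- test_ischemia()
  isc$midpoint <- 16  # single node deep in the core
  tr <- run_simulation(m, mesh_1d(1, 1), isc, duration = 5 * 60 * 1e3,
                       settings = solver_settings(dt = 2500),
                       snapshot_every = 30e3)
  nt <- length(tr$times)
  ke <- tr$free["K", 1, 2, ]
  nai <- tr$free["Na", 1, 1, ]
  # normalized half-rise time: K_e reaches half its final change earlier
  half_time <- function(v) {
    target <- v[1] + (v[nt] - v[1]) / 2
    tr$times[which(v >= target)[1]]
  }
  expect_lt(half_time(ke), half_time(nai))
  # late K_e slope is a small fraction of its early slope (plateau tendency)
  early <- (ke[3] - ke[1]) / (tr$times[3] - tr$times[1])
  late <- (ke[nt] - ke[nt - 2]) / (tr$times[nt] - tr$times[nt - 2])
  expect_lt(abs(late), 0.35 * abs(early))
  # Na_i still rising in the final minute
  expect_gt(nai[nt] - nai[nt - 2], 0)
  # the ischemic core ends depolarized relative to rest
  expect_gt(tr$vm[1, nt], tr$vm[1, 1])
})
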