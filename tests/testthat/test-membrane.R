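cst <- phys_constants()

test_that("background channel: reversal, zero density, linearity, sign flip", {
  e_k <- nernst_potential(135, 4, 1, cst)
  expect_equal(j_background(e_k, 135, 4, 1, 3e-9, cst), 0)
  expect_equal(j_background(-60, 135, 4, 1, 0, cst), 0)
  j1 <- j_background(-60, 135, 4, 1, 1e-9, cst)
  expect_equal(j_background(-60, 135, 4, 1, 5e-9, cst), 5 * j1)
  below <- j_background(e_k - 10, 135, 4, 1, 1e-9, cst)
  above <- j_background(e_k + 10, 135, 4, 1, 1e-9, cst)
  expect_true(below > 0 && above < 0)  # cation: influx below E, efflux above
  # anion: signs mirror
  e_cl <- nernst_potential(18, 110, -1, cst)
  expect_lt(j_background(e_cl - 10, 18, 110, -1, 1e-9, cst), 0)
})

test_that("NaK pump: full inhibition, 3:2 stoichiometry, Na_i monotonicity", {
  kin <- default_config()$membrane$kinetics$nak
  full <- j_nak(8, 140, 4, -70, 1e-6, kin, inhibition = 1)
  expect_equal(full$na, 0)
  expect_equal(full$k, 0)
  st <- generate_fixtures("membrane_states", seed = 11, n = 25)
  out <- j_nak(st$free_i["Na", ], st$free_e["Na", ], st$free_e["K", ],
               st$vm, 1e-6, kin)
  expect_equal(out$na / out$k, rep(-3 / 2, 25))
  sweep <- j_nak(seq(1, 20, by = 0.5), 140, 4, -80, 1e-6, kin)$cycle
  expect_true(all(diff(sweep) > 0))
  expect_error(j_nak(4, 140, 4, -80, 1e-6, kin, inhibition = 2), "inhibition")
  expect_error(j_nak(4, 140, 4, -80, 1e-6, list()), "kinetic")
})

test_that("NCX: stoichiometry, thermodynamic reversal, sign flip in Vm", {
  kin <- default_config()$membrane$kinetics$ncx
  st <- generate_fixtures("membrane_states", seed = 3, n = 25)
  out <- j_ncx(st$free_i["Na", ], st$free_e["Na", ], st$free_i["Ca", ],
               st$free_e["Ca", ], st$vm, 1e-4, kin, cst)
  expect_equal(out$na, -3 * out$ca)
  # reversal potential 3 E_Na - 2 E_Ca at the reference concentrations
  e_na <- nernst_potential(4, 140, 1, cst)
  e_ca <- nernst_potential(1e-4, 1.2, 2, cst)
  v_rev <- 3 * e_na - 2 * e_ca
  at_rev <- j_ncx(4, 140, 1e-4, 1.2, v_rev, 1e-4, kin, cst)
  expect_equal(at_rev$ca, 0, tolerance = 1e-18)
  vms <- seq(v_rev - 40, v_rev + 40, by = 5)
  cyc <- j_ncx(4, 140, 1e-4, 1.2, vms, 1e-4, kin, cst)$cycle
  expect_true(all(cyc[vms < v_rev] < 0))
  expect_true(all(cyc[vms > v_rev] > 0))
})

test_that("acid-base transporters: equilibria, electroneutrality, NHE pH dependence", {
  m <- test_model()
  x <- m$densities; kin <- m$kinetics
  mk_free <- function(na_i = 4, na_e = 140, cl_i = 18, cl_e = 110,
                      h_i = ph_to_h(7.1), h_e = ph_to_h(7.4),
                      hco3_i = 11.7, hco3_e = 23.35) {
    n <- max(lengths(list(na_i, cl_i, h_i, hco3_i)))
    fi <- matrix(m$species$c_i0, 8, n); fe <- matrix(m$species$c_e0, 8, n)
    fi[1, ] <- na_i; fi[3, ] <- cl_i; fi[5, ] <- h_i; fi[6, ] <- hco3_i
    fe[1, ] <- na_e; fe[3, ] <- cl_e; fe[5, ] <- h_e; fe[6, ] <- hco3_e
    list(fi = fi, fe = fe)
  }
  # each transporter at its own equilibrium ratio gives zero flux
  eq_nhe <- mk_free(na_i = 140 * ph_to_h(7.1) / ph_to_h(7.4))
  expect_equal(j_acid_transporters(eq_nhe$fi, eq_nhe$fe, x, kin)$nhe$na, 0)
  eq_che <- mk_free(cl_i = 110 * ph_to_h(7.4) / ph_to_h(7.1))
  expect_equal(j_acid_transporters(eq_che$fi, eq_che$fe, x, kin)$che$cl, 0)
  eq_ae <- mk_free(hco3_i = 18 * 23.35 / 110)
  expect_equal(j_acid_transporters(eq_ae$fi, eq_ae$fe, x, kin)$ae$cl, 0)
  eq_nbc <- mk_free(hco3_i = 140 * 23.35 / 4)
  expect_equal(j_acid_transporters(eq_nbc$fi, eq_nbc$fe, x, kin)$nbc$na, 0)

  # z-weighted flux of each pathway vanishes identically
  st <- generate_fixtures("membrane_states", seed = 5, n = 30)
  acid <- j_acid_transporters(st$free_i, st$free_e, x, kin)
  expect_equal(acid$nhe$na * 1 + acid$nhe$h * 1, rep(0, 30))
  expect_equal(acid$che$cl * -1 + acid$che$h * 1, rep(0, 30))
  expect_equal(acid$ae$cl * -1 + acid$ae$hco3 * -1, rep(0, 30))
  expect_equal(acid$nbc$na * 1 + acid$nbc$hco3 * -1, rep(0, 30))

  # NHE flux strictly decreasing in pH_i over 6.4-7.4
  phs <- seq(6.4, 7.4, by = 0.05)
  probe <- mk_free(h_i = ph_to_h(phs))
  j <- j_acid_transporters(probe$fi, probe$fe, x, kin)$nhe$na
  expect_true(all(diff(j) < 0))
})

test_that("MCT1: equilibrium, 1:1 stoichiometry, cosubstrate saturation", {
  kin <- default_config()$membrane$kinetics$mct1
  # equal transmembrane lactate x H products -> zero
  expect_equal(j_mct1(0.5, 1, 2 * ph_to_h(7.4), ph_to_h(7.4), 1e-7, kin), 0)
  # cotransport is antisymmetric under swapping the two faces
  j <- j_mct1(0.3, 2, ph_to_h(7.0), ph_to_h(7.3), 1e-7, kin)
  j_rev <- j_mct1(2, 0.3, ph_to_h(7.3), ph_to_h(7.0), 1e-7, kin)
  expect_equal(j_rev, -j)
  expect_gt(j, 0)
  # saturation: at 100x the cosubstrate pair the flux is within 1% of the
  # numerically computed asymptote
  lac_e <- 1; h_e <- ph_to_h(7.4)
  at100 <- j_mct1(0.5, 100 * lac_e, ph_to_h(7.1), 100 * h_e, 1e-7, kin)
  asym <- j_mct1(0.5, 1e6 * lac_e, ph_to_h(7.1), 1e6 * h_e, 1e-7, kin)
  expect_lt(abs(at100 - asym) / abs(asym), 0.01)
})

test_that("membrane CO2 flux: equilibrium, linearity, fast equilibration", {
  expect_equal(j_co2(1.17, 1.17, 0.058), 0)
  expect_equal(j_co2(1, 2, 0.058), 2 * j_co2(1, 2, 0.029))
  # closed two-box relaxation time far below 1 s at the model permeability
  m <- test_model()
  geo <- m$geometry
  rate <- geo$chi * m$co2$p_m * (1 / geo$f_cyt + 1 / geo$f_e)  # 1/ms
  ci <- 1; ce <- 2
  dt <- 1e-4
  for (s in 1:500) {
    j <- j_co2(ci, ce, m$co2$p_m)
    ci <- ci + dt * geo$chi * j / geo$f_cyt
    ce <- ce - dt * geo$chi * j / geo$f_e
  }
  # 0.05 ms of integration; transmembrane gradient decays like exp(-rate t)
  expect_lt(abs(ce - ci), (2 - 1) * exp(-rate * 0.05 * 0.9))
  expect_lt(1 / rate, 1000)  # time constant << 1 s
})

test_that("calcium equilibrium: degenerate split, root oracle, conservation", {
  m <- test_model()
  geo <- m$geometry
  # B = 0 and SR decoupled: free = total scaled by the cytosol/SR volumes
  ca0 <- list(v_max = 0, p_leak = 0, k_serca = 3e-4)
  b0 <- buffer_spec(0, 6e-4)
  out <- ca_equilibrium(c(0.01, 0.2), b0, ca0, geo)
  expect_equal(out$free, c(0.01, 0.2) / (1 + geo$f_sr / geo$f_cyt))

  # closed form against a bracketed numerical root, 1000 random draws
  set.seed(42)
  n <- 1000
  draws <- data.frame(
    tot = 10^runif(n, -4, 0),
    B = 10^runif(n, -2, 0.5),
    kb = 10^runif(n, -4, -2),
    ks = 10^runif(n, -4, -2),
    vmax = 10^runif(n, -6, -4),
    pleak = 10^runif(n, -5, -3)
  )
  for (i in seq_len(n)) {
    d <- draws[i, ]
    ca <- list(v_max = d$vmax, p_leak = d$pleak, k_serca = d$ks)
    buf <- buffer_spec(d$B, d$kb)
    got <- ca_equilibrium(d$tot, buf, ca, geo)
    f <- function(c) ca_total_from_free_oracle(c, buf, ca, geo) - d$tot
    ref <- uniroot(f, c(0, d$tot), tol = 1e-15)$root
    expect_equal(got$free, ref, tolerance = 1e-6)
    # total calcium conserved across cytosol, buffer and SR partitions
    back <- got$free + got$bound + (geo$f_sr / geo$f_cyt) * got$sr
    expect_equal(back, d$tot, tolerance = 1e-10)
  }

  # calibrated resting fixed point
  rest <- ca_equilibrium(unname(m$state0$c_i_tot["Ca"]), m$ca$buffer, m$ca, geo)
  expect_equal(rest$free, m$ca$resting, tolerance = 1e-9)
  expect_equal(rest$sr, m$ca$sr0, tolerance = 1e-9)
  expect_error(ca_equilibrium(-1, m$ca$buffer, m$ca, geo), ">= 0")
})

test_that("membrane potential: neutrality, linearity, calibrated value", {
  m <- test_model()
  c0 <- m$state0$c_i_tot
  expect_equal(vm_from_charge(c0, m$q_static_i, m), -80)
  # adding equal amounts of a +1 and a -1 species leaves Vm unchanged
  c1 <- c0; c1["Na"] <- c1["Na"] + 0.5; c1["Cl"] <- c1["Cl"] + 0.5
  expect_equal(vm_from_charge(c1, m$q_static_i, m), -80)
  # moving potassium in shifts Vm by the slope
  c2 <- c0; c2["K"] <- c2["K"] + 1e-4
  expect_equal(vm_from_charge(c2, m$q_static_i, m) - (-80),
               m$vm_slope * 1e-4)
})

test_that("gap junction factor: normalization, acid closure, single maximum", {
  gj <- default_config()$membrane$gap_junction
  expect_equal(gap_junction_scale(7.1, gj), 1)
  expect_lt(gap_junction_scale(5.2, gj), 0.1)
  grid <- seq(5.5, 8.5, by = 0.01)
  g <- gap_junction_scale(grid, gj)
  peak <- which.max(g)
  expect_gt(peak, 1)
  expect_lt(peak, length(grid))
  expect_true(all(diff(g[1:peak]) > 0))
  expect_true(all(diff(g[peak:length(g)]) < 0))
  expect_error(gap_junction_scale(3, gj), "range")
})

test_that("net membrane flux: calibrated zero, pump-block sign response", {
  m <- test_model()
  expect_lt(max(abs(resting_flux_residual(m))), 1e-12)
  # 60% NaK inhibition: net Na+ flux turns positive (influx) immediately
  out <- net_membrane_flux(matrix(m$species$c_i0, 8), matrix(m$species$c_e0, 8),
                           m$vm_rest, m, nak_scale = 0.4)
  expect_gt(out$J["Na", 1], 0)
  expect_lt(out$J["K", 1], 0)
  # z-weighted current reported alongside
  expect_equal(out$current, sum(out$J[, 1] * c(1, 1, -1, 2, 1, -1, 0, -1)))
})

test_that("closed-cell charge bookkeeping: Vm from charge matches flux integral", {
  m <- test_model()
  tr <- run_simulation(m, mesh_1d(1, 1),
                       ischemia_config(nak_inhibition = 0.5, ikb_activation = 1,
                                       co2_source = 0, h_source = 0,
                                       midpoint = 16),
                       duration = 10e3, settings = solver_settings(dt = 1000),
                       snapshot_every = 10e3)
  nt <- length(tr$times)
  z <- c(1, 1, -1, 2, 1, -1, 0, -1)
  dvm_conc <- m$vm_slope * sum(z * (tr$conc[, 1, 1, nt] - tr$conc[, 1, 1, 1]))
  expect_equal(tr$vm[1, nt] - tr$vm[1, 1], dvm_conc, tolerance = 1e-9)
  # the intracellular charge change is exactly the z-weighted transmembrane
  # ledger (no transport in a single-node strand)
  dvm_led <- m$vm_slope * sum(z * tr$ledger$trans[, 1, 1])
  expect_equal(tr$vm[1, nt] - tr$vm[1, 1], dvm_led, tolerance = 1e-6)
})

test_that("calibrated 0D cell holds its state for ten minutes", {
  m <- test_model()
  tr <- run_cell(m, duration = 10 * 60 * 1e3,
                 settings = solver_settings(dt = 5000))
  drift <- abs(tr$conc[, , , 2] - tr$conc[, , , 1]) /
    pmax(abs(tr$conc[, , , 1]), 1e-12)
  expect_lt(max(drift), 1e-3)
  expect_equal(tr$vm[1, 2], -80, tolerance = 1e-6)
})
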