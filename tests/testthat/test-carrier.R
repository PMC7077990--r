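test_that("carrier derivatives reproduce term-by-term evaluation of the rate equations", {
  p <- ref_params()
  bc <- ref_bc()
  p_mit <- 21
  x <- rep(p$mpc_total / 6, 6)              # equal occupancy
  d <- carrier_derivatives(x, p_mit, p, bc)

  # independent hand substitution, one equation at a time
  kon <- 100; koffh <- 20; koffp <- 2.12e6; f1 <- 200; f2 <- 3000
  ho <- 0.063; hi <- 0.016; po <- 33; pi_ <- 21
  e <- p$mpc_total / 6
  expect_equal(d[["mpc_o"]], koffh * e + f1 * e - kon * e * ho - f1 * e)
  expect_equal(d[["mpc_i"]], koffh * e + f1 * e - kon * e * hi - f1 * e)
  expect_equal(d[["mpc_o_h"]], kon * e * ho + koffp * e - koffh * e - kon * e * po)
  expect_equal(d[["mpc_i_h"]], kon * e * hi + koffp * e - koffh * e - kon * e * pi_)
  expect_equal(d[["mpc_o_hp"]], kon * e * po + f2 * e - koffp * e - f2 * e)
  expect_equal(d[["mpc_i_hp"]], kon * e * pi_ + f2 * e - koffp * e - f2 * e)

  # carrier conservation: derivatives cancel pairwise for any state
  set.seed(42)
  for (k in 1:10) {
    x <- runif(6, 0, 1)
    d <- carrier_derivatives(x, runif(1, 0, 100), p, bc)
    expect_lt(abs(sum(d)), 1e-9 * max(abs(d), 1))
  }

  # no ligands anywhere and balanced empty carrier: nothing moves
  d0 <- carrier_derivatives(c(1.62, 1.62, 0, 0, 0, 0), 0, p,
                            boundary_conditions(p_cyt = 0, h_cyt = 0,
                                                h_mit = 0))
  expect_equal(unname(as.numeric(d0)), rep(0, 6))

  expect_error(carrier_derivatives(c(-1, 1, 1, 1, 1, 1), 0, p, bc),
               "non-negative")
})

test_that("occupancy steady state is stationary, conserved, and matches integration", {
  p <- ref_params()
  bc <- ref_bc()
  st <- carrier_occupancies_at(33, 21, p, bc)
  expect_equal(sum(st), p$mpc_total, tolerance = 1e-12)
  d <- carrier_derivatives(st, 21, p, bc)
  expect_lt(max(abs(d)), 1e-9 * p$mpc_total)

  # symmetric ligands give mirror-symmetric occupancies
  bcs <- boundary_conditions(p_cyt = 50, h_cyt = 0.04, h_mit = 0.04)
  ss <- carrier_occupancies_at(50, 50, p, bcs)
  expect_equal(ss[["mpc_o"]], ss[["mpc_i"]], tolerance = 1e-10)
  expect_equal(ss[["mpc_o_h"]], ss[["mpc_i_h"]], tolerance = 1e-10)
  expect_equal(ss[["mpc_o_hp"]], ss[["mpc_i_hp"]], tolerance = 1e-10)

  # no pyruvate, no ternary complex
  s0 <- carrier_occupancies_at(0, 0, p, bc)
  expect_equal(s0[["mpc_o_hp"]], 0, tolerance = 1e-15)
  expect_equal(s0[["mpc_i_hp"]], 0, tolerance = 1e-15)

  # long clamped integration agrees componentwise to 1e-6 relative
  xi <- integrate_carrier_clamped(33, 21, p, bc)
  expect_equal(unname(as.numeric(st)), unname(as.numeric(xi)),
               tolerance = 1e-6)
})

test_that("net flux vanishes at the proton-ratio equilibrium, is antisymmetric and dose-linear", {
  p <- ref_params()
  bc <- ref_bc()
  for (po in c(1, 10, 100, 1000)) {
    peq <- equilibrium_matrix_pyruvate(po, bc)
    expect_equal(peq, po * 0.063 / 0.016)
    expect_lt(abs(net_transport_flux(po, peq, p, bc)), 1e-10)
  }
  # pH-symmetric: equilibrium at equal concentrations
  bcs <- boundary_conditions(p_cyt = 10, h_cyt = 0.05, h_mit = 0.05)
  expect_equal(equilibrium_matrix_pyruvate(10, bcs), 10)

  # antisymmetry under exchanging the membrane faces
  bc_swap <- boundary_conditions(p_cyt = 21, h_cyt = bc$h_mit,
                                 h_mit = bc$h_cyt)
  expect_equal(net_transport_flux(33, 21, p, bc),
               -net_transport_flux(21, 33, p, bc_swap), tolerance = 1e-10)

  # exact linearity in carrier dosage
  p2 <- carrier_params(mpc_total = 2 * p$mpc_total)
  expect_equal(net_transport_flux(33, 21, p2, bc),
               2 * net_transport_flux(33, 21, p, bc), tolerance = 1e-12)

  # no cis substrate: pure efflux
  expect_lt(net_transport_flux(0, 100, p, bc), 0)

  expect_error(equilibrium_matrix_pyruvate(10, boundary_conditions(
    p_cyt = 10, h_cyt = 0.05, h_mit = 0)), "positive")
})

test_that("loaded-carrier influx shows trans-acceleration and reduces to net flux at zero trans", {
  p <- ref_params()
  bc <- ref_bc()
  # at zero trans, influx exceeds net flux only by the f2/(f2 + k_off_p)
  # fraction of loaded carriers that translocate back before releasing
  expect_equal(unidirectional_influx(100, 0, p, bc),
               net_transport_flux(100, 0, p, bc), tolerance = 2e-3)
  expect_gte(unidirectional_influx(100, 0, p, bc),
             net_transport_flux(100, 0, p, bc))
  grid <- c(0, 10, 50, 100, 300, 1000)
  infl <- vapply(grid, function(pm) unidirectional_influx(100, pm, p, bc),
                 numeric(1))
  expect_true(all(diff(infl) > 0))        # f2 > f1: accelerated exchange
  expect_gt(unidirectional_influx(100, 1000, p, bc),
            unidirectional_influx(100, 0, p, bc))
  # influx bounds net flux whenever trans substrate is present
  expect_gte(unidirectional_influx(100, 50, p, bc),
             net_transport_flux(100, 50, p, bc))
})

test_that("zero-trans scan recovers the apparent Michaelis constant of the carrier", {
  zt <- fit_zero_trans_km()
  expect_equal(zt$k_zt, 150, tolerance = 0.10)
  expect_lt(zt$residual_norm, 1e-3)
  # dosage rescaling: k_zt invariant, apparent Vmax doubles
  zt2 <- fit_zero_trans_km(carrier_params(mpc_total = 2 * 3.24))
  expect_equal(zt2$k_zt, zt$k_zt, tolerance = 1e-6)
  expect_equal(zt2$v_max_app, 2 * zt$v_max_app, tolerance = 1e-6)
  expect_error(fit_zero_trans_km(grid = c(1, 10, 100)), "grid")
})

test_that("carrier and boundary constructors validate their inputs", {
  expect_error(carrier_params(k_on = -1), "positive")
  expect_error(carrier_params(mpc_total = 0), "positive")
  expect_error(boundary_conditions(p_cyt = -5), "non-negative")
  expect_error(sink_params(k_m_pdh = 0), "positive")
  # pH constructor: published rounded values at 7.2/7.8, exact power rule otherwise
  b <- boundary_conditions_from_ph()
  expect_equal(b$h_cyt, 0.063)
  expect_equal(b$h_mit, 0.016)
  b7 <- boundary_conditions_from_ph(ph_cyt = 7, ph_mit = 7)
  expect_equal(b7$h_cyt, 0.1)
})
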