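test_that("sink rates follow Michaelis-Menten kinetics with the reference constants", {
  s <- ref_sinks()
  expect_equal(pdh_rate(0, s), 0)
  expect_equal(pc_rate(0, s), 0)
  expect_equal(pdh_rate(10, s), 1.34 / 2)          # half-saturation
  expect_equal(pdh_rate(21, s), 0.91, tolerance = 0.01)
  expect_equal(pc_rate(21, s), 0.29, tolerance = 0.01)
  expect_equal(pc_rate(1e9, s), 3.3, tolerance = 1e-6)
  expect_true(all(diff(pdh_rate(seq(0, 500, by = 10), s)) > 0))
  expect_error(pdh_rate(-1, s), "non-negative")
})

test_that("whole-system steady state reproduces the reference operating point", {
  ss <- solve_system_steady_state()
  expect_equal(ss$p_mit, 21, tolerance = 0.02)
  expect_equal(ss$fluxes$j_pdh, 0.91, tolerance = 0.02)
  expect_equal(ss$fluxes$j_pc, 0.29, tolerance = 0.02)
  expect_equal(100 * ss$fluxes$pdh_fraction, 76, tolerance = 1 / 76)
  expect_equal(100 * ss$fluxes$pc_fraction, 24, tolerance = 1 / 24)
  expect_equal(ss$fluxes$j_transport, 1.2, tolerance = 0.02)
  # flux balance at the fixed point
  expect_lt(abs(ss$fluxes$j_transport - ss$fluxes$j_pdh - ss$fluxes$j_pc),
            1e-9)
  # the full derivative vector vanishes there
  d <- system_derivatives(c(as.numeric(ss$occupancies), ss$p_mit))
  expect_lt(max(abs(d)), 1e-9)
})

test_that("system derivatives match hand substitution and degenerate cases", {
  p <- ref_params(); bc <- ref_bc(); s <- ref_sinks()
  x <- c(0.5, 0.4, 0.6, 0.7, 0.04, 0.05, 15)
  d <- system_derivatives(x, p, bc, s)
  dc <- carrier_derivatives(x[1:6], x[7], p, bc)
  expect_equal(unname(d[1:6]), unname(dc))
  expect_equal(d[["p_mit"]],
               2.12e6 * 0.05 - 100 * 0.7 * 15 -
                 1.34 * 15 / 25 - 3.3 * 15 / 235)
  # empty matrix pool with no ternary complex: pool cannot move
  d0 <- system_derivatives(c(1, 1, 0.6, 0.64, 0, 0, 0), p, bc, s)
  expect_equal(d0[["p_mit"]], 0)
  expect_error(system_derivatives(rep(1, 6)), "seven")
})

test_that("root-found steady state agrees with long integration across parameter draws", {
  # default parameters
  ss <- solve_system_steady_state()
  tr <- integrate_system(initial = c(rep(3.24 / 6, 6), 0),
                         t_grid = c(0, 10^(0:4)))
  expect_equal(tr$p_mit_uM[nrow(tr)], ss$p_mit, tolerance = 1e-6)

  set.seed(7)
  for (k in 1:5) {
    f <- function(x) x * runif(1, 0.5, 1.5)     # +-50% around reference
    p <- carrier_params(mpc_total = f(3.24), k_on = f(100), k_off_h = f(20),
                        k_off_p = f(2.12e6), f1 = f(200), f2 = f(3000))
    s <- sink_params(v_max_pdh = f(1.34), k_m_pdh = f(10),
                     v_max_pc = f(3.3), k_m_pc = f(220))
    bc <- boundary_conditions(p_cyt = f(33))
    ss <- solve_system_steady_state(p, bc, s)
    tr <- integrate_system(initial = c(rep(p$mpc_total / 6, 6), 0),
                           params = p, bc = bc, sinks = s,
                           t_grid = c(0, 10^(0:4)))
    expect_equal(tr$p_mit_uM[nrow(tr)], ss$p_mit, tolerance = 1e-6)
  }
})

test_that("steady state sits below equilibrium and rises with substrate and dosage", {
  bc <- ref_bc()
  # consumption pulls the pool below thermodynamic equilibrium
  for (po in c(5, 33, 200)) {
    ss <- solve_system_steady_state(bc = boundary_conditions(p_cyt = po))
    expect_lt(ss$p_mit, equilibrium_matrix_pyruvate(po, bc))
  }
  # removing the sinks restores equilibrium exactly
  ss0 <- solve_system_steady_state(sinks = sink_params(v_max_pdh = 0,
                                                       v_max_pc = 0))
  expect_equal(ss0$p_mit, equilibrium_matrix_pyruvate(33, bc),
               tolerance = 1e-12)
  # no substrate: empty pool
  ssz <- solve_system_steady_state(bc = boundary_conditions(p_cyt = 0))
  expect_equal(ssz$p_mit, 0)
  expect_equal(ssz$fluxes$j_pdh, 0)

  # monotone in cytosolic pyruvate and in carrier dosage
  pm_po <- vapply(c(1, 10, 33, 100, 1000), function(po)
    solve_system_steady_state(bc = boundary_conditions(p_cyt = po))$p_mit,
    numeric(1))
  expect_true(all(diff(pm_po) > 0))
  pm_d <- vapply(c(0.5, 1, 2, 4), function(m)
    solve_system_steady_state(carrier_params(mpc_total = m * 3.24))$p_mit,
    numeric(1))
  expect_true(all(diff(pm_d) > 0))
})

test_that("perturbation protocols show the anaplerotic steal and its rescue", {
  ss <- solve_system_steady_state()
  # no perturbation: flat trace at the fixed point, carrier pool conserved
  tr0 <- integrate_system(t_grid = seq(0, 200, by = 1))
  expect_lt(max(abs(tr0$p_mit_uM - ss$p_mit)), 1e-6 * ss$p_mit)
  tot <- rowSums(tr0[, c("mpc_o", "mpc_i", "mpc_o_h", "mpc_i_h",
                         "mpc_o_hp", "mpc_i_hp")])
  expect_lt(max(abs(tot - 3.24)), 1e-9 * 3.24)

  # doubling PDH capacity depletes the pool and steals PC flux
  sch1 <- perturbation_schedule(100, list(c(v_max_pdh = 2)))
  tr1 <- integrate_system(schedule = sch1, t_grid = seq(0, 500, by = 1))
  end1 <- tr1[nrow(tr1), ]
  expect_lt(end1$p_mit_uM, ss$p_mit)
  expect_lt(end1$j_pc, ss$fluxes$j_pc)

  # doubling PDH and the carrier together sustains PDH with less PC loss
  sch2 <- perturbation_schedule(100, list(c(v_max_pdh = 2, mpc_total = 2)))
  tr2 <- integrate_system(schedule = sch2, t_grid = seq(0, 500, by = 1))
  end2 <- tr2[nrow(tr2), ]
  expect_gt(end2$j_pdh, ss$fluxes$j_pdh)
  expect_lt(abs(end2$j_pc - ss$fluxes$j_pc),
            abs(end1$j_pc - ss$fluxes$j_pc))

  expect_error(perturbation_schedule(c(10, 5), list(c(p_cyt = 1),
                                                    c(p_cyt = 2))),
               "increasing")
  expect_error(perturbation_schedule(10, list(c(bogus = 2))), "named")
})
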