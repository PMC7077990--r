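# Shared fixtures: the reference parameter set and small utilities.

ref_params <- function() carrier_params()
ref_bc <- function(p_cyt = 33) boundary_conditions(p_cyt = p_cyt)
ref_sinks <- function() sink_params()

# Long clamped-carrier integration: independent oracle for the linear
# occupancy solve (integrates the six carrier ODEs with p_mit held fixed).
integrate_carrier_clamped <- function(p_cyt, p_mit, params, bc, t_end = 10) {
  bc2 <- bc
  bc2$p_cyt <- p_cyt
  y0 <- rep(params$mpc_total / 6, 6)
  names(y0) <- c("mpc_o", "mpc_i", "mpc_o_h", "mpc_i_h", "mpc_o_hp",
                 "mpc_i_hp")
  f <- function(t, y, parms)
    list(as.numeric(carrier_derivatives(pmax(y, 0), p_mit, params, bc2)))
  sol <- deSolve::lsoda(y0, c(0, t_end), f, parms = NULL,
                        rtol = 1e-11, atol = 1e-13)
  sol[nrow(sol), -1]
}

# Dense noiseless matrix-pyruvate trace around a partial transporter block,
# straight from the model (no sensor, no noise): ODE oracle for the
# stop-protocol estimators.
dense_stop_trace <- function(inhibition = 0.69, params = ref_params(),
                             bc = ref_bc(), sinks = ref_sinks(),
                             t_block = 300, t_end = 600, dt = 0.1) {
  sch <- perturbation_schedule(times = t_block,
                               multipliers = list(c(mpc_total = 1 - inhibition)))
  tr <- integrate_system(schedule = sch, params = params, bc = bc,
                         sinks = sinks, t_grid = seq(0, t_end, by = dt))
  time_course(tr$time_s, pmax(tr$p_mit_uM, 0), channel = "concentration")
}
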