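#' Michaelis-Menten rates of the matrix pyruvate sinks
#'
#' Saturable consumption of matrix pyruvate by pyruvate dehydrogenase
#' (`pdh_rate`) and pyruvate carboxylase (`pc_rate`):
#' `v_max * p / (k_m + p)`. Vectorized over `p_mit`.
#'
#' @param p_mit matrix pyruvate, uM (vectorized).
#' @param sinks [sink_params()].
#' @return Consumption rate, uM/s.
#' @export
pdh_rate <- function(p_mit, sinks = sink_params()) {
  if (any(!is.finite(p_mit)) || any(p_mit < 0))
    stop("pdh_rate: 'p_mit' must be non-negative", call. = FALSE)
  sinks$v_max_pdh * p_mit / (sinks$k_m_pdh + p_mit)
}

#' @rdname pdh_rate
#' @export
pc_rate <- function(p_mit, sinks = sink_params()) {
  if (any(!is.finite(p_mit)) || any(p_mit < 0))
    stop("pc_rate: 'p_mit' must be non-negative", call. = FALSE)
  sinks$v_max_pc * p_mit / (sinks$k_m_pc + p_mit)
}

#' Time derivatives of the coupled carrier-sink system
#'
#' The seven-dimensional system: six carrier occupancies plus matrix
#' pyruvate. The carrier part follows [carrier_derivatives()]; matrix
#' pyruvate obeys
#' `dP_i/dt = k_off_p * [MPC_iHP] - k_on * [MPC_iH] * P_i - PDH - PC`.
#' Cytosolic pyruvate and both proton concentrations are clamped.
#'
#' @param state numeric vector of length 7: the six carrier states followed
#'   by `p_mit` (uM).
#' @param params [carrier_params()].
#' @param bc [boundary_conditions()].
#' @param sinks [sink_params()].
#' @return Named numeric vector of seven derivatives, uM/s.
#' @export
system_derivatives <- function(state, params = carrier_params(),
                               bc = boundary_conditions(),
                               sinks = sink_params()) {
  state <- as.numeric(state)
  if (length(state) != 7L || any(!is.finite(state)) || any(state < 0))
    stop("system_derivatives: 'state' must be seven finite non-negative values",
         call. = FALSE)
  carrier <- state[1:6]
  p_mit <- state[7]
  dc <- carrier_derivatives(carrier, p_mit, params, bc)
  dp <- params$k_off_p * carrier[6] - params$k_on * carrier[4] * p_mit -
    pdh_rate(p_mit, sinks) - pc_rate(p_mit, sinks)
  c(dc, p_mit = dp)
}

# Unvalidated right-hand side for the integrator. The solver may probe
# slightly negative states near zero crossings; the polynomial/MM right-hand
# side extrapolates smoothly there, and clamping inside the RHS would create
# non-smooth chatter that collapses the step size.
.system_rhs <- function(state, params, bc, sinks) {
  p_mit <- state[7]
  A <- .carrier_rate_matrix(bc$p_cyt, p_mit, params, bc)
  dc <- drop(A %*% state[1:6])
  dp <- params$k_off_p * state[6] - params$k_on * state[4] * p_mit -
    sinks$v_max_pdh * p_mit / (sinks$k_m_pdh + p_mit) -
    sinks$v_max_pc * p_mit / (sinks$k_m_pc + p_mit)
  c(dc, dp)
}

# Analytic Jacobian of the seven-state system (used by the stiff solver:
# the fast binding modes have eigenvalues ~ k_off_p, 1e5-fold faster than
# the pyruvate pool, and BDF steps need the exact linearization).
.system_jacobian <- function(state, params, bc, sinks) {
  p <- state[7]
  J <- matrix(0, 7, 7)
  J[1:6, 1:6] <- .carrier_rate_matrix(bc$p_cyt, p, params, bc)
  J[4, 7] <- -params$k_on * state[4]
  J[6, 7] <- params$k_on * state[4]
  J[7, 4] <- -params$k_on * p
  J[7, 6] <- params$k_off_p
  J[7, 7] <- -params$k_on * state[4] -
    sinks$v_max_pdh * sinks$k_m_pdh / (sinks$k_m_pdh + p)^2 -
    sinks$v_max_pc * sinks$k_m_pc / (sinks$k_m_pc + p)^2
  J
}

# Flux breakdown at a given matrix pyruvate (steady-state bookkeeping).
.flux_breakdown <- function(p_mit, p_cyt, params, bc, sinks) {
  j_pdh <- pdh_rate(p_mit, sinks)
  j_pc <- pc_rate(p_mit, sinks)
  j_tr <- net_transport_flux(p_cyt, p_mit, params, bc)
  tot <- j_pdh + j_pc
  structure(list(j_transport = j_tr, j_pdh = j_pdh, j_pc = j_pc,
                 pdh_fraction = if (tot > 0) j_pdh / tot else NA_real_,
                 pc_fraction = if (tot > 0) j_pc / tot else NA_real_),
            class = "flux_breakdown")
}

#' @export
print.flux_breakdown <- function(x, ...) {
  cat(sprintf("Fluxes (uM/s): transport %.4g, PDH %.4g (%.1f%%), PC %.4g (%.1f%%)\n",
              x$j_transport, x$j_pdh, 100 * x$pdh_fraction,
              x$j_pc, 100 * x$pc_fraction))
  invisible(x)
}

#' Whole-system steady state of the coupled carrier-sink model
#'
#' Finds the matrix pyruvate concentration at which net carrier transport
#' balances total sink consumption, by bracketed one-dimensional root finding
#' on `[0, equilibrium_matrix_pyruvate(p_cyt)]`. The upper bracket is the
#' thermodynamic equilibrium, where net flux is zero while consumption is
#' positive, so a sign change is guaranteed whenever any sink is active.
#' With the published parameters and cytosolic pyruvate 33 uM the steady
#' state is ~21 uM matrix pyruvate with PDH/PC fluxes 0.91/0.29 uM/s
#' (76%/24% of a 1.2 uM/s total).
#'
#' @param params [carrier_params()].
#' @param bc [boundary_conditions()] (supplies clamped `p_cyt`).
#' @param sinks [sink_params()].
#' @param tol absolute tolerance on matrix pyruvate for the root find, uM.
#' @return List of class `system_steady_state`: `p_mit` (uM), `fluxes`
#'   (a `flux_breakdown`), and `occupancies` (a `carrier_state`).
#' @export
solve_system_steady_state <- function(params = carrier_params(),
                                      bc = boundary_conditions(),
                                      sinks = sink_params(),
                                      tol = 1e-12) {
  p_cyt <- bc$p_cyt
  p_eq <- equilibrium_matrix_pyruvate(p_cyt, bc)
  if (p_eq == 0) {                       # no substrate: trivial steady state
    occ <- carrier_occupancies_at(p_cyt, 0, params, bc)
    return(structure(list(p_mit = 0,
                          fluxes = .flux_breakdown(0, p_cyt, params, bc, sinks),
                          occupancies = occ),
                     class = "system_steady_state"))
  }
  imbalance <- function(p)
    net_transport_flux(p_cyt, p, params, bc) -
      pdh_rate(p, sinks) - pc_rate(p, sinks)
  total_vmax <- sinks$v_max_pdh + sinks$v_max_pc
  if (total_vmax == 0) {                 # no sinks: equilibrium exactly
    occ <- carrier_occupancies_at(p_cyt, p_eq, params, bc)
    return(structure(list(p_mit = p_eq,
                          fluxes = .flux_breakdown(p_eq, p_cyt, params, bc, sinks),
                          occupancies = occ),
                     class = "system_steady_state"))
  }
  lo <- p_eq * 1e-12
  if (imbalance(lo) <= 0 || imbalance(p_eq) >= 0)
    stop("solve_system_steady_state: no sign change in bracket; model inconsistency",
         call. = FALSE)
  root <- stats::uniroot(imbalance, c(lo, p_eq), tol = tol)$root
  structure(list(p_mit = root,
                 fluxes = .flux_breakdown(root, p_cyt, params, bc, sinks),
                 occupancies = carrier_occupancies_at(p_cyt, root, params, bc)),
            class = "system_steady_state")
}

#' @export
print.system_steady_state <- function(x, ...) {
  cat(sprintf("Steady state: matrix pyruvate %.4g uM\n", x$p_mit))
  print(x$fluxes)
  invisible(x)
}

#' Build a perturbation schedule
#'
#' An ordered set of step perturbations applied during [integrate_system()].
#' Each row scales one or more quantities from its time onward (multipliers
#' compose with the baseline values, not with each other): `mpc_total`,
#' `v_max_pdh`, `v_max_pc` (dosage/activity scaling) or `p_cyt` (boundary
#' step). A multiplier of 2 on `v_max_pdh` is "PDH activation by 100%"; a
#' multiplier of `1 - i` on `mpc_total` represents partial transporter block
#' with inhibited fraction `i`.
#'
#' @param times numeric vector of event times, s (strictly increasing).
#' @param multipliers list (one element per time) of named numeric vectors;
#'   names among `mpc_total`, `v_max_pdh`, `v_max_pc`, `p_cyt`; values >= 0.
#' @return Object of class `perturbation_schedule`.
#' @examples
#' perturbation_schedule(times = 100, multipliers = list(c(v_max_pdh = 2)))
#' @export
perturbation_schedule <- function(times = numeric(), multipliers = list()) {
  if (length(times) != length(multipliers))
    stop("perturbation_schedule: one multiplier set per time", call. = FALSE)
  if (length(times) && (any(diff(times) <= 0) || any(!is.finite(times))))
    stop("perturbation_schedule: times must be finite and strictly increasing",
         call. = FALSE)
  ok <- c("mpc_total", "v_max_pdh", "v_max_pc", "p_cyt")
  for (m in multipliers) {
    if (is.null(names(m)) || !all(names(m) %in% ok) || any(m < 0))
      stop("perturbation_schedule: multipliers must be named among ",
           paste(ok, collapse = ", "), " and non-negative", call. = FALSE)
  }
  structure(list(times = as.numeric(times), multipliers = multipliers),
            class = "perturbation_schedule")
}

# Apply a multiplier set (relative to baseline) to the parameter objects.
.apply_multipliers <- function(m, params, bc, sinks) {
  p <- params; b <- bc; s <- sinks
  if ("mpc_total" %in% names(m)) p$mpc_total <- params$mpc_total * m[["mpc_total"]]
  if ("v_max_pdh" %in% names(m)) s$v_max_pdh <- sinks$v_max_pdh * m[["v_max_pdh"]]
  if ("v_max_pc" %in% names(m))  s$v_max_pc <- sinks$v_max_pc * m[["v_max_pc"]]
  if ("p_cyt" %in% names(m))     b$p_cyt <- bc$p_cyt * m[["p_cyt"]]
  list(params = p, bc = b, sinks = s)
}

#' Integrate the coupled system under a perturbation protocol
#'
#' Stiff integration of the seven-state system (deSolve `lsoda`; the rate
#' constants span 20 to 2.12e6 s^-1, a stiffness ratio of ~1e5, so an
#' implicit method is required). Multipliers from the schedule are applied
#' piecewise: integration restarts at each event time with scaled
#' parameters. Dosage rescaling redistributes the carrier proportionally so
#' conservation holds at the new total.
#'
#' @param initial either a `system_steady_state`, or a numeric vector of
#'   length 7 (six carrier occupancies then `p_mit`), or `NULL` to start at
#'   the baseline steady state.
#' @param params,bc,sinks baseline model parameters.
#' @param schedule [perturbation_schedule()].
#' @param t_grid output time grid, s (increasing, from 0).
#' @param rtol,atol integrator tolerances (uM for `atol`).
#' @return A data.frame of class `system_trace` with columns `time_s`,
#'   `p_mit_uM`, `j_transport`, `j_pdh`, `j_pc`, the six carrier occupancies,
#'   and attribute `schedule`.
#' @export
integrate_system <- function(initial = NULL, params = carrier_params(),
                             bc = boundary_conditions(),
                             sinks = sink_params(),
                             schedule = perturbation_schedule(),
                             t_grid = seq(0, 600, by = 1),
                             rtol = 1e-8, atol = 1e-12) {
  if (any(diff(t_grid) <= 0))
    stop("integrate_system: 't_grid' must be strictly increasing", call. = FALSE)
  if (length(schedule$times) &&
      (min(schedule$times) < min(t_grid) || max(schedule$times) > max(t_grid)))
    stop("integrate_system: schedule times must lie within 't_grid'",
         call. = FALSE)
  if (is.null(initial))
    initial <- solve_system_steady_state(params, bc, sinks)
  y <- if (inherits(initial, "system_steady_state"))
    c(as.numeric(initial$occupancies), initial$p_mit)
  else as.numeric(initial)
  if (length(y) != 7L)
    stop("integrate_system: 'initial' must have 7 states", call. = FALSE)
  names(y) <- c(.carrier_state_names, "p_mit")

  # segment boundaries: t_grid start, event times, t_grid end
  ev <- schedule$times
  bounds <- unique(c(min(t_grid), ev, max(t_grid)))
  active <- list(params = params, bc = bc, sinks = sinks)

  rows <- NULL
  for (k in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1L]
    idx <- match(t0, ev)
    if (!is.na(idx))
      active <- .apply_multipliers(schedule$multipliers[[idx]], params, bc, sinks)
    if (!is.na(idx) && "mpc_total" %in% names(schedule$multipliers[[idx]])) {
      tot <- sum(y[1:6])               # rescale carrier pool to the new total
      if (tot > 0) y[1:6] <- y[1:6] * active$params$mpc_total / tot
    }
    tt <- sort(unique(c(t0, t_grid[t_grid > t0 & t_grid < t1], t1)))
    deriv <- function(t, state, parms)
      list(.system_rhs(state, active$params, active$bc, active$sinks))
    jac <- function(t, state, parms)
      .system_jacobian(state, active$params, active$bc, active$sinks)
    # integrate in segment-local time: the solver's step heuristics are
    # better behaved starting from 0 than from a large absolute time
    sol <- suppressWarnings(
      deSolve::lsoda(y, tt - t0, deriv, parms = NULL, jacfunc = jac,
                     jactype = "fullusr", rtol = rtol, atol = atol,
                     maxsteps = 50000))
    if (attr(sol, "istate")[1] < 0) {
      # rare lsoda stalls on this stiffness ratio: retry with radau
      sol <- deSolve::radau(y, tt - t0, deriv, parms = NULL, jacfunc = jac,
                            jactype = "fullusr", rtol = rtol, atol = atol,
                            maxsteps = 50000)
      if (attr(sol, "istate")[1] < 0)
        stop("integrate_system: integrator failure in segment ", k,
             call. = FALSE)
    }
    seg <- as.data.frame(sol)
    names(seg)[1] <- "time_s"
    seg$time_s <- tt
    # report each grid point once: the segment owns [t0, t1), last owns t1 too,
    # so an event-time grid point is reported with post-event parameters
    keep <- seg$time_s %in% t_grid &
      (seg$time_s < t1 | k == length(bounds) - 1L)
    if (any(keep)) {
      pm <- pmax(seg$p_mit[keep], 0)
      rows <- rbind(rows, cbind(
        seg[keep, , drop = FALSE],
        j_pdh = pdh_rate(pm, active$sinks),
        j_pc = pc_rate(pm, active$sinks),
        j_transport = active$params$k_off_p * seg$mpc_i_hp[keep] -
          active$params$k_on * seg$mpc_i_h[keep] * pm))
    }
    y <- pmax(unlist(seg[nrow(seg), -1]), 0)
  }
  out <- rows[, c("time_s", "p_mit", "j_transport", "j_pdh", "j_pc",
                  .carrier_state_names)]
  names(out)[2] <- "p_mit_uM"
  rownames(out) <- NULL
  attr(out, "schedule") <- schedule
  class(out) <- c("system_trace", "data.frame")
  out
}
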