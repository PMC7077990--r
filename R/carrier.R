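#' Construct a carrier state vector
#'
#' The six conformations of the carrier, in fixed order: outward-facing and
#' inward-facing, each empty (`mpc_o`, `mpc_i`), proton-loaded (`mpc_o_h`,
#' `mpc_i_h`), or proton+pyruvate-loaded (`mpc_o_hp`, `mpc_i_hp`).
#' Concentrations in uM.
#'
#' @param mpc_o,mpc_i,mpc_o_h,mpc_i_h,mpc_o_hp,mpc_i_hp state occupancies, uM.
#' @return Named numeric vector of length 6, class `carrier_state`.
#' @export
carrier_state <- function(mpc_o, mpc_i, mpc_o_h, mpc_i_h, mpc_o_hp, mpc_i_hp) {
  x <- c(mpc_o = mpc_o, mpc_i = mpc_i, mpc_o_h = mpc_o_h,
         mpc_i_h = mpc_i_h, mpc_o_hp = mpc_o_hp, mpc_i_hp = mpc_i_hp)
  if (any(!is.finite(x)) || any(x < 0))
    stop("carrier_state: occupancies must be finite and non-negative",
         call. = FALSE)
  structure(x, class = c("carrier_state", "numeric"))
}

.carrier_state_names <- c("mpc_o", "mpc_i", "mpc_o_h",
                          "mpc_i_h", "mpc_o_hp", "mpc_i_hp")

# Rate matrix of the carrier subsystem at clamped ligand concentrations.
# State order as .carrier_state_names; dx/dt = A %*% x.
.carrier_rate_matrix <- function(p_cyt, p_mit, params, bc) {
  kon <- params$k_on; koffh <- params$k_off_h; koffp <- params$k_off_p
  f1 <- params$f1; f2 <- params$f2
  ho <- bc$h_cyt; hi <- bc$h_mit
  A <- matrix(0, 6, 6, dimnames = list(.carrier_state_names,
                                       .carrier_state_names))
  # d[MPC_o]   = koffh*MPC_oH + f1*MPC_i - kon*MPC_o*H_o - f1*MPC_o
  A[1, ] <- c(-kon * ho - f1, f1, koffh, 0, 0, 0)
  # d[MPC_i]   = koffh*MPC_iH + f1*MPC_o - kon*MPC_i*H_i - f1*MPC_i
  A[2, ] <- c(f1, -kon * hi - f1, 0, koffh, 0, 0)
  # d[MPC_oH]  = kon*MPC_o*H_o + koffp*MPC_oHP - koffh*MPC_oH - kon*MPC_oH*P_o
  A[3, ] <- c(kon * ho, 0, -koffh - kon * p_cyt, 0, koffp, 0)
  # d[MPC_iH]  = kon*MPC_i*H_i + koffp*MPC_iHP - koffh*MPC_iH - kon*MPC_iH*P_i
  A[4, ] <- c(0, kon * hi, 0, -koffh - kon * p_mit, 0, koffp)
  # d[MPC_oHP] = kon*MPC_oH*P_o + f2*MPC_iHP - koffp*MPC_oHP - f2*MPC_oHP
  A[5, ] <- c(0, 0, kon * p_cyt, 0, -koffp - f2, f2)
  # d[MPC_iHP] = kon*MPC_iH*P_i + f2*MPC_oHP - koffp*MPC_iHP - f2*MPC_iHP
  A[6, ] <- c(0, 0, 0, kon * p_mit, f2, -koffp - f2)
  A
}

#' Time derivatives of the six carrier states
#'
#' Evaluates the carrier rate equations at clamped ligand concentrations:
#' ordered binding (proton first, then pyruvate), empty-carrier translocation
#' at `f1`, loaded-carrier translocation at `f2`, proton-only forms immobile.
#' The six derivatives always sum to zero (carrier conservation).
#'
#' @param state named numeric vector of the six occupancies (uM), in the
#'   order produced by [carrier_state()].
#' @param p_mit matrix pyruvate, uM.
#' @param params [carrier_params()].
#' @param bc [boundary_conditions()] (supplies `p_cyt`, `h_cyt`, `h_mit`).
#' @return Named numeric vector of six time derivatives, uM/s.
#' @export
carrier_derivatives <- function(state, p_mit, params = carrier_params(),
                                bc = boundary_conditions()) {
  state <- as.numeric(state)
  if (length(state) != 6L || any(!is.finite(state)) || any(state < 0))
    stop("carrier_derivatives: 'state' must be six finite non-negative values",
         call. = FALSE)
  if (!is.finite(p_mit) || p_mit < 0)
    stop("carrier_derivatives: 'p_mit' must be non-negative", call. = FALSE)
  A <- .carrier_rate_matrix(bc$p_cyt, p_mit, params, bc)
  d <- drop(A %*% state)
  names(d) <- .carrier_state_names
  d
}

#' Carrier-occupancy steady state at clamped ligand concentrations
#'
#' Solves the six-state linear system for the stationary occupancy
#' distribution given clamped pyruvate and proton concentrations on both
#' sides: the rate equations with one row replaced by the conservation
#' constraint (sum of states = `mpc_total`). Exact up to linear-solver
#' round-off; cross-validated against long stiff integration in the test
#' suite.
#'
#' @param p_cyt cytosolic pyruvate, uM (overrides `bc$p_cyt`).
#' @param p_mit matrix pyruvate, uM.
#' @inheritParams carrier_derivatives
#' @return A `carrier_state` vector summing to `params$mpc_total`.
#' @export
carrier_occupancies_at <- function(p_cyt, p_mit, params = carrier_params(),
                                   bc = boundary_conditions()) {
  if (!is.finite(p_cyt) || p_cyt < 0 || !is.finite(p_mit) || p_mit < 0)
    stop("carrier_occupancies_at: ligand concentrations must be non-negative",
         call. = FALSE)
  A <- .carrier_rate_matrix(p_cyt, p_mit, params, bc)
  A[6, ] <- 1                      # conservation row replaces one rate equation
  b <- c(rep(0, 5), params$mpc_total)
  x <- tryCatch(solve(A, b), error = function(e)
    stop("carrier_occupancies_at: singular carrier system (", conditionMessage(e),
         ")", call. = FALSE))
  names(x) <- .carrier_state_names
  structure(x, class = c("carrier_state", "numeric"))
}

#' Net carrier-mediated pyruvate flux into the matrix
#'
#' Net delivery of pyruvate to the matrix at the carrier-occupancy steady
#' state: `k_off_p * [MPC_iHP] - k_on * [MPC_iH] * p_mit` (uM/s, positive =
#' influx). Antisymmetric under exchange of the two membrane faces, zero at
#' the proton-coupled equilibrium `p_cyt * h_cyt = p_mit * h_mit`, and
#' exactly linear in carrier dosage.
#'
#' @inheritParams carrier_occupancies_at
#' @return Net flux, uM/s.
#' @export
net_transport_flux <- function(p_cyt, p_mit, params = carrier_params(),
                               bc = boundary_conditions()) {
  x <- carrier_occupancies_at(p_cyt, p_mit, params, bc)
  params$k_off_p * x[["mpc_i_hp"]] - params$k_on * x[["mpc_i_h"]] * p_mit
}

#' Unidirectional influx (loaded-carrier inward translocation rate)
#'
#' The one-way inward flux `f2 * [MPC_oHP]` at the occupancy steady state:
#' inward translocation events of the fully loaded carrier per unit time.
#' Because the loaded carrier translocates faster than the empty one
#' (`f2 > f1` in the published set), influx at fixed cytosolic pyruvate
#' increases with trans-side (matrix) pyruvate: accelerated exchange.
#' At zero trans substrate the unidirectional influx exceeds the net flux
#' only by the small fraction `f2 / (f2 + k_off_p)` of loaded carriers that
#' translocate back before releasing their pyruvate (~0.14% with the
#' published rates).
#'
#' @inheritParams carrier_occupancies_at
#' @return Unidirectional influx, uM/s.
#' @export
unidirectional_influx <- function(p_cyt, p_mit, params = carrier_params(),
                                  bc = boundary_conditions()) {
  x <- carrier_occupancies_at(p_cyt, p_mit, params, bc)
  params$f2 * x[["mpc_o_hp"]]
}

#' Matrix pyruvate at thermodynamic equilibrium of the symporter
#'
#' For a 1:1 proton-pyruvate symporter with side-symmetric rate constants the
#' net flux vanishes when the chemical products match:
#' `p_mit = p_cyt * h_cyt / h_mit`. With the physiological ~4-fold proton
#' gradient (pH 7.2/7.8) equilibrium matrix pyruvate is ~3.9x cytosolic.
#'
#' @param p_cyt cytosolic pyruvate, uM.
#' @param bc [boundary_conditions()].
#' @return Equilibrium matrix pyruvate, uM.
#' @export
equilibrium_matrix_pyruvate <- function(p_cyt, bc = boundary_conditions()) {
  if (bc$h_mit <= 0)
    stop("equilibrium_matrix_pyruvate: h_mit must be positive", call. = FALSE)
  p_cyt * bc$h_cyt / bc$h_mit
}

#' Apparent zero-trans kinetics of the carrier
#'
#' Measures carrier influx with matrix pyruvate clamped at zero over a grid
#' of cytosolic pyruvate concentrations and fits a rectangular hyperbola
#' `V * S / (K + S)` by unweighted nonlinear least squares. The published
#' carrier parameters yield an apparent zero-trans Michaelis constant (K_zt)
#' of ~150 uM, far above the cytosolic pyruvate concentration, so transport
#' operates in its quasi-linear range. The exact flux curve is not itself a
#' hyperbola; `k_zt` is protocol-dependent in the same way the experimental
#' quantity is.
#'
#' @param params [carrier_params()].
#' @param bc [boundary_conditions()] (only the proton terms are used).
#' @param grid cytosolic pyruvate grid, uM; default 40 log-spaced points
#'   spanning 1 to 1e4.
#' @return List of class `transport_kinetics` with elements `k_zt` (uM),
#'   `v_max_app` (uM/s), `residual_norm` (RMS residual as a fraction of
#'   `v_max_app`), `grid`, `flux`, and the `fit` object.
#' @export
fit_zero_trans_km <- function(params = carrier_params(),
                              bc = boundary_conditions(),
                              grid = 10^seq(0, 4, length.out = 40)) {
  if (length(grid) < 10L || min(grid) > 1 || max(grid) < 5000)
    stop("fit_zero_trans_km: grid must have >= 10 points spanning at least 1-5000 uM",
         call. = FALSE)
  v <- vapply(grid, function(s) net_transport_flux(s, 0, params, bc),
              numeric(1))
  df <- data.frame(s = grid, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ V * s / (K + s), data = df,
                      start = list(V = max(v), K = stats::median(grid))),
    error = function(e)
      stop("fit_zero_trans_km: hyperbola fit failed to converge (",
           conditionMessage(e), ")", call. = FALSE))
  co <- stats::coef(fit)
  structure(list(k_zt = unname(co["K"]), v_max_app = unname(co["V"]),
                 residual_norm = sqrt(mean(stats::resid(fit)^2)) / co[["V"]],
                 grid = grid, flux = v, fit = fit),
            class = "transport_kinetics")
}

#' @export
print.transport_kinetics <- function(x, ...) {
  cat(sprintf("Zero-trans kinetics: K_zt %.4g uM, apparent Vmax %.4g uM/s (RMS resid %.2g of Vmax)\n",
              x$k_zt, x$v_max_app, x$residual_norm))
  invisible(x)
}
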