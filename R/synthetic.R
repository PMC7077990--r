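# Run code under a fixed seed, restoring the caller's RNG state afterwards.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Deterministic child seeds derived from one master seed.
.child_seeds <- function(master_seed, n)
  .with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))

#' Define a segmented experiment protocol
#'
#' A protocol is a contiguous sequence of named segments, each starting at
#' `t_start` (seconds) and running to the next segment's start (the last one
#' to `t_end`). Per segment, `p_cyt` sets the clamped cytosolic pyruvate
#' (uM; `NA` keeps the baseline value) and `inhibition` is the fraction of
#' carrier activity blocked in that segment (applied as a `1 - inhibition`
#' multiplier on total carrier dosage, modeling fast, occupancy-level
#' transporter block).
#'
#' @param segments data.frame with columns `name`, `t_start`, `p_cyt`,
#'   `inhibition`.
#' @param t_end end of the experiment, s.
#' @return Object of class `experiment_protocol`.
#' @seealso [default_protocol()] for the shipped presets.
#' @export
experiment_protocol <- function(segments, t_end) {
  req <- c("name", "t_start", "p_cyt", "inhibition")
  if (!is.data.frame(segments) || !all(req %in% names(segments)))
    stop("experiment_protocol: 'segments' needs columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (nrow(segments) < 1L || any(diff(segments$t_start) <= 0))
    stop("experiment_protocol: segment starts must be strictly increasing",
         call. = FALSE)
  if (t_end <= max(segments$t_start))
    stop("experiment_protocol: 't_end' must exceed the last segment start",
         call. = FALSE)
  if (any(segments$inhibition < 0 | segments$inhibition > 1, na.rm = TRUE))
    stop("experiment_protocol: 'inhibition' must lie in [0, 1]", call. = FALSE)
  segments$inhibition[is.na(segments$inhibition)] <- 0
  structure(list(segments = segments, t_end = t_end),
            class = "experiment_protocol")
}

#' @export
print.experiment_protocol <- function(x, ...) {
  cat(sprintf("Experiment protocol (%d segments, %g s total):\n",
              nrow(x$segments), x$t_end))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Shipped experiment protocols
#'
#' Presets mirroring the standard experimental designs:
#' \describe{
#'   \item{`"stop"`}{forced-zero calibration segment (p_cyt 0, 0-120 s),
#'     baseline superfusion (p_cyt 33 uM, 120-420 s), then a partial
#'     transporter block (inhibition 0.69) for 300 s: the transporter-stop
#'     flux protocol with its calibration anchor.}
#'   \item{`"uptake"`}{pyruvate-free baseline (0-60 s) followed by a
#'     cytosolic pyruvate step to 300 uM: the uptake/initial-rate design.}
#'   \item{`"calibration"`}{physiological baseline (33 uM, 0-120 s), forced
#'     zero by lactate exchange (120-300 s), then a saturating 10 mM
#'     pyruvate load (300-480 s): the one-point-calibration design.}
#'   \item{`"pulse3x"`}{three 30-s partial blocks (inhibition 0.69) from a
#'     33 uM baseline, with 120-s recoveries: the repeated-pulse design.}
#' }
#' The same presets ship as YAML under `inst/extdata/protocols/` and can be
#' loaded with [read_protocol_yaml()].
#'
#' @param name preset name.
#' @return An [experiment_protocol()].
#' @export
default_protocol <- function(name = c("stop", "uptake", "calibration",
                                      "pulse3x")) {
  name <- match.arg(name)
  seg <- function(...) data.frame(...)
  switch(name,
    stop = experiment_protocol(seg(
      name = c("forced_zero", "baseline", "block"),
      t_start = c(0, 120, 420), p_cyt = c(0, 33, 33),
      inhibition = c(0, 0, 0.69)), t_end = 720),
    uptake = experiment_protocol(seg(
      name = c("zero", "substrate_step"),
      t_start = c(0, 60), p_cyt = c(0, 300),
      inhibition = c(0, 0)), t_end = 420),
    calibration = experiment_protocol(seg(
      name = c("baseline", "forced_zero", "saturating"),
      t_start = c(0, 120, 300), p_cyt = c(33, 0, 10000),
      inhibition = c(0, 0, 0)), t_end = 480),
    pulse3x = experiment_protocol(seg(
      name = c("baseline", "block1", "recover1", "block2", "recover2",
               "block3", "recover3"),
      t_start = c(0, 120, 150, 270, 300, 420, 450),
      p_cyt = rep(33, 7),
      inhibition = c(0, 0.69, 0, 0.69, 0, 0.69, 0)), t_end = 570))
}

#' Read a protocol from YAML
#'
#' @param path YAML file with keys `t_end` and `segments` (a list of maps
#'   with `name`, `t_start`, `p_cyt`, `inhibition`).
#' @return An [experiment_protocol()].
#' @export
read_protocol_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  segs <- do.call(rbind, lapply(raw$segments, function(s)
    data.frame(name = s$name, t_start = s$t_start,
               p_cyt = if (is.null(s$p_cyt)) NA_real_ else s$p_cyt,
               inhibition = if (is.null(s$inhibition)) 0 else s$inhibition)))
  experiment_protocol(segs, t_end = raw$t_end)
}

# Simulate the deterministic model trajectory of one protocol.
# Returns time grid, p_mit(t), fluxes, and the initial steady state.
.simulate_protocol <- function(protocol, params, bc, sinks, dt) {
  segs <- protocol$segments
  t_grid <- seq(0, protocol$t_end, by = dt)
  bc0 <- bc
  if (!is.na(segs$p_cyt[1])) bc0$p_cyt <- segs$p_cyt[1]
  par0 <- params
  par0$mpc_total <- params$mpc_total * (1 - segs$inhibition[1])
  ss0 <- solve_system_steady_state(par0, bc0, sinks)
  state <- c(as.numeric(ss0$occupancies), ss0$p_mit)

  out <- NULL
  for (k in seq_len(nrow(segs))) {
    t0 <- segs$t_start[k]
    t1 <- if (k < nrow(segs)) segs$t_start[k + 1] else protocol$t_end
    bck <- bc
    if (!is.na(segs$p_cyt[k])) bck$p_cyt <- segs$p_cyt[k]
    park <- params
    park$mpc_total <- params$mpc_total * (1 - segs$inhibition[k])
    # keep the carrier pool consistent with the segment's dosage
    tot <- sum(state[1:6])
    if (tot > 0) state[1:6] <- state[1:6] * park$mpc_total / tot
    tt <- sort(unique(c(t0, t_grid[t_grid > t0 & t_grid < t1], t1)))
    tr <- integrate_system(initial = state, params = park, bc = bck,
                           sinks = sinks, t_grid = tt)
    keep <- tr$time_s %in% t_grid & (tr$time_s < t1 | k == nrow(segs))
    out <- rbind(out, tr[keep, c("time_s", "p_mit_uM", "j_transport",
                                 "j_pdh", "j_pc")])
    last <- tr[nrow(tr), ]
    state <- pmax(as.numeric(last[c(.carrier_state_names, "p_mit_uM")]), 0)
  }
  rownames(out) <- NULL
  list(trace = out, initial_steady_state = ss0)
}

#' Generate one synthetic single-cell fluorescence experiment
#'
#' Composes the mechanistic model with the sensor model: integrates the
#' coupled carrier-sink system through the protocol segments, maps matrix
#' pyruvate through the sensor hyperbola to a fluorescence trace
#' (`F = f_zero * (1 + df_max * p / (k_d + p))`), optionally applies a
#' common-mode multiplicative drift to emulate a pH transient (affecting
#' the isosbestic channel identically), and adds seeded Gaussian noise with
#' standard deviation `noise_sd * f_zero` per channel. The full ground
#' truth (matrix pyruvate, fluxes, parameters, consumption at block time)
#' travels with the data, so estimation pipelines can be scored by
#' parameter recovery.
#'
#' @param protocol [experiment_protocol()].
#' @param params,bc,sinks model parameters ([carrier_params()],
#'   [boundary_conditions()], [sink_params()]).
#' @param sensor [sensor_params()].
#' @param noise_sd noise standard deviation as a fraction of baseline
#'   fluorescence (default 0.02).
#' @param seed integer seed (required: all randomness is seeded).
#' @param dt sampling interval, s.
#' @param f_zero_true true zero-pyruvate fluorescence, a.u.
#' @param ph_drift `NULL`, or a function of time returning a multiplicative
#'   common-mode factor (e.g. `function(t) 1 + 0.1 * sin(t / 60)`).
#' @param isosbestic emit a second (pyruvate-independent) channel.
#' @return List of class `synthetic_cell`: `f488` (a [time_course()]),
#'   `f435` (or `NULL`), and `truth` (list: `trace` data.frame with
#'   `time_s`, `p_mit_uM`, fluxes and noiseless fluorescence; `params`,
#'   `sinks`, `bc`, `sensor`, `f_zero`, `noise_sd`, `seed`, `protocol`, and
#'   `consumption_at_block` - total sink flux just before the first
#'   inhibited segment, if any).
#' @export
generate_cell <- function(protocol = default_protocol("stop"),
                          params = carrier_params(),
                          bc = boundary_conditions(),
                          sinks = sink_params(),
                          sensor = sensor_params(),
                          noise_sd = 0.02, seed, dt = 1,
                          f_zero_true = 100, ph_drift = NULL,
                          isosbestic = FALSE) {
  if (missing(seed)) stop("generate_cell: 'seed' is required", call. = FALSE)
  if (noise_sd < 0) stop("generate_cell: 'noise_sd' must be >= 0", call. = FALSE)
  sim <- .simulate_protocol(protocol, params, bc, sinks, dt)
  tr <- sim$trace
  f_clean <- f_zero_true * (1 + response_fraction(pmax(tr$p_mit_uM, 0), sensor))
  drift <- if (is.null(ph_drift)) rep(1, nrow(tr)) else ph_drift(tr$time_s)
  f435_clean <- f_zero_true * drift            # isosbestic: ligand-independent
  f488_clean <- f_clean * drift

  noise <- .with_seed(seed, {
    n <- nrow(tr)
    list(a = stats::rnorm(n, 0, noise_sd * f_zero_true),
         b = stats::rnorm(n, 0, noise_sd * f_zero_true))
  })
  f488 <- time_course(tr$time_s, f488_clean + noise$a, channel = "F488")
  f435 <- if (isosbestic)
    time_course(tr$time_s, f435_clean + noise$b, channel = "F435") else NULL

  segs <- protocol$segments
  blk <- which(segs$inhibition > 0)
  # operating point: end of the last segment before the first block (or of
  # the whole experiment when nothing is blocked)
  p_baseline <- if (length(blk)) {
    t_b <- segs$t_start[blk[1]]
    pre <- tr[tr$time_s < t_b, ]
    pre$p_mit_uM[nrow(pre)]
  } else tr$p_mit_uM[nrow(tr)]
  consumption_at_block <- if (length(blk))
    pdh_rate(p_baseline, sinks) + pc_rate(p_baseline, sinks)
  else NA_real_

  truth <- list(trace = cbind(tr, f488_clean = f488_clean,
                              f435_clean = f435_clean),
                params = params, sinks = sinks, bc = bc, sensor = sensor,
                f_zero = f_zero_true, noise_sd = noise_sd, seed = seed,
                protocol = protocol, p_mit_baseline = p_baseline,
                consumption_at_block = consumption_at_block,
                inhibition = if (length(blk)) segs$inhibition[blk[1]] else 0)
  structure(list(f488 = f488, f435 = f435, truth = truth),
            class = "synthetic_cell")
}

#' @export
print.synthetic_cell <- function(x, ...) {
  cat("Synthetic cell experiment\n")
  print(x$f488)
  if (!is.null(x$f435)) print(x$f435)
  if (is.finite(x$truth$consumption_at_block))
    cat(sprintf("  true consumption at block: %.4g uM/s (inhibition %.2f)\n",
                x$truth$consumption_at_block, x$truth$inhibition))
  invisible(x)
}

#' Population specification for synthetic cohorts
#'
#' Cell-to-cell heterogeneity is modeled as independent log-normal
#' multipliers (median 1) on carrier dosage, the two sink capacities and
#' cytosolic pyruvate. `dispersion` is the log-normal `sdlog` per parameter
#' (a single value recycles to all four); the default 0.35 reproduces the
#' roughly ten-fold spread of per-cell consumption observed across cells.
#'
#' @param n_cells number of cells.
#' @param dispersion log-normal sdlog for `mpc_total`, `v_max_pdh`,
#'   `v_max_pc`, `p_cyt` (length 1 or 4).
#' @param noise_sd fluorescence noise (fraction of baseline).
#' @param dt sampling interval, s.
#' @param seed master seed; all child seeds derive from it.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n_cells = 44, dispersion = 0.35, noise_sd = 0.02,
                            dt = 1, seed = 1) {
  if (n_cells < 1) stop("population_spec: 'n_cells' must be >= 1", call. = FALSE)
  if (any(dispersion < 0)) stop("population_spec: 'dispersion' must be >= 0",
                                call. = FALSE)
  if (!length(dispersion) %in% c(1L, 4L))
    stop("population_spec: 'dispersion' must have length 1 or 4", call. = FALSE)
  dispersion <- rep(dispersion, length.out = 4)
  names(dispersion) <- c("mpc_total", "v_max_pdh", "v_max_pc", "p_cyt")
  structure(list(n_cells = as.integer(n_cells), dispersion = dispersion,
                 noise_sd = noise_sd, dt = dt, seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a synthetic cell population
#'
#' Draws per-cell parameters log-normally around the supplied base values,
#' derives one child seed per cell from the master seed, runs
#' [generate_cell()] for each, and returns the experiments together with a
#' tidy ground-truth table (per-cell parameters, steady-state matrix
#' pyruvate and total consumption). Identical master seeds give
#' bit-identical output.
#'
#' @param spec [population_spec()].
#' @param protocol [experiment_protocol()].
#' @param params,bc,sinks,sensor base model and sensor parameters.
#' @param ... further arguments passed to [generate_cell()] (e.g.
#'   `isosbestic`, `ph_drift`).
#' @return List of class `synthetic_population`: `cells` (list of
#'   `synthetic_cell`) and `truth` (data.frame with one row per cell:
#'   `cell_id`, the four parameter multipliers, `p_mit_ss_uM`,
#'   `consumption_um_s`, `seed`).
#' @export
generate_population <- function(spec = population_spec(),
                                protocol = default_protocol("stop"),
                                params = carrier_params(),
                                bc = boundary_conditions(),
                                sinks = sink_params(),
                                sensor = sensor_params(), ...) {
  n <- spec$n_cells
  seeds <- .child_seeds(spec$seed, n + 1L)
  mult <- .with_seed(seeds[n + 1L], {
    m <- vapply(spec$dispersion, function(s)
      stats::rlnorm(n, meanlog = 0, sdlog = s), numeric(n))
    matrix(m, nrow = n, dimnames = list(NULL, names(spec$dispersion)))
  })
  cells <- vector("list", n)
  truth <- vector("list", n)
  for (j in seq_len(n)) {
    pj <- params; pj$mpc_total <- params$mpc_total * mult[j, "mpc_total"]
    sj <- sinks
    sj$v_max_pdh <- sinks$v_max_pdh * mult[j, "v_max_pdh"]
    sj$v_max_pc <- sinks$v_max_pc * mult[j, "v_max_pc"]
    bj <- bc; bj$p_cyt <- bc$p_cyt * mult[j, "p_cyt"]
    cells[[j]] <- generate_cell(protocol, pj, bj, sj, sensor,
                                noise_sd = spec$noise_sd, seed = seeds[j],
                                dt = spec$dt, ...)
    ss <- cells[[j]]$truth
    truth[[j]] <- data.frame(
      cell_id = j,
      mult_mpc = mult[j, "mpc_total"], mult_pdh = mult[j, "v_max_pdh"],
      mult_pc = mult[j, "v_max_pc"], mult_p_cyt = mult[j, "p_cyt"],
      p_mit_ss_uM = ss$p_mit_baseline,
      consumption_um_s = if (is.finite(ss$consumption_at_block))
        ss$consumption_at_block
      else pdh_rate(ss$p_mit_baseline, sj) + pc_rate(ss$p_mit_baseline, sj),
      seed = seeds[j])
  }
  structure(list(cells = cells, truth = do.call(rbind, truth), spec = spec),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("Synthetic population: %d cells (noise %.1f%%, master seed %d)\n",
              x$spec$n_cells, 100 * x$spec$noise_sd, x$spec$seed))
  cat(sprintf("  steady p_mit median %.3g uM; consumption median %.3g uM/s\n",
              stats::median(x$truth$p_mit_ss_uM),
              stats::median(x$truth$consumption_um_s)))
  invisible(x)
}

#' Generate a synthetic sensor dose-response data set
#'
#' Hyperbolic responses on a concentration grid with seeded multiplicative
#' Gaussian noise, replicate-wise, for exercising [fit_dose_response()] by
#' parameter recovery.
#'
#' @param sensor [sensor_params()].
#' @param grid concentrations, uM (must include 0).
#' @param replicates replicates per concentration.
#' @param noise_sd multiplicative noise sd (fraction of the true response).
#' @param seed integer seed.
#' @return data.frame with columns `concentration_uM`, `response_frac`,
#'   `replicate`.
#' @export
generate_dose_response <- function(sensor = sensor_params(),
                                   grid = c(0, 30, 100, 300, 1000, 3000,
                                            10000),
                                   replicates = 3, noise_sd = 0.03, seed) {
  if (missing(seed)) stop("generate_dose_response: 'seed' is required",
                          call. = FALSE)
  if (!any(grid == 0)) stop("generate_dose_response: grid must include 0",
                            call. = FALSE)
  if (replicates < 1) stop("generate_dose_response: 'replicates' must be >= 1",
                           call. = FALSE)
  df <- expand.grid(concentration_uM = grid, replicate = seq_len(replicates))
  r_true <- response_fraction(df$concentration_uM, sensor)
  eps <- .with_seed(seed, stats::rnorm(nrow(df), 0, noise_sd))
  df$response_frac <- r_true * (1 + eps)
  df[order(df$replicate, df$concentration_uM), c("concentration_uM",
                                                 "response_frac", "replicate")]
}
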