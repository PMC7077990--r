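#' Fractional fluorescence response of the sensor to pyruvate
#'
#' Rectangular hyperbola `df_max * p / (k_d + p)`: the fractional change in
#' fluorescence over the zero-pyruvate level. Vectorized over `p`.
#'
#' @param p pyruvate concentration, uM.
#' @param sensor [sensor_params()].
#' @return Fractional fluorescence change (dimensionless).
#' @export
response_fraction <- function(p, sensor = sensor_params()) {
  if (any(!is.finite(p)) || any(p < 0))
    stop("response_fraction: 'p' must be non-negative", call. = FALSE)
  sensor$df_max * p / (sensor$k_d + p)
}

#' Invert the sensor dose-response: fluorescence to concentration
#'
#' Exact inverse of the hyperbola: with `r = (f - f_zero) / f_zero`,
#' `p = k_d * r / (df_max - r)`. Requires a calibrated `f_zero` on the
#' sensor. Responses at or above `df_max` are unidentifiable (sensor
#' saturated) and raise an error; fluorescence below `f_zero` (e.g. noise
#' around a true zero) raises an error unless `clamp_below_zero = TRUE`, in
#' which case those samples are clamped to 0 uM with a warning.
#'
#' @param f fluorescence, a.u. (vectorized).
#' @param sensor [sensor_params()] with `f_zero` set.
#' @param below_zero how to treat fluorescence below `f_zero`: `"error"`
#'   (default), `"clamp"` (clamp to 0 uM with a warning; matches the display
#'   convention that concentrations are non-negative), or `"extend"`
#'   (evaluate the inverse hyperbola on the negative branch, returning small
#'   negative concentrations; this keeps measurement noise around a true
#'   zero symmetric and is recommended when the output feeds rate
#'   estimators).
#' @return Pyruvate concentration, uM.
#' @export
fluorescence_to_concentration <- function(f, sensor,
                                          below_zero = c("error", "clamp",
                                                         "extend")) {
  below_zero <- match.arg(below_zero)
  if (is.na(sensor$f_zero))
    stop("fluorescence_to_concentration: sensor has no 'f_zero'; calibrate first",
         call. = FALSE)
  r <- (f - sensor$f_zero) / sensor$f_zero
  if (any(r >= sensor$df_max))
    stop("fluorescence_to_concentration: response at or above df_max; ",
         "sensor saturated, concentration unidentifiable", call. = FALSE)
  if (any(r < 0)) {
    if (below_zero == "error")
      stop("fluorescence_to_concentration: fluorescence below f_zero; ",
           "use below_zero = \"clamp\" or \"extend\"", call. = FALSE)
    if (below_zero == "clamp") {
      warning("fluorescence_to_concentration: ", sum(r < 0),
              " sample(s) below f_zero clamped to 0 uM", call. = FALSE)
      r <- pmax(r, 0)
    }
  }
  sensor$k_d * r / (sensor$df_max - r)
}

#' One-point in-cell calibration of a fluorescence trace
#'
#' Converts an in-cell fluorescence trace to concentration using the in
#' vitro dose-response parameters and a single in-cell anchor: the mean
#' fluorescence over a window in which cytosolic pyruvate has been forced to
#' a nominal zero (trans-acceleration of the monocarboxylate transporter by
#' lactate) defines `f_zero`; the whole trace is then interpolated on the in
#' vitro hyperbola. This assumes the in vitro `k_d` and `df_max` hold in
#' cells; the returned saturation diagnostic (max response as a fraction of
#' `df_max`) surfaces how far up the curve the trace reaches.
#'
#' @param trace [time_course()] of raw fluorescence.
#' @param zero_window `(start, end)` seconds of the forced-zero segment
#'   (>= 3 samples).
#' @param sensor [sensor_params()] carrying the in vitro `k_d`, `df_max`.
#' @param below_zero passed to [fluorescence_to_concentration()]; the
#'   default `"extend"` keeps noise around the forced-zero anchor symmetric
#'   (recommended when the calibrated trace feeds rate estimators); use
#'   `"clamp"` for display-style non-negative concentrations.
#' @return List of class `calibration`: `sensor` (with `f_zero` filled in),
#'   `concentration` (a `time_course` in uM), and `saturation_fraction`.
#' @export
one_point_calibrate <- function(trace, zero_window,
                                sensor = sensor_params(),
                                below_zero = "extend") {
  idx <- .window_idx(trace, zero_window, "zero_window", min_n = 3L)
  f_zero <- mean(trace$value[idx])
  if (f_zero <= 0)
    stop("one_point_calibrate: non-positive mean fluorescence in zero window",
         call. = FALSE)
  cal <- sensor_params(k_d = sensor$k_d, df_max = sensor$df_max,
                       f_zero = f_zero)
  conc <- fluorescence_to_concentration(trace$value, cal,
                                        below_zero = below_zero)
  structure(list(sensor = cal,
                 concentration = time_course(trace$time, conc,
                                             channel = "concentration"),
                 saturation_fraction =
                   max((trace$value - f_zero) / f_zero) / sensor$df_max),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("One-point calibration: f_zero %.4g a.u., peak at %.1f%% of sensor range\n",
              x$sensor$f_zero, 100 * x$saturation_fraction))
  print(x$concentration)
  invisible(x)
}

#' Isosbestic-ratio pH correction
#'
#' The cpGFP fluorophore is pH sensitive, but excitation at the isosbestic
#' point is pyruvate-independent, so any effect common to both channels
#' (pH drift, expression, focus) cancels in the ratio. The corrected trace
#' is the pointwise ratio of the pyruvate-sensitive channel to the
#' isosbestic channel, renormalized so its mean over the baseline window is
#' 1: a dimensionless F/F0 trace. Because it depends on the data only
#' through the ratio, any factor common to both channels cancels exactly.
#' Downstream quantification is unaffected by the change of units:
#' [one_point_calibrate()] and [percent_of_max()] are both invariant to
#' multiplicative rescaling of the trace.
#'
#' @param f488 [time_course()], pyruvate-sensitive channel.
#' @param f435 [time_course()], isosbestic channel, same time grid.
#' @param baseline_window `(start, end)` seconds of the pre-perturbation
#'   baseline; default the first 10% of the trace.
#' @param reference_smooth running-mean window (seconds) applied to the
#'   isosbestic channel before ratioing; 0 (default) uses the raw reference
#'   and cancels common-mode factors exactly. A nonzero window (e.g. 30 s)
#'   is standard ratiometric practice when the common-mode drift is slow
#'   compared to the shot noise of the reference channel: it stops the
#'   reference's own noise from being injected into the corrected trace, at
#'   the cost of slightly imperfect cancellation of fast drift components.
#' @return Corrected [time_course()] (channel `"F488"`, baseline-normalized
#'   units).
#' @export
ph_correct <- function(f488, f435, baseline_window = NULL,
                       reference_smooth = 0) {
  if (!isTRUE(all.equal(f488$time, f435$time)))
    stop("ph_correct: channels must share one time grid", call. = FALSE)
  if (any(f435$value <= 0))
    stop("ph_correct: isosbestic channel contains non-positive values",
         call. = FALSE)
  if (is.null(baseline_window)) {
    span <- range(f488$time)
    baseline_window <- c(span[1], span[1] + 0.1 * diff(span))
  }
  idx <- .window_idx(f488, baseline_window, "baseline_window", min_n = 2L)
  ref <- f435$value
  if (reference_smooth > 0) {
    dt <- stats::median(diff(f435$time))
    k <- max(1L, round(reference_smooth / dt))
    if (k %% 2L == 0L) k <- k + 1L
    sm <- stats::filter(ref, rep(1 / k, k), sides = 2)
    ref <- ifelse(is.na(sm), ref, as.numeric(sm))  # raw at the edges
  }
  ratio <- f488$value / ref
  time_course(f488$time, ratio / mean(ratio[idx]), channel = "F488")
}

#' Normalize a trace to percent of maximum change
#'
#' `100 * (F - F_zero) / (F_max - F_zero)` with `F_zero` and `F_max` taken
#' as window means: 0% at the forced-zero level, 100% at the saturating
#' level. Invariant to affine rescaling of the raw fluorescence.
#'
#' @param trace [time_course()].
#' @param zero_window,max_window `(start, end)` second pairs.
#' @return [time_course()] with channel `"percent_max"`.
#' @export
percent_of_max <- function(trace, zero_window, max_window) {
  iz <- .window_idx(trace, zero_window, "zero_window")
  im <- .window_idx(trace, max_window, "max_window")
  f0 <- mean(trace$value[iz])
  fm <- mean(trace$value[im])
  if (fm <= f0)
    stop("percent_of_max: max-window mean must exceed zero-window mean",
         call. = FALSE)
  time_course(trace$time, 100 * (trace$value - f0) / (fm - f0),
              channel = "percent_max")
}

#' Fit the hyperbolic dose-response of the sensor
#'
#' Nonlinear least squares of `df_max * p / (k_d + p)` to fractional
#' responses, with asymptotic standard errors. Warns when the fitted `k_d`
#' exceeds the largest tested concentration (saturation not reached: the
#' `k_d` estimate is then poorly identified, which the wide standard error
#' reflects).
#'
#' @param concentrations pyruvate, uM (must include 0 and >= 5 distinct
#'   values).
#' @param responses fractional responses (same length), replicate
#'   observations allowed as repeated concentrations.
#' @param start optional list of starting values `k_d`, `df_max`.
#' @return List of class `dose_response_fit`: `sensor` (a [sensor_params()]
#'   with the estimates), `se` (named standard errors), `fit`.
#' @export
fit_dose_response <- function(concentrations, responses, start = NULL) {
  if (length(concentrations) != length(responses))
    stop("fit_dose_response: lengths differ", call. = FALSE)
  if (length(unique(concentrations)) < 5L || !any(concentrations == 0))
    stop("fit_dose_response: need >= 5 distinct concentrations including 0",
         call. = FALSE)
  df <- data.frame(p = concentrations, r = responses)
  if (is.null(start))
    start <- list(df_max = max(responses), k_d = stats::median(concentrations[concentrations > 0]))
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ df_max * p / (k_d + p), data = df, start = start,
                      lower = c(df_max = 1e-12, k_d = 1e-12)),
    error = function(e)
      stop("fit_dose_response: fit failed to converge (", conditionMessage(e),
           ")", call. = FALSE))
  co <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  if (co[["k_d"]] > max(concentrations))
    warning("fit_dose_response: fitted k_d exceeds the largest tested ",
            "concentration; estimate poorly identified", call. = FALSE)
  structure(list(sensor = sensor_params(k_d = co[["k_d"]],
                                        df_max = co[["df_max"]]),
                 se = c(k_d = unname(se["k_d"]), df_max = unname(se["df_max"])),
                 fit = fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit: K_D %.4g +- %.2g uM, df_max %.4g +- %.2g\n",
              x$sensor$k_d, x$se["k_d"], x$sensor$df_max, x$se["df_max"]))
  invisible(x)
}
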