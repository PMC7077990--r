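#' Carrier kinetic parameters for the six-state MPC model
#'
#' Parameters of the alternating-access mitochondrial pyruvate carrier (MPC)
#' model. The carrier cycles between outward- and inward-facing conformations,
#' each empty, proton-loaded, or proton+pyruvate-loaded (six states). Binding
#' is ordered (proton first, then pyruvate); the empty carrier translocates at
#' rate `f1`, the fully loaded carrier at `f2`, and proton-only forms do not
#' translocate. All rate constants are side-symmetric.
#'
#' Defaults are the published parameter set for astrocytic mitochondria:
#' total carrier 3.24 uM, association rate 1e8 M^-1 s^-1 (= 100 uM^-1 s^-1,
#' shared by proton and pyruvate), proton off-rate 20 s^-1, pyruvate off-rate
#' 2.12e6 s^-1, translocation rates 200 s^-1 (empty) and 3000 s^-1 (loaded).
#'
#' @param mpc_total total carrier concentration, uM (all six states).
#' @param k_on bimolecular association rate, uM^-1 s^-1 (protons and pyruvate).
#' @param k_off_h proton dissociation rate, s^-1.
#' @param k_off_p pyruvate dissociation rate, s^-1.
#' @param f1 empty-carrier translocation rate, s^-1 (both directions).
#' @param f2 loaded-carrier translocation rate, s^-1 (both directions).
#'
#' @return An object of class `carrier_params`.
#' @examples
#' carrier_params()                 # published set
#' carrier_params(mpc_total = 6.48) # doubled dosage
#' @export
carrier_params <- function(mpc_total = 3.24, k_on = 100, k_off_h = 20,
                           k_off_p = 2.12e6, f1 = 200, f2 = 3000) {
  p <- list(mpc_total = mpc_total, k_on = k_on, k_off_h = k_off_h,
            k_off_p = k_off_p, f1 = f1, f2 = f2)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("carrier_params: '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  structure(p, class = "carrier_params")
}

#' @export
print.carrier_params <- function(x, ...) {
  cat("MPC carrier parameters (uM, s):\n")
  cat(sprintf("  mpc_total %-10g k_on %-10g k_off_h %-10g\n",
              x$mpc_total, x$k_on, x$k_off_h))
  cat(sprintf("  k_off_p   %-10g f1   %-10g f2      %-10g\n",
              x$k_off_p, x$f1, x$f2))
  invisible(x)
}

#' Clamped boundary conditions: cytosolic pyruvate and proton concentrations
#'
#' Cytosolic pyruvate and the proton concentrations on both faces of the inner
#' membrane are held fixed (the model integrates no cytosolic equations).
#' Protons are carried in uM; the defaults are the rounded values for
#' cytosolic pH 7.2 (63 nM = 0.063 uM) and matrix pH 7.8 (16 nM = 0.016 uM),
#' a ~4-fold transmembrane proton gradient.
#'
#' @param p_cyt cytosolic pyruvate, uM.
#' @param h_cyt cytosolic proton concentration, uM.
#' @param h_mit matrix proton concentration, uM.
#' @return An object of class `boundary_conditions`.
#' @seealso [boundary_conditions_from_ph()]
#' @examples
#' boundary_conditions(p_cyt = 33)
#' @export
boundary_conditions <- function(p_cyt = 33, h_cyt = 0.063, h_mit = 0.016) {
  for (nm in c("p_cyt", "h_cyt", "h_mit")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("boundary_conditions: '", nm, "' must be a single non-negative number",
           call. = FALSE)
  }
  structure(list(p_cyt = p_cyt, h_cyt = h_cyt, h_mit = h_mit),
            class = "boundary_conditions")
}

#' Boundary conditions from pH values
#'
#' Convenience constructor converting pH to proton concentration in uM.
#' The physiological pair 7.2/7.8 maps to the rounded published values
#' 0.063/0.016 uM (rather than exact `10^-pH`) so that printed steady-state
#' numbers are reproduced; any other pH uses `10^(6 - pH)`.
#'
#' @param p_cyt cytosolic pyruvate, uM.
#' @param ph_cyt cytosolic pH.
#' @param ph_mit mitochondrial matrix pH.
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions_from_ph <- function(p_cyt = 33, ph_cyt = 7.2, ph_mit = 7.8) {
  rounded <- c(`7.2` = 0.063, `7.8` = 0.016)
  conv <- function(ph) {
    key <- as.character(ph)
    if (key %in% names(rounded)) rounded[[key]] else 10^(6 - ph)
  }
  boundary_conditions(p_cyt = p_cyt, h_cyt = conv(ph_cyt), h_mit = conv(ph_mit))
}

#' @export
print.boundary_conditions <- function(x, ...) {
  cat(sprintf("Boundary conditions: p_cyt %g uM, h_cyt %g uM, h_mit %g uM\n",
              x$p_cyt, x$h_cyt, x$h_mit))
  invisible(x)
}

#' Michaelis-Menten parameters of the matrix pyruvate sinks
#'
#' The two matrix pyruvate sinks: pyruvate dehydrogenase (PDH, oxidation) and
#' pyruvate carboxylase (PC, anaplerosis), each modeled as a saturable
#' reaction. Defaults are the published values: PDH Vmax 1.34 uM/s, Km 10 uM;
#' PC Vmax 3.3 uM/s, Km 220 uM. The order-of-magnitude Km difference is what
#' makes PC flux ultrasensitive to matrix pyruvate in the low-micromolar
#' range while PDH is nearly saturated.
#'
#' @param v_max_pdh,k_m_pdh PDH maximal rate (uM/s) and Michaelis constant (uM).
#' @param v_max_pc,k_m_pc PC maximal rate (uM/s) and Michaelis constant (uM).
#' @return An object of class `sink_params`.
#' @export
sink_params <- function(v_max_pdh = 1.34, k_m_pdh = 10,
                        v_max_pc = 3.3, k_m_pc = 220) {
  p <- list(v_max_pdh = v_max_pdh, k_m_pdh = k_m_pdh,
            v_max_pc = v_max_pc, k_m_pc = k_m_pc)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("sink_params: '", nm, "' must be a single non-negative number",
           call. = FALSE)
    if (grepl("^k_m", nm) && v <= 0)
      stop("sink_params: '", nm, "' must be strictly positive", call. = FALSE)
  }
  structure(p, class = "sink_params")
}

#' @export
print.sink_params <- function(x, ...) {
  cat(sprintf("Sinks: PDH Vmax %g uM/s Km %g uM; PC Vmax %g uM/s Km %g uM\n",
              x$v_max_pdh, x$k_m_pdh, x$v_max_pc, x$k_m_pc))
  invisible(x)
}

#' Hyperbolic biosensor dose-response parameters
#'
#' Single-fluorophore pyruvate sensor model: the fractional fluorescence
#' change follows a rectangular hyperbola `df_max * p / (k_d + p)`. Defaults
#' are the in vitro characterization of the mito-targetable sensor:
#' K_D 480 uM, maximal change 247% (`df_max = 2.47`). `f_zero` is the
#' per-cell fluorescence at zero pyruvate (arbitrary units), set by
#' calibration.
#'
#' @param k_d dissociation constant, uM.
#' @param df_max maximal fractional fluorescence change (dimensionless).
#' @param f_zero fluorescence at zero pyruvate, arbitrary units (NA until
#'   calibrated).
#' @return An object of class `sensor_params`.
#' @export
sensor_params <- function(k_d = 480, df_max = 2.47, f_zero = NA_real_) {
  if (!is.numeric(k_d) || length(k_d) != 1L || !is.finite(k_d) || k_d <= 0)
    stop("sensor_params: 'k_d' must be a single positive number", call. = FALSE)
  if (!is.numeric(df_max) || length(df_max) != 1L || !is.finite(df_max) ||
      df_max <= 0)
    stop("sensor_params: 'df_max' must be a single positive number",
         call. = FALSE)
  if (!is.na(f_zero) && (!is.numeric(f_zero) || f_zero <= 0))
    stop("sensor_params: 'f_zero' must be positive when supplied",
         call. = FALSE)
  structure(list(k_d = k_d, df_max = df_max, f_zero = f_zero),
            class = "sensor_params")
}

#' @export
print.sensor_params <- function(x, ...) {
  cat(sprintf("Sensor: K_D %g uM, max fractional change %g (%.0f%%)",
              x$k_d, x$df_max, 100 * x$df_max))
  if (!is.na(x$f_zero)) cat(sprintf(", f_zero %g a.u.", x$f_zero))
  cat("\n")
  invisible(x)
}

#' Read or write a model configuration file
#'
#' Configuration files are YAML (or JSON, via yaml's parser) with top-level
#' keys `carrier`, `boundary`, `sinks`, `sensor`, each holding the fields of
#' the corresponding constructor. Units are uM and seconds throughout.
#' A defaults file with the published parameter set ships with the package
#' (`system.file("extdata", "default_params.yaml", package = "pyruflux")`).
#'
#' @param path file path.
#' @return `read_model_config()` returns a list with elements `carrier`,
#'   `boundary`, `sinks`, `sensor` (those present in the file, validated
#'   through the constructors). `write_model_config()` returns `path`
#'   invisibly.
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$carrier))  out$carrier  <- do.call(carrier_params, raw$carrier)
  if (!is.null(raw$boundary)) out$boundary <- do.call(boundary_conditions, raw$boundary)
  if (!is.null(raw$sinks))    out$sinks    <- do.call(sink_params, raw$sinks)
  if (!is.null(raw$sensor)) {
    s <- raw$sensor
    s$f_zero <- if (is.null(s$f_zero)) NA_real_ else s$f_zero
    out$sensor <- do.call(sensor_params, s)
  }
  out
}

#' @rdname read_model_config
#' @param config list with any of `carrier`, `boundary`, `sinks`, `sensor`.
#' @export
write_model_config <- function(config, path) {
  strip <- function(x) if (is.null(x)) NULL else lapply(unclass(x), identity)
  out <- list(carrier = strip(config$carrier), boundary = strip(config$boundary),
              sinks = strip(config$sinks), sensor = strip(config$sensor))
  out <- Filter(Negate(is.null), out)
  yaml::write_yaml(out, path)
  invisible(path)
}
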