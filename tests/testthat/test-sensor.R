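test_that("sensor hyperbola and its inverse round-trip exactly", {
  sp <- sensor_params()
  expect_equal(response_fraction(0, sp), 0)
  expect_equal(response_fraction(480, sp), 2.47 / 2)   # half-saturation at K_D
  expect_equal(response_fraction(10000, sp), 2.47 * 10000 / 10480)
  expect_error(response_fraction(-1, sp), "non-negative")

  cal <- sensor_params(f_zero = 100)
  expect_equal(fluorescence_to_concentration(100, cal), 0)
  # half of df_max maps back to K_D
  expect_equal(fluorescence_to_concentration(100 * (1 + 2.47 / 2), cal), 480)
  # round trip across the working range
  for (p in c(0.5, 5, 21, 33, 480, 1e4)) {
    f <- 100 * (1 + response_fraction(p, cal))
    expect_equal(fluorescence_to_concentration(f, cal), p,
                 tolerance = 1e-9)
  }
  # saturation is unidentifiable
  expect_error(fluorescence_to_concentration(100 * (1 + 2.47), cal),
               "saturated")
  # sub-baseline handling: error, clamp with warning, symmetric extension
  expect_error(fluorescence_to_concentration(99, cal), "below f_zero")
  expect_warning(p0 <- fluorescence_to_concentration(99, cal, "clamp"),
                 "clamped")
  expect_equal(p0, 0)
  expect_lt(fluorescence_to_concentration(99, cal, "extend"), 0)
})

test_that("one-point calibration recovers the concentration scale from a forced zero", {
  # deterministic trace: zero segment at 100 a.u., plateau at 21 uM
  cell <- generate_cell(seed = 5, noise_sd = 0)
  cal <- one_point_calibrate(cell$f488, zero_window = c(10, 110))
  expect_equal(cal$sensor$f_zero, 100, tolerance = 1e-10)
  plateau <- cal$concentration$value[cal$concentration$time >= 380 &
                                       cal$concentration$time <= 419]
  expect_equal(mean(plateau), 21, tolerance = 0.02)

  # flat all-zero trace calibrates to flat 0 uM
  flat <- time_course(0:120, rep(100, 121), channel = "F488")
  cal0 <- one_point_calibrate(flat, zero_window = c(0, 120))
  expect_true(all(cal0$concentration$value == 0))

  # noisy zero window: anchor recovered to sub-percent accuracy
  set.seed(31)
  noisy <- time_course(0:120, 100 + rnorm(121, 0, 2), channel = "F488")
  caln <- one_point_calibrate(noisy, zero_window = c(0, 49))
  expect_lt(abs(caln$sensor$f_zero - 100) / 100, 0.01)

  expect_error(one_point_calibrate(flat, zero_window = c(0, 1)), "samples")
})

test_that("isosbestic ratioing removes common-mode drift exactly", {
  t <- 0:300
  signal <- 100 * (1 + response_fraction(c(rep(0, 100), rep(21, 201))))
  drift <- 1 + 0.1 * sin(t / 20)
  f488 <- time_course(t, signal * drift, channel = "F488")
  f435 <- time_course(t, 100 * drift, channel = "F435")
  corr <- ph_correct(f488, f435, baseline_window = c(0, 99))
  clean <- signal / mean(signal[1:100])
  expect_equal(corr$value, clean, tolerance = 1e-12)

  # arbitrary common-mode factor leaves the corrected trace unchanged
  g <- exp(0.2 * cos(t / 7)) * (1 + 0.05 * t / 300)
  f488g <- time_course(t, f488$value * g, channel = "F488")
  f435g <- time_course(t, f435$value * g, channel = "F435")
  corr_g <- ph_correct(f488g, f435g, baseline_window = c(0, 99))
  expect_equal(corr_g$value, corr$value, tolerance = 1e-12)

  # constant reference: correction is a pure rescaling of the signal channel
  f435c <- time_course(t, rep(77, length(t)), channel = "F435")
  corr_c <- ph_correct(f488, f435c, baseline_window = c(0, 99))
  expect_equal(corr_c$value / corr_c$value[1],
               f488$value / f488$value[1], tolerance = 1e-12)

  expect_error(ph_correct(f488, time_course(t, c(0, rep(1, 300)),
                                            channel = "F435")),
               "non-positive")
})

test_that("percent-of-max normalization anchors its windows and ignores affine scale", {
  t <- 0:100
  f <- c(rep(100, 20), seq(100, 300, length.out = 61), rep(300, 20))
  tc <- time_course(t, f, channel = "F488")
  pm <- percent_of_max(tc, zero_window = c(0, 19), max_window = c(81, 100))
  expect_equal(mean(pm$value[1:20]), 0, tolerance = 1e-12)
  expect_equal(mean(pm$value[82:101]), 100, tolerance = 1e-12)
  expect_equal(pm$value[f == 200][1], 50, tolerance = 1e-12)

  # affine rescaling of the raw fluorescence changes nothing
  tc2 <- time_course(t, 3.7 * f + 12, channel = "F488")
  pm2 <- percent_of_max(tc2, zero_window = c(0, 19), max_window = c(81, 100))
  expect_equal(pm2$value, pm$value, tolerance = 1e-12)

  expect_error(percent_of_max(tc, c(81, 100), c(0, 19)), "exceed")
})

test_that("dose-response fitting recovers the sensor constants", {
  sp <- sensor_params()
  grid <- c(0, 30, 100, 300, 1000, 3000, 10000)
  # noiseless: exact recovery
  fit0 <- fit_dose_response(grid, response_fraction(grid, sp))
  expect_equal(fit0$sensor$k_d, 480, tolerance = 1e-6)
  expect_equal(fit0$sensor$df_max, 2.47, tolerance = 1e-6)

  # scale equivariance: scaling responses scales df_max, leaves k_d alone
  fitc <- fit_dose_response(grid, 3 * response_fraction(grid, sp))
  expect_equal(fitc$sensor$k_d, 480, tolerance = 1e-6)
  expect_equal(fitc$sensor$df_max, 3 * 2.47, tolerance = 1e-6)

  # 3% multiplicative noise, triplicates: recovery within 15% / 5%
  # in at least 95% of seeded repetitions
  hits <- vapply(1:50, function(s) {
    dr <- generate_dose_response(seed = s)
    fit <- fit_dose_response(dr$concentration_uM, dr$response_frac)
    abs(fit$sensor$k_d - 480) / 480 < 0.15 &&
      abs(fit$sensor$df_max - 2.47) / 2.47 < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # truncated titration: saturation unreached, poorly identified k_d flagged
  gtr <- c(0, 5, 10, 25, 50, 100)
  expect_warning(fit_tr <- fit_dose_response(gtr, response_fraction(gtr, sp)),
                 "poorly identified")
  expect_gt(fit_tr$se["k_d"] / fit_tr$sensor$k_d,
            fit0$se["k_d"] / fit0$sensor$k_d)

  expect_error(fit_dose_response(c(1, 2, 3), c(0.1, 0.2, 0.3)), "distinct")
})
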