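test_that("measured loop width agrees with the analytic width to 1%", {
  ser <- sine_loop()
  m <- measure_hysteresis_width(ser)
  w_analytic <- hysteresis_width(duct_10mm, air_cfd, proto_sine)
  expect_equal(w_analytic, 2.352, tolerance = 1e-4)
  expect_lt(abs(m$width - w_analytic) / w_analytic, 0.01)
})

test_that("width measurement interpolates crossings linearly", {
  # hand-computed: crossing between (-1, 1 Pa) and (+1, 2 Pa) sits at 1.5 Pa
  ser <- manual_series(
    time = c(0, 1, 2),
    flow = c(-1e-6, 1e-6, -1e-6),
    pressure = c(1.0, 2.0, 3.0)
  )
  m <- measure_hysteresis_width(ser)
  expect_equal(m$crossings$pressure, c(1.5, 2.5))
  expect_equal(m$width, 1.0)
})

test_that("width convergence in sampling spacing is at least first order", {
  w_true <- hysteresis_width(duct_10mm, air_cfd, proto_sine)
  # rates chosen so the zero crossings fall between samples; crossings that
  # land on the grid are measured exactly and carry no information on order
  rates <- c(11, 21, 41, 81)
  err <- vapply(rates, function(rate) {
    abs(measure_hysteresis_width(sine_loop(sampling_rate = rate))$width - w_true)
  }, numeric(1))
  h <- 1 / rates
  order_est <- mean(diff(log(err)) / diff(log(h)))
  expect_gt(order_est, 1)
})

test_that("width is undefined for unidirectional series", {
  ser <- manual_series(
    time = 0:3, flow = c(1, 2, 3, 2) * 1e-4,
    pressure = c(1, 2, 3, 2)
  )
  expect_error(measure_hysteresis_width(ser), "zero crossings")
})

test_that("fixed-length fit recovers the generating diameter within 0.5%", {
  for (dh_true in c(6e-3, 8e-3, 10e-3)) {
    steady <- generate_rmm_timeseries(
      duct_model(dh_true, 0.1), air_cfd,
      proto_sine, blended,
      include_unsteady = FALSE
    )
    fit <- fit_dh_fixed_length(steady, 0.1, policy = blended)
    expect_lt(abs(fit$hydraulic_diameter - dh_true) / dh_true, 0.005)
    expect_true(fit$convergence)
  }
})

test_that("fixed-length fits preserve resistance ordering", {
  fits <- vapply(c(6e-3, 10e-3), function(dh) {
    ser <- generate_rmm_timeseries(duct_model(dh, 0.1), air_cfd, proto_sine,
      laminar,
      include_unsteady = FALSE
    )
    fit_dh_fixed_length(ser, 0.1, policy = laminar)$hydraulic_diameter
  }, numeric(1))
  expect_lt(fits[1], fits[2])
  # the higher-resistance curve yields the smaller fitted diameter
  r6 <- hagen_poiseuille_resistance(duct_model(6e-3, 0.1), air_cfd)
  r10 <- hagen_poiseuille_resistance(duct_model(10e-3, 0.1), air_cfd)
  expect_gt(r6, r10)
})

test_that("fixed-length fit validates its inputs", {
  ser <- sine_loop()
  expect_error(fit_dh_fixed_length(ser[1:5, ], 0.1), "at least two samples|10 samples")
  still <- manual_series(
    time = seq(0, 1, length.out = 12),
    flow = rep(0, 12), pressure = rep(0, 12)
  )
  expect_error(fit_dh_fixed_length(still, 0.1), "degenerate")
})

test_that("hysteresis-constrained fit recovers diameter and length in round-trip", {
  ser <- sine_loop()
  fit <- fit_dh_hysteresis_constrained(ser, policy = laminar)
  expect_lt(abs(fit$hydraulic_diameter - 0.01) / 0.01, 0.01)
  expect_lt(abs(fit$length - 0.1) / 0.1, 0.03)
  expect_equal(fit$length_source, "recovered")
})

test_that("a zero width degenerates the constrained fit", {
  ser <- sine_loop()
  expect_error(
    fit_dh_hysteresis_constrained(ser, width = 0),
    "degenerate"
  )
})

test_that("Haaland-everywhere misfits a laminar-regime loop more than the blend", {
  # Qmax = 200 mL/s at Dh = 10 mm keeps peak Re below 2000: fully laminar
  ser <- sine_loop(qmax = 200e-6, policy = blended)
  expect_lt(
    reynolds_number(200e-6, duct_10mm, air_cfd),
    2000
  )
  fit_blend <- fit_dh_hysteresis_constrained(ser, policy = blended)
  fit_haaland <- fit_dh_hysteresis_constrained(ser, policy = turbulent)
  expect_gt(fit_haaland$residual_rms, fit_blend$residual_rms)
})

test_that("fits are deterministic", {
  ser <- sine_loop()
  f1 <- fit_dh_fixed_length(ser, 0.1, policy = laminar)
  f2 <- fit_dh_fixed_length(ser, 0.1, policy = laminar)
  expect_identical(f1, f2)
  g1 <- fit_dh_hysteresis_constrained(ser, policy = laminar)
  g2 <- fit_dh_hysteresis_constrained(ser, policy = laminar)
  expect_identical(g1, g2)
})

test_that("parameter recovery holds across a randomized parameter grid", {
  set.seed(23)
  for (i in 1:5) {
    dh <- stats::runif(1, 4e-3, 15e-3)
    len <- stats::runif(1, 0.05, 0.15)
    qmax <- stats::runif(1, 200e-6, 800e-6)
    tau <- stats::runif(1, 3, 8)
    pr <- breathing_protocol("sine", qmax, tau)
    duct <- duct_model(dh, len)
    steady <- generate_rmm_timeseries(duct, air_cfd, pr, blended,
      include_unsteady = FALSE
    )
    fit_fl <- fit_dh_fixed_length(steady, len, policy = blended)
    expect_lt(abs(fit_fl$hydraulic_diameter - dh) / dh, 0.005)

    loop <- generate_rmm_timeseries(duct, air_cfd, pr, blended)
    fit_hc <- fit_dh_hysteresis_constrained(loop, policy = blended)
    expect_lt(abs(fit_hc$hydraulic_diameter - dh) / dh, 0.01)
    expect_lt(abs(fit_hc$length - len) / len, 0.03)
  }
})

test_that("channel length inverts the width relation", {
  w <- hysteresis_width(duct_10mm, air_cfd, proto_sine)
  expect_equal(
    channel_length_from_width(w, 0.01, proto_sine, air_cfd),
    0.1,
    tolerance = 1e-12
  )
  expect_equal(channel_length_from_width(0, 0.01, proto_sine, air_cfd), 0)
  expect_equal(
    channel_length_from_width(2 * w, 0.01, proto_sine, air_cfd),
    0.2,
    tolerance = 1e-12
  )
  expect_error(
    channel_length_from_width(w, 0.01, breathing_protocol("sine", 0, 5), air_cfd),
    "undefined"
  )
})

test_that("resistance is constant along a steady laminar curve", {
  steady <- sine_loop(include_unsteady = FALSE)
  r_hp <- hagen_poiseuille_resistance(duct_10mm, air_cfd)
  r100 <- resistance_at(steady, 100e-6)
  r300 <- resistance_at(steady, 300e-6)
  expect_equal(r100, r_hp, tolerance = 1e-4)
  expect_equal(r100, r300, tolerance = 1e-4)
  expect_equal(r100, 7290.67, tolerance = 1e-4)
  expect_error(resistance_at(steady, 0), "zero flow")
  expect_error(resistance_at(steady, 700e-6), "outside the sampled flow range")
})
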