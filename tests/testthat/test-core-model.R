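test_that("Reynolds number follows the internal duct-flow definition", {
  expect_equal(reynolds_number(0, duct_10mm, air_rounded), 0)
  expect_equal(reynolds_number(600e-6, duct_10mm, air_rounded),
    4 * 600e-6 / (pi * 1.5e-5 * 0.01),
    tolerance = 1e-12
  )
  expect_equal(reynolds_number(600e-6, duct_10mm, air_rounded), 5092.958,
    tolerance = 1e-6
  )
  # linear in |Q|, sign-blind
  expect_equal(
    reynolds_number(300e-6, duct_10mm, air_rounded),
    reynolds_number(600e-6, duct_10mm, air_rounded) / 2
  )
  expect_equal(
    reynolds_number(-300e-6, duct_10mm, air_rounded),
    reynolds_number(300e-6, duct_10mm, air_rounded)
  )
  expect_error(duct_model(-0.01, 0.1), "positive")
})

test_that("friction factor branches match their correlations", {
  expect_equal(friction_factor(2000, policy = laminar), 64 / 2000)
  expect_equal(friction_factor(4000, policy = turbulent), 0.0404229,
    tolerance = 1e-5
  )
  haaland_1e5 <- friction_factor(1e5, policy = turbulent)
  expect_equal(haaland_1e5, 0.0178249, tolerance = 1e-5)
  # independent smooth-pipe check: Blasius correlation at the same Re
  blasius <- 0.3164 / 1e5^0.25
  expect_lt(abs(haaland_1e5 - blasius) / blasius, 0.02)

  expect_error(friction_factor(0, policy = laminar), "undefined")
  expect_error(friction_factor(0, policy = blended), "undefined")
  expect_error(friction_factor(4000, relative_roughness = -0.1), "non-negative")
})

test_that("blended friction factor is continuous and collapses to the pure branches", {
  re <- sort(c(
    10^seq(0.5, 6, length.out = 200),
    seq(1900, 4100, by = 10), 2000, 4000
  ))
  fb <- friction_factor(re, policy = blended)
  # coincides with pure branches outside the transition band
  lam_side <- re <= 2000
  expect_equal(fb[lam_side], 64 / re[lam_side])
  turb_side <- re >= 4000
  expect_equal(fb[turb_side], friction_factor(re[turb_side], policy = turbulent))
  # no jumps: relative step between adjacent fine-grid values stays small
  fine <- seq(1500, 4500, by = 1)
  ff <- friction_factor(fine, policy = blended)
  expect_lt(max(abs(diff(ff)) / ff[-1]), 1e-3)
})

test_that("transition weight is 1 below, 0 above, and monotone within the band", {
  expect_equal(transition_weight(c(0, 1000, 2000)), c(1, 1, 1))
  expect_equal(transition_weight(c(4000, 1e6)), c(0, 0))
  w <- transition_weight(seq(2000, 4000, by = 10))
  expect_true(all(diff(w) <= 0))
  expect_error(friction_policy(blend_lower = 4000, blend_upper = 2000), "less")
})

test_that("Hagen-Poiseuille resistance has the quartic diameter scaling", {
  expect_equal(hagen_poiseuille_resistance(duct_model(0.01, 0), air_cfd), 0)
  expect_equal(hagen_poiseuille_resistance(duct_10mm, air_cfd),
    7290.67,
    tolerance = 1e-5
  )
  r1 <- hagen_poiseuille_resistance(duct_model(0.005, 0.1), air_cfd)
  r2 <- hagen_poiseuille_resistance(duct_model(0.01, 0.1), air_cfd)
  expect_equal(r1 / r2, 16, tolerance = 1e-12)
})

test_that("bilateral resistance is the harmonic combination with occlusion support", {
  expect_equal(combine_unilateral_resistances(2, 2), 1)
  expect_equal(combine_unilateral_resistances(3, 6), 2)
  expect_equal(combine_unilateral_resistances(7.5, NA), 7.5)
  expect_equal(combine_unilateral_resistances(NA, 7.5), 7.5)
  # symmetric and never above the smaller side
  set.seed(11)
  for (i in 1:25) {
    r <- stats::runif(2, 0.1, 100)
    bi <- combine_unilateral_resistances(r[1], r[2])
    expect_equal(bi, combine_unilateral_resistances(r[2], r[1]))
    expect_lte(bi, min(r))
  }
  expect_error(combine_unilateral_resistances(0, 5), "positive")
  expect_error(combine_unilateral_resistances(Inf, 5), "positive")
  expect_error(combine_unilateral_resistances(NA, NA), "at least one")
})

test_that("steady laminar pressure drop is the Hagen-Poiseuille line", {
  expect_equal(
    pressure_drop(100e-6, 0, duct_10mm, air_cfd, laminar),
    0.729067,
    tolerance = 1e-5
  )
  # property: dP = R_HP * Q to relative 1e-12 over randomized parameters
  set.seed(7)
  for (i in 1:30) {
    duct <- duct_model(stats::runif(1, 2e-3, 3e-2), stats::runif(1, 0.01, 0.5))
    fl <- fluid_properties(stats::runif(1, 0.8, 1.5), stats::runif(1, 1e-5, 3e-5))
    q <- stats::runif(1, -1e-3, 1e-3)
    expect_equal(
      pressure_drop(q, 0, duct, fl, laminar),
      hagen_poiseuille_resistance(duct, fl) * q,
      tolerance = 1e-12
    )
  }
  # the line passes through the origin
  expect_identical(pressure_drop(0, 0, duct_10mm, air_cfd, laminar), 0)
})

test_that("friction opposes the flow in both directions", {
  for (pol in list(laminar, turbulent, blended)) {
    dp_fwd <- pressure_drop(4e-4, 0, duct_10mm, air_cfd, pol)
    dp_rev <- pressure_drop(-4e-4, 0, duct_10mm, air_cfd, pol)
    expect_equal(dp_fwd, -dp_rev, tolerance = 1e-12)
    expect_gt(dp_fwd, 0)
  }
})

test_that("the unsteady term alone gives half the hysteresis width at zero flow", {
  omega <- 2 * pi / 5
  dp <- pressure_drop(0, omega * 600e-6, duct_10mm, air_cfd, blended)
  expect_equal(dp, 1.176, tolerance = 1e-4)
  w <- hysteresis_width(duct_10mm, air_cfd, proto_sine)
  expect_equal(2 * dp, w, tolerance = 1e-12)
})

test_that("hysteresis width matches the analytic sinusoidal formula", {
  expect_equal(
    hysteresis_width(
      duct_10mm, air_cfd,
      breathing_protocol("sine", 0, 5)
    ), 0
  )
  expect_equal(hysteresis_width(duct_10mm, air_cfd, proto_sine), 2.352,
    tolerance = 1e-6
  )
  # W = 2 * pressure_drop(0, omega * Qmax) for random parameter draws
  set.seed(13)
  for (i in 1:25) {
    duct <- duct_model(stats::runif(1, 3e-3, 2e-2), stats::runif(1, 0.02, 0.3))
    pr <- breathing_protocol("sine", stats::runif(1, 1e-4, 1e-3),
      period = stats::runif(1, 2, 10)
    )
    expect_equal(
      hysteresis_width(duct, air_cfd, pr),
      2 * pressure_drop(
        0, pr$angular_frequency * pr$peak_flowrate,
        duct, air_cfd, blended
      ),
      tolerance = 1e-12
    )
  }
})

test_that("relative hysteresis width equals W / (R_HP * Qmax) exactly", {
  expect_equal(relative_hysteresis_width(0.01, 5, air_rounded), 0.5235988,
    tolerance = 1e-6
  )
  set.seed(17)
  for (i in 1:25) {
    duct <- duct_model(stats::runif(1, 3e-3, 2e-2), stats::runif(1, 0.02, 0.3))
    pr <- breathing_protocol("sine", stats::runif(1, 1e-4, 1e-3),
      period = stats::runif(1, 2, 10)
    )
    w <- hysteresis_width(duct, air_cfd, pr)
    r_hp <- hagen_poiseuille_resistance(duct, air_cfd)
    expect_equal(
      relative_hysteresis_width(duct, pr, air_cfd),
      w / (r_hp * pr$peak_flowrate),
      tolerance = 1e-10
    )
  }
})

test_that("Womersley number has the square-root frequency scaling", {
  expect_equal(womersley_number(0.005, 0, air_rounded), 0)
  wo <- womersley_number(0.005, 0.2, air_rounded)
  expect_equal(wo, 0.7236, tolerance = 1e-4)
  expect_equal(womersley_number(0.005, 0.8, air_rounded), 2 * wo,
    tolerance = 1e-12
  )
})

test_that("dimensionless groups are invariant under consistent unit rescaling", {
  # rescale lengths by lambda, times by theta; Q ~ L^3/T, nu ~ L^2/T, f ~ 1/T
  lambda <- 3.7
  theta <- 2.3
  dh <- 0.008
  q <- 4e-4
  nu <- 1.4e-5
  tau <- 4
  base_fluid <- fluid_properties(1, nu)
  scaled_fluid <- fluid_properties(1, nu * lambda^2 / theta)
  expect_equal(
    reynolds_number(q, duct_model(dh, 0.1), base_fluid),
    reynolds_number(
      q * lambda^3 / theta,
      duct_model(dh * lambda, 0.1 * lambda), scaled_fluid
    ),
    tolerance = 1e-12
  )
  expect_equal(
    womersley_number(dh, 1 / tau, base_fluid),
    womersley_number(dh * lambda, 1 / (tau * theta), scaled_fluid),
    tolerance = 1e-12
  )
  expect_equal(
    relative_hysteresis_width(dh, tau, base_fluid),
    relative_hysteresis_width(dh * lambda, tau * theta, scaled_fluid),
    tolerance = 1e-12
  )
})

test_that("duct construction from a cross-section applies Dh = 4A/O", {
  r <- 0.004
  circ <- duct_from_cross_section(pi * r^2, 2 * pi * r, length = 0.1)
  expect_equal(circ$hydraulic_diameter, 2 * r, tolerance = 1e-12)
  a <- 0.003
  sq <- duct_from_cross_section(a^2, 4 * a, length = 0.1)
  expect_equal(sq$hydraulic_diameter, a, tolerance = 1e-12)
  expect_equal(hydraulic_diameter(1e-4, 0.05), 8e-3)
})
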