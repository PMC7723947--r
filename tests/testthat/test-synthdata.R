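# independent power-series evaluation of J0, valid for moderate |z|
j0_series <- function(z, terms = 80) {
  s <- 0 + 0i; term <- 1 + 0i
  for (k in 0:terms) {
    if (k > 0) term <- term * (-(z / 2)^2) / k^2
    s <- s + term
  }
  s
}

test_that("constant flow gives the exact Poiseuille profile", {
  sc <- patient_scenario()
  t <- seq(0, 0.999, by = 1e-3)
  cw <- flow_waveform(t, rep(100, length(t)), 1)
  ev <- womersley_velocity(cw, sc$tube, sc$fluid, K = 3)
  R <- sc$tube$radius
  r <- seq(0, R, length.out = 101)
  u <- ev(r, c(0, 0.37))
  exact <- 2 * 100e-6 / (pi * R^2) * (1 - (r / R)^2)
  expect_lt(max(abs(u - exact)), 1e-12)
})

test_that("the Womersley evaluator satisfies no-slip at the wall", {
  ev <- patient_womersley()
  R <- attr(ev, "radius")
  expect_lt(max(abs(ev(R, seq(0, 0.81, by = 0.027)))), 1e-12)
})

test_that("complex Bessel evaluation agrees with an independent power series", {
  # oscillatory-flow argument at Womersley number 20
  z <- 20 * exp(1i * 3 * pi / 4) * seq(0.05, 1, by = 0.05)
  impl <- hemowk:::besselJ_complex(z, 0L)
  orac <- vapply(z, j0_series, complex(1))
  expect_lt(max(abs(impl - orac) / abs(orac)), 1e-8)
  # real-argument cross-check against base R
  x <- c(0.5, 1.8, 7.3)
  expect_equal(Re(hemowk:::besselJ_complex(x + 0i, 0L)), besselJ(x, 0),
               tolerance = 1e-12)
  expect_equal(Re(hemowk:::besselJ_complex(x + 0i, 1L)), besselJ(x, 1),
               tolerance = 1e-12)
})

test_that("a single-harmonic profile matches the analytic annular solution", {
  sc <- patient_scenario()
  fluid <- sc$fluid
  R <- 0.01
  tube <- tube_spec(radius = R)
  Tp <- 2 * pi * fluid$density * R^2 / (400 * fluid$viscosity)  # alpha = 20
  t <- (0:511) * Tp / 512
  qa <- 50  # mL/s amplitude
  w <- flow_waveform(t, 100 + qa * cos(2 * pi * t / Tp), Tp)
  ev <- womersley_velocity(w, tube, fluid, K = 2)
  expect_equal(attr(ev, "alpha")[1], 20, tolerance = 1e-9)

  Lam <- 20 * exp(1i * 3 * pi / 4)
  r <- seq(0, R, length.out = 41)
  J0L <- j0_series(Lam)
  shape <- (1 - vapply(Lam * r / R, j0_series, complex(1)) / J0L)
  # flow integral of the shape: 1 - 2 J1(L)/(L J0(L)); J1 via series
  j1_series <- function(z, terms = 80) {
    s <- 0 + 0i; term <- z / 2
    for (k in 0:terms) {
      if (k > 0) term <- term * (-(z / 2)^2) / (k * (k + 1))
      s <- s + term
    }
    s
  }
  flow_fac <- 1 - 2 * j1_series(Lam) / (Lam * J0L)
  tt <- c(0, Tp / 3, Tp / 2)
  exact <- 2 * 100e-6 / (pi * R^2) * (1 - (r / R)^2) +
    Re(outer(shape / (pi * R^2 * flow_fac) * qa * 1e-6,
             exp(1i * 2 * pi * tt / Tp)))
  expect_lt(max(abs(ev(r, tt) - exact)), 1e-8)
  # oscillatory annular profile is flatter than a parabola in the core
  osc <- Re(shape / flow_fac)
  expect_lt(max(osc) / mean(osc[r < 0.9 * R]), 1.5)
})

test_that("cross-section integration reproduces the prescribed flow to 0.1%", {
  sc <- patient_scenario()
  w <- patient_waveform_adjusted()
  ev <- patient_womersley()
  R <- sc$tube$radius
  r <- seq(0, R, length.out = 4001)
  tt <- w$time[seq(1, length(w$time), by = 41)]
  u <- ev(r, tt)
  Q <- apply(u, 2, function(uu) {
    g <- uu * r
    2 * pi * sum((g[-1] + g[-length(g)]) / 2) * (r[2] - r[1])
  }) * 1e6
  Qw <- stats::approx(c(w$time, w$period), c(w$flow, w$flow[1]), xout = tt)$y
  expect_lt(max(abs(Q - Qw)) / max(abs(Qw)), 1e-3)
})

test_that("plane ensembles have the expected frame structure and determinism", {
  sc <- patient_scenario()
  # uniform-flow evaluator: all frames identical
  t <- seq(0, 0.999, by = 1e-3)
  cw <- flow_waveform(t, rep(100, length(t)), 1)
  evc <- womersley_velocity(cw, sc$tube, sc$fluid, K = 2)
  ens <- plane_field_ensemble(evc, sc$tube, nx = 10, ny = 15, frame_rate = 8,
                              n_cycles = 2)
  expect_identical(ens$frames_per_cycle, 8L)
  expect_equal(ens$frames[[1]]$u, ens$frames[[5]]$u)

  # patient waveform at 22 Hz: 18 phases, 10 cycles -> 180 frames
  ens2 <- plane_field_ensemble(patient_womersley(), sc$tube, nx = 8, ny = 11,
                               frame_rate = 22, n_cycles = 10)
  expect_identical(ens2$frames_per_cycle, 18L)
  expect_length(ens2$frames, 180L)

  # deterministic: regenerating gives identical values
  ens3 <- plane_field_ensemble(patient_womersley(), sc$tube, nx = 8, ny = 11,
                               frame_rate = 22, n_cycles = 10)
  expect_identical(ens2$frames[[37]]$u, ens3$frames[[37]]$u)
})

test_that("noise injection is seeded, reproducible and mask-preserving", {
  sc <- patient_scenario()
  ens <- plane_field_ensemble(patient_womersley(), sc$tube, nx = 10, ny = 15,
                              frame_rate = 22, n_cycles = 2)
  # zero noise is the identity
  same <- add_measurement_noise(ens, noise_spec(sigma = 0, outlier_fraction = 0,
                                                cycle_gain_sd = 0, seed = 1))
  expect_equal(same$frames[[7]]$u, ens$frames[[7]]$u)

  spec <- noise_spec(sigma = 0.02, outlier_fraction = 0.03, seed = 99)
  n1 <- add_measurement_noise(ens, spec)
  n2 <- add_measurement_noise(ens, spec)
  expect_identical(n1$frames[[5]]$u, n2$frames[[5]]$u)
  expect_identical(attr(n1, "outlier_truth"), attr(n2, "outlier_truth"))
  expect_identical(n1$frames[[5]]$valid, ens$frames[[5]]$valid)
  expect_identical(n1$frames[[5]]$x, ens$frames[[5]]$x)
  # a different seed changes the draw
  n3 <- add_measurement_noise(ens, noise_spec(sigma = 0.02, outlier_fraction = 0.03,
                                              seed = 100))
  expect_false(identical(n1$frames[[5]]$u, n3$frames[[5]]$u))
})

test_that("valve ringing attenuates downstream and filters away cleanly", {
  Tp <- 0.82; fs <- 200
  t <- seq(0, Tp - 1 / fs, by = 1 / fs)
  base <- pressure_waveform(t, 110 + 25 * sin(2 * pi * t / Tp - 0.7), Tp)
  spec <- valve_ring_spec()

  none <- synth_pressure_with_ringing(base, valve_ring_spec(amplitude = 0))
  expect_equal(none$pressure, base$pressure)

  s1 <- synth_pressure_with_ringing(base, spec, station = 1)
  s2 <- synth_pressure_with_ringing(base, spec, station = 2)
  e1 <- sum((s1$pressure - base$pressure)^2)
  e2 <- sum((s2$pressure - base$pressure)^2)
  expect_lt(e2, e1)

  filt <- savitzky_golay_filter(s1)
  i0 <- extract_pressure_indices(base)
  i1 <- extract_pressure_indices(filt)
  expect_lt(abs(i1$P_sys - i0$P_sys), 1)
  expect_lt(abs(i1$P_dia - i0$P_dia), 1)

  expect_error(valve_ring_spec(frequency = 150), "Nyquist")
})

test_that("the patient fixture carries the published values consistently", {
  sc <- patient_scenario()
  expect_equal(sc$targets$P_sys, 150)
  expect_equal(sc$targets$P_dia, 80)
  expect_equal(sum(sc$targets$flows), sc$targets$Q_in)
  expect_equal(sc$network$branches[["DA"]]$wk$R2, 1.15)
  expect_equal(sc$network$branches[["BT"]]$wk$R1, 0.25)
  expect_equal(sc$fluid$density, 1310)
  expect_equal(sc$fluid$viscosity, 2.2e-3)
  expect_equal(sc$waveform_spec$stroke_volume, 107.6, tolerance = 1e-9)
  # byte-stable across calls
  expect_identical(sc, patient_scenario())
})
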