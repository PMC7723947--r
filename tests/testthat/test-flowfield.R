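# small deterministic ensemble used across phase-averaging tests
small_ensemble <- function(n_cycles = 5) {
  sc <- patient_scenario()
  tube <- tube_spec(radius = sc$tube$radius, length = 0.03)
  plane_field_ensemble(patient_womersley(), tube, nx = 24, ny = 31,
                       frame_rate = 22, n_cycles = n_cycles)
}

test_that("phase averaging of identical cycles is the identity with zero SD", {
  ens <- small_ensemble(5)
  pa <- phase_average(ens)
  for (p in c(1, 9, 18)) {
    expect_equal(pa$u_mean[, , p], ens$frames[[p]]$u)
    expect_lt(max(pa$u_sd[, , p]), 1e-12)
  }
  expect_true(all(pa$n == 5))
})

test_that("a single cycle yields mean = cycle and SD = 0 with n = 1", {
  ens <- small_ensemble(1)
  pa <- phase_average(ens)
  expect_equal(pa$u_mean[, , 3], ens$frames[[3]]$u)
  expect_true(all(pa$u_sd == 0))
  expect_true(all(pa$n == 1))
})

test_that("phase-averaged SD estimates recover the injected noise level", {
  ens <- small_ensemble(10)
  noisy <- add_measurement_noise(ens, noise_spec(sigma = 0.03, seed = 42))
  pa <- phase_average(noisy)
  # per-point SD estimates from 10 cycles scatter; their central tendency
  # must sit within 25% of the injected sigma
  expect_lt(abs(median(pa$u_sd) - 0.03) / 0.03, 0.25)
  expect_lt(abs(mean(pa$u_sd) - 0.03) / 0.03, 0.25)
})

test_that("convergence variation vanishes for identical cycles and grows with noise", {
  ens <- small_ensemble(8)
  cc0 <- convergence_curve(ens)
  expect_lt(max(cc0$variation), 1e-9)

  n1 <- add_measurement_noise(ens, noise_spec(sigma = 0.02, cycle_gain_sd = 0, seed = 5))
  n2 <- add_measurement_noise(ens, noise_spec(sigma = 0.04, cycle_gain_sd = 0, seed = 5))
  c1 <- convergence_curve(n1)
  c2 <- convergence_curve(n2)
  expect_true(all(c2$variation > c1$variation))
})

test_that("normalized median test flags an isolated spike and nothing else", {
  u <- matrix(1, 15, 15)
  v <- matrix(0, 15, 15)
  f0 <- velocity_field(seq_len(15) * 1e-3, seq_len(15) * 1e-3, u, v)
  clean <- normalized_median_filter(f0)
  expect_true(!any(clean$flags))

  u[8, 8] <- 10
  f1 <- velocity_field(seq_len(15) * 1e-3, seq_len(15) * 1e-3, u, v)
  res <- normalized_median_filter(f1, eps = 0.02)
  expect_identical(which(res$flags), which(u == 10))
})

test_that("flag sets are monotone in the threshold", {
  sc <- patient_scenario()
  ens <- small_ensemble(1)
  noisy <- add_measurement_noise(ens, noise_spec(sigma = 0.05, seed = 9))
  f <- noisy$frames[[5]]
  hi <- normalized_median_filter(f, threshold = 3)$flags
  lo <- normalized_median_filter(f, threshold = 1.5)$flags
  expect_true(all(lo[hi]))
})

test_that("labelled synthetic outliers are recovered at the standard settings", {
  st <- outlier_filter_stats()
  expect_true(all(st$recall >= 0.95))
  expect_true(all(st$fpr <= 0.02))
})

test_that("profile extraction is exact on uniform and shear fields", {
  x <- seq(0, 0.02, length.out = 21)
  y <- seq(0, 0.03, length.out = 31)
  uni <- velocity_field(x, y, matrix(1, 31, 21), matrix(0, 31, 21))
  # downward vertical line: normal is +x
  line <- profile_line(c(0.01, 0.028), c(0.01, 0.002), n = 200)
  expect_equal(line$normal, c(1, 0))
  prof <- extract_profile(uni, line)
  expect_true(all(abs(prof$u_n - 1) < 1e-12))

  a <- 50
  shear <- velocity_field(x, y, matrix(rep(a * y, 21), 31, 21), matrix(0, 31, 21))
  prof2 <- extract_profile(shear, line)
  yy <- 0.028 - prof2$s
  expect_equal(prof2$u_n, a * yy, tolerance = 1e-12)

  # rotated line in the same shear field: u_n = u(y(s)) * n_x
  p0 <- c(0.004, 0.004); p1 <- c(0.016, 0.025)
  line3 <- profile_line(p0, p1, n = 150)
  prof3 <- extract_profile(shear, line3)
  ys <- p0[2] + prof3$s * line3$direction[2]
  expect_equal(prof3$u_n, a * ys * line3$normal[1], tolerance = 1e-10)

  expect_error(extract_profile(uni, profile_line(c(1, 1), c(2, 2))), "outside")
})

test_that("the profile-difference metric matches hand evaluations", {
  pe <- velocity_profile(c(0, 0.5, 1), c(1, 2, 3))
  pc <- velocity_profile(c(0, 0.5, 1), c(2, 2, 2))
  expect_equal(delta_metric(pe, pc, n = 3)$delta, 100 * (1 + 0 + 1) / 3 / 2,
               tolerance = 1e-10)
  expect_equal(delta_metric(pc, pc, n = 3)$delta, 0)
  pe2 <- velocity_profile(c(0, 1), c(0, 0))
  pc2 <- velocity_profile(c(0, 1), c(1, -1))
  expect_equal(delta_metric(pe2, pc2, n = 2)$delta, 100, tolerance = 1e-10)
  expect_error(delta_metric(pe, velocity_profile(c(0, 0.5, 1), c(0, 0, 0)), n = 3),
               "normaliser")
})

test_that("the profile-difference metric is scale- but not shift-invariant", {
  set.seed(21)
  s <- seq(0, 1, length.out = 50)
  pe <- velocity_profile(s, sin(2 * pi * s) + rnorm(50, 0, 0.1))
  pc <- velocity_profile(s, sin(2 * pi * s))
  d0 <- delta_metric(pe, pc, n = 50)$delta
  k <- 3.7
  dk <- delta_metric(velocity_profile(s, k * pe$u_n),
                     velocity_profile(s, k * pc$u_n), n = 50)$delta
  expect_equal(dk, d0, tolerance = 1e-10)
  dc <- delta_metric(velocity_profile(s, pe$u_n + 2),
                     velocity_profile(s, pc$u_n + 2), n = 50)$delta
  expect_false(isTRUE(all.equal(dc, d0, tolerance = 1e-6)))
})

test_that("axisymmetric integration reproduces closed-form flow rates", {
  R <- 0.015
  s <- seq(0, 2 * R, length.out = 1001)
  r <- abs(s - R)
  uni <- velocity_profile(s, rep(0.5, length(s)))
  expect_equal(axisymmetric_flow_rate(uni, R), pi * R^2 * 0.5 * 1e6,
               tolerance = 5e-3)
  u0 <- 0.8
  pois <- velocity_profile(s, u0 * (1 - (r / R)^2))
  expect_equal(axisymmetric_flow_rate(pois, R), pi * R^2 * u0 / 2 * 1e6,
               tolerance = 5e-3)
  expect_error(axisymmetric_flow_rate(uni, 3 * R), "axis")
})

test_that("flow-rate integration converges at second order in resolution", {
  R <- 0.015; u0 <- 0.8
  exact <- pi * R^2 * u0 / 2 * 1e6
  err <- vapply(c(51, 101, 201), function(n) {
    s <- seq(0, 2 * R, length.out = n)
    r <- abs(s - R)
    abs(axisymmetric_flow_rate(velocity_profile(s, u0 * (1 - (r / R)^2)), R,
                               n_radial = (n + 1) %/% 2) - exact)
  }, 0)
  ratio <- err[-length(err)] / err[-1]
  expect_true(all(ratio > 3 & ratio < 5.5))
})

test_that("Womersley chords recover the generator flow within 1%", {
  sc <- patient_scenario()
  w <- patient_waveform_adjusted()
  ens <- plane_field_ensemble(patient_womersley(), sc$tube, nx = 40, ny = 201,
                              frame_rate = 22, n_cycles = 1)
  R <- sc$tube$radius
  qfun <- approxfun(c(w$time, w$period), c(w$flow, w$flow[1]))
  for (p in c(3, 6, 12)) {
    f <- ens$frames[[p]]
    # downward chord: the +90-degree normal points along +x (the tube axis)
    line <- profile_line(c(f$x[20], R), c(f$x[20], -R), n = 1001)
    prof <- extract_profile(f, line)
    Q <- axisymmetric_flow_rate(prof, R)
    expect_equal(Q, qfun((p - 1) / 22), tolerance = 0.01)
  }
})

test_that("mass-conservation error matches its definition", {
  expect_equal(mass_conservation_error(c(100, 100, 100)), 0)
  expect_equal(mass_conservation_error(c(100, 95)), 5 / 97.5 * 100,
               tolerance = 1e-10)
  expect_equal(mass_conservation_error(c(100, 95), method = "sd"),
               stats::sd(c(100, 95)) / 97.5 * 100, tolerance = 1e-10)

  # 28 successive chords through one Womersley frame agree to < 1%
  sc <- patient_scenario()
  ens <- plane_field_ensemble(patient_womersley(), sc$tube, nx = 56, ny = 201,
                              frame_rate = 22, n_cycles = 1)
  f <- ens$frames[[6]]
  R <- sc$tube$radius
  flows <- vapply(seq(2, 56, by = 2), function(j) {
    prof <- extract_profile(f, profile_line(c(f$x[j], R), c(f$x[j], -R), n = 501))
    axisymmetric_flow_rate(prof, R)
  }, 0)
  expect_length(flows, 28L)
  expect_lt(mass_conservation_error(flows), 1)
})
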