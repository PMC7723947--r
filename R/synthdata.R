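#' Straight-tube stand-in geometry
#'
#' Circular rigid tube used by the synthetic field generator; the analytic
#' Womersley solution holds there, making generated fields exact oracles.
#'
#' @param radius tube radius R, m.
#' @param length imaged section length along the axis, m (default 0.1).
#' @return object of class `tube_spec`.
#' @export
tube_spec <- function(radius, length = 0.1) {
  if (radius <= 0 || length <= 0) stop("radius and length must be positive")
  structure(list(radius = radius, length = length), class = "tube_spec")
}

#' Measurement-noise specification
#'
#' Error sources emulating a planar PIV acquisition: i.i.d. Gaussian noise on
#' both components, a fraction of spurious-vector outliers of large amplitude,
#' and a per-cycle multiplicative gain emulating inter-cycle variability.
#'
#' @param sigma Gaussian noise SD, m/s (default 0.03).
#' @param outlier_fraction fraction of valid vectors replaced by outliers per
#'   frame, in `[0, 1)` (default 0).
#' @param outlier_amplitude outlier magnitude as a multiple of the ensemble's
#'   maximum speed (default 5).
#' @param cycle_gain_sd relative SD of the per-cycle gain (default 0.01).
#' @param seed integer RNG seed (default 1).
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0.03, outlier_fraction = 0,
                       outlier_amplitude = 5, cycle_gain_sd = 0.01, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must be in [0, 1)")
  structure(list(sigma = sigma, outlier_fraction = outlier_fraction,
                 outlier_amplitude = outlier_amplitude,
                 cycle_gain_sd = cycle_gain_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Valve-ringing specification
#'
#' Damped oscillation bursts superimposed on pressure signals at the opening
#' and closing of a mechanical valve (start of systole and of diastole), with
#' amplitude attenuating at stations further downstream. Frequency and decay
#' defaults (20 Hz, 0.05 s) are package choices placed below the Nyquist
#' frequency of the 200 Hz pressure acquisition.
#'
#' @param frequency ringing frequency, Hz (default 20).
#' @param decay decay time constant, s (default 0.05).
#' @param amplitude burst amplitude at the first station, mmHg (default 5).
#' @param attenuation amplitude factor per downstream station, in (0, 1]
#'   (default 0.6).
#' @param sampling_rate pressure sampling rate, Hz (default 200); the ringing
#'   frequency must be below its Nyquist frequency.
#' @return object of class `valve_ring_spec`.
#' @export
valve_ring_spec <- function(frequency = 20, decay = 0.05, amplitude = 5,
                            attenuation = 0.6, sampling_rate = 200) {
  if (frequency >= sampling_rate / 2)
    stop("ringing frequency must be below the Nyquist frequency of the sampling")
  if (attenuation <= 0 || attenuation > 1) stop("attenuation must be in (0, 1]")
  structure(list(frequency = frequency, decay = decay, amplitude = amplitude,
                 attenuation = attenuation, sampling_rate = sampling_rate),
            class = "valve_ring_spec")
}

# Bessel function of the first kind, integer order, complex argument, via the
# contour-integral representation J_n(z) = (1/2pi) int_0^2pi e^{i z sin t} e^{-i n t} dt,
# evaluated with the periodic trapezoid rule (spectrally accurate; M chosen
# comfortably above |z|).
besselJ_complex <- function(z, n = 0L, M = 1024L) {
  theta <- 2 * pi * (0:(M - 1L)) / M
  s <- sin(theta)
  e_nt <- exp(-1i * n * theta)
  vapply(z, function(zz) mean(exp(1i * zz * s) * e_nt), complex(1))
}

#' Analytical Womersley velocity evaluator
#'
#' Builds the exact axial velocity u(r, t) of fully developed pulsatile flow
#' in a rigid circular tube carrying the given flow waveform. The steady
#' Fourier component drives a Poiseuille profile; each harmonic k is the
#' annular Womersley solution built from order-zero Bessel functions of
#' complex argument, rescaled so that its cross-section-integrated flow equals
#' the waveform's k-th Fourier coefficient exactly. The evaluator therefore
#' reproduces the K-harmonic truncation of Q(t) identically and satisfies
#' no-slip u(R, t) = 0 by construction.
#'
#' @param waveform a [flow_waveform()] (mL/s).
#' @param tube a [tube_spec()].
#' @param fluid a [fluid_properties()].
#' @param K number of harmonics retained (default 10); must stay below the
#'   waveform's Nyquist harmonic.
#' @return a function `u(r, t)` (r in metres, t in seconds, both vectorised;
#'   returns an `length(r) x length(t)` matrix in m/s) with attributes
#'   `harmonics` (complex flow coefficients, m^3/s) and `alpha` (Womersley
#'   numbers per harmonic).
#' @export
womersley_velocity <- function(waveform, tube, fluid, K = 10L) {
  stopifnot(inherits(waveform, "flow_waveform"), inherits(tube, "tube_spec"),
            inherits(fluid, "fluid_properties"))
  if (K < 1L) stop("K must be >= 1")
  N <- length(waveform$flow)
  if (K >= N / 2) stop("K exceeds the waveform's Nyquist harmonic")
  Tp <- waveform$period
  R <- tube$radius
  A <- pi * R^2
  q_m3 <- waveform$flow * 1e-6
  # one-sided Fourier coefficients: Q(t) ~ Q0 + sum_k Re(Qk e^{i k w t})
  ft <- stats::fft(q_m3) / N
  Q0 <- Re(ft[1L])
  Qk <- 2 * ft[2:(K + 1L)]
  omega <- 2 * pi / Tp
  nu <- fluid$viscosity / fluid$density
  alpha <- R * sqrt((1:K) * omega / nu)
  Lam <- alpha * exp(1i * 3 * pi / 4)  # i^{3/2} alpha
  J0L <- besselJ_complex(Lam, 0L)
  J1L <- besselJ_complex(Lam, 1L)
  # flow factor of the unit-pressure-gradient profile shape
  shape_flow <- 1 - 2 * J1L / (Lam * J0L)
  f <- function(r, t) {
    r <- pmin(abs(r), R)
    steady <- 2 * Q0 / A * (1 - (r / R)^2)
    out <- matrix(0, length(r), length(t))
    out[] <- rep(steady, times = length(t))
    for (k in seq_len(K)) {
      prof <- (1 - besselJ_complex(Lam[k] * r / R, 0L) / J0L[k]) /
        (A * shape_flow[k])
      out <- out + Re(outer(prof * Qk[k], exp(1i * k * omega * t)))
    }
    out
  }
  attr(f, "harmonics") <- c(Q0, Qk)
  attr(f, "alpha") <- alpha
  attr(f, "radius") <- R
  attr(f, "period") <- Tp
  class(f) <- c("womersley_evaluator", "function")
  f
}

#' Noise-free planar field ensemble from a velocity evaluator
#'
#' Samples the axial-plane velocity of a straight tube on a regular grid at
#' the acquisition frame times: x runs along the tube axis over the section
#' length, y across the lumen in [-R, R], and the axial component
#' u(x, y, t) = u_eval(|y|, t) is independent of x (fully developed flow);
#' the cross-plane component v is 0. Frame k is taken at t = (k-1)/f, giving
#' `round(T*f)` phases per cycle. Deterministic.
#'
#' @param evaluator a [womersley_velocity()] evaluator (or any `u(r, t)`
#'   function with a `radius` attribute).
#' @param tube a [tube_spec()].
#' @param nx,ny grid size (defaults 200 x 150, a 20x downscale of a
#'   4000 x 3000 px camera).
#' @param frame_rate acquisition rate f, Hz.
#' @param n_cycles number of cycles.
#' @param period cycle length, s (default: the evaluator's period).
#' @return a [cycle_ensemble()].
#' @export
plane_field_ensemble <- function(evaluator, tube, nx = 200L, ny = 150L,
                                 frame_rate, n_cycles, period = NULL) {
  stopifnot(inherits(tube, "tube_spec"))
  if (nx < 2L || ny < 2L) stop("degenerate grid")
  if (is.null(period)) period <- attr(evaluator, "period")
  fpc <- as.integer(round(period * frame_rate))
  if (fpc < 4L) stop("need at least 4 phases per cycle")
  R <- tube$radius
  x <- seq(0, tube$length, length.out = nx)
  y <- seq(-R, R, length.out = ny)
  # velocity depends only on |y| and phase
  phase_t <- (0:(fpc - 1L)) / frame_rate
  uy <- evaluator(abs(y), phase_t)  # ny x fpc
  frames <- vector("list", fpc * n_cycles)
  for (k in seq_along(frames)) {
    p <- (k - 1L) %% fpc + 1L
    u <- matrix(uy[, p], ny, nx)
    frames[[k]] <- velocity_field(x, y, u, matrix(0, ny, nx),
                                  phase = p, cycle = (k - 1L) %/% fpc + 1L)
  }
  cycle_ensemble(frames, frame_rate, period, n_cycles)
}

#' Inject measurement noise into a field ensemble
#'
#' Adds, reproducibly for a given seed: a per-cycle multiplicative gain
#' (inter-cycle variability), i.i.d. Gaussian noise on both components, and a
#' fraction of spurious-vector outliers of amplitude
#' `outlier_amplitude * max speed` in a random direction. Masks and grid
#' geometry are preserved exactly; the outlier locations are returned as
#' ground truth.
#'
#' @param ensemble a [cycle_ensemble()].
#' @param spec a [noise_spec()].
#' @return a [cycle_ensemble()] with attribute `outlier_truth`: a list of
#'   logical matrices (one per frame) marking injected outliers.
#' @export
add_measurement_noise <- function(ensemble, spec) {
  stopifnot(inherits(ensemble, "cycle_ensemble"), inherits(spec, "noise_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  max_speed <- max(vapply(ensemble$frames,
                          function(f) max(sqrt(f$u^2 + f$v^2)[f$valid]), 0))
  gains <- 1 + stats::rnorm(ensemble$n_cycles, 0, spec$cycle_gain_sd)
  fpc <- ensemble$frames_per_cycle
  truth <- vector("list", length(ensemble$frames))
  frames <- ensemble$frames
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    cyc <- (k - 1L) %/% fpc + 1L
    ny <- length(f$y); nx <- length(f$x)
    u <- gains[cyc] * f$u + matrix(stats::rnorm(ny * nx, 0, spec$sigma), ny, nx)
    v <- gains[cyc] * f$v + matrix(stats::rnorm(ny * nx, 0, spec$sigma), ny, nx)
    flags <- matrix(FALSE, ny, nx)
    if (spec$outlier_fraction > 0) {
      idx_valid <- which(f$valid)
      n_out <- round(spec$outlier_fraction * length(idx_valid))
      if (n_out > 0) {
        pick <- sample(idx_valid, n_out)
        ang <- stats::runif(n_out, 0, 2 * pi)
        amp <- spec$outlier_amplitude * max_speed
        u[pick] <- amp * cos(ang)
        v[pick] <- amp * sin(ang)
        flags[pick] <- TRUE
      }
    }
    frames[[k]] <- velocity_field(f$x, f$y, u, v, f$valid, f$phase, f$cycle)
    truth[[k]] <- flags
  }
  out <- cycle_ensemble(frames, ensemble$frame_rate, ensemble$period,
                        ensemble$n_cycles)
  attr(out, "outlier_truth") <- truth
  out
}

#' Superimpose valve-ringing oscillations on a pressure waveform
#'
#' Adds two exponentially damped sinusoid bursts — at the onset of systole
#' (valve opening) and at the onset of diastole (valve closing) — whose
#' amplitude is attenuated by `attenuation^(station - 1)` at downstream
#' measurement stations.
#'
#' @param base a [pressure_waveform()].
#' @param spec a [valve_ring_spec()].
#' @param systole_onset burst 1 start time, s (default 0).
#' @param systole_offset burst 2 start time, s (default T/3); both must lie
#'   inside the cycle.
#' @param station 1-based downstream station index (default 1).
#' @return a [pressure_waveform()].
#' @export
synth_pressure_with_ringing <- function(base, spec, systole_onset = 0,
                                        systole_offset = base$period / 3,
                                        station = 1L) {
  stopifnot(inherits(base, "pressure_waveform"), inherits(spec, "valve_ring_spec"))
  Tp <- base$period
  if (systole_onset < 0 || systole_onset >= Tp ||
      systole_offset <= 0 || systole_offset >= Tp)
    stop("burst onsets must lie inside the cycle")
  amp <- spec$amplitude * spec$attenuation^(station - 1L)
  burst <- function(t0) {
    dt_ <- (base$time - t0) %% Tp
    amp * exp(-dt_ / spec$decay) * sin(2 * pi * spec$frequency * dt_)
  }
  p <- base$pressure
  if (amp > 0) p <- p + burst(systole_onset) + burst(systole_offset)
  pressure_waveform(base$time, p, Tp)
}

#' The in-paper patient fixture
#'
#' Byte-stable bundle of the personalisation fixture used throughout the
#' tests: the clinical target set (systolic/diastolic pressure and branch
#' mean flows), the published outlet Windkessel parameter set, the inlet
#' waveform specification, acquisition rates, blood-mimicking fluid
#' properties, and the tube geometry implied by the reported mean Reynolds
#' number.
#'
#' @return list with `targets` ([target_set()]), `network`
#'   ([aortic_network()]), `waveform_spec` ([waveform_spec()]), `acquisition`
#'   (PIV frame rate 22 Hz, pressure sampling 200 Hz), `fluid`
#'   (rho = 1310 kg/m^3, mu = 2.2e-3 Pa s) and `tube`.
#' @export
patient_scenario <- function() {
  targets <- target_set(P_sys = 150, P_dia = 80,
                        flows = c(BT = 22.5, LCC = 8.9, LSA = 9.8, DA = 93.3),
                        Q_in = 134.5)
  network <- aortic_network(list(
    branch_spec("BT", windkessel_params(0.25, 6.00, 0.30)),
    branch_spec("LCC", windkessel_params(0.63, 10.00, 0.07)),
    branch_spec("LSA", windkessel_params(0.57, 10.00, 0.07)),
    branch_spec("DA", windkessel_params(0.01, 1.15, 0.30))))
  fluid <- fluid_properties(density = 1310, viscosity = 2.2e-3)
  # inlet diameter implied by the mean Reynolds number 3472 at 134.5 mL/s
  D <- 4 * fluid$density * 134.5e-6 / (pi * fluid$viscosity * 3472)
  list(targets = targets,
       network = network,
       waveform_spec = waveform_spec(period = 0.8, mean_flow = 134.5),
       acquisition = list(piv_frame_rate = 22, pressure_sampling = 200),
       fluid = fluid,
       tube = tube_spec(radius = D / 2))
}
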