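#' Periodic flow waveform
#'
#' Container for a uniformly sampled pulsatile flow waveform over one cardiac
#' cycle. Time starts at 0 and ends strictly before the period `T`, so that
#' tiling copies of the series yields the periodic signal without duplicated
#' samples.
#'
#' @param time numeric vector of sample times in seconds, uniform grid
#'   starting at 0 and ending before `period`.
#' @param flow numeric vector of flow values in mL/s, same length as `time`.
#' @param period cycle length T in seconds.
#' @return an object of class `flow_waveform` with fields `time`, `flow`,
#'   `period` and `dt`.
#' @export
flow_waveform <- function(time, flow, period) {
  .check_waveform_grid(time, flow, period)
  structure(list(time = time, flow = flow, period = period,
                 dt = if (length(time) > 1L) time[2L] - time[1L] else period,
                 unit = "mL/s"),
            class = c("flow_waveform", "waveform"))
}

#' Periodic pressure waveform
#'
#' Uniformly sampled pressure signal in mmHg. The series may span several
#' cardiac cycles; `period` records the cycle length.
#'
#' @param time sample times in seconds (uniform grid from 0).
#' @param pressure pressure values in mmHg.
#' @param period cycle length in seconds.
#' @return an object of class `pressure_waveform`.
#' @export
pressure_waveform <- function(time, pressure, period) {
  .check_waveform_grid(time, pressure, period, one_cycle = FALSE)
  structure(list(time = time, pressure = pressure, period = period,
                 dt = if (length(time) > 1L) time[2L] - time[1L] else period,
                 unit = "mmHg"),
            class = c("pressure_waveform", "waveform"))
}

.check_waveform_grid <- function(time, values, period, one_cycle = TRUE) {
  stopifnot(is.numeric(time), is.numeric(values), length(time) == length(values))
  if (!all(is.finite(time)) || !all(is.finite(values)))
    stop("waveform samples must be finite")
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stop("period must be a positive scalar")
  if (length(time) > 1L) {
    dts <- diff(time)
    if (any(abs(dts - dts[1L]) > 1e-9 * dts[1L] + 1e-12))
      stop("waveform requires a uniform sampling grid")
  }
  if (abs(time[1L]) > 1e-12) stop("waveform time must start at 0")
  if (one_cycle && time[length(time)] >= period - 1e-12)
    stop("waveform time must end strictly before the period")
  invisible(TRUE)
}

#' @export
print.waveform <- function(x, ...) {
  kind <- if (inherits(x, "flow_waveform")) "flow" else "pressure"
  vals <- if (kind == "flow") x$flow else x$pressure
  cat(sprintf("<%s_waveform> %d samples, dt = %.4g s, T = %.4g s, range [%.4g, %.4g] %s\n",
              kind, length(x$time), x$dt, x$period, min(vals), max(vals), x$unit))
  invisible(x)
}

#' Inlet waveform specification
#'
#' Clinical parameters defining a personalised aortic inlet waveform: cycle
#' length, mean flow and/or stroke volume, optional peak flow and the fraction
#' of the cycle occupied by systole. When both stroke volume and mean flow are
#' given they must be consistent (SV = mean flow x T within 0.5%).
#'
#' @param period cycle length T in seconds.
#' @param mean_flow cycle-averaged flow in mL/s (>= 0).
#' @param stroke_volume ejected volume per cycle in mL.
#' @param peak_flow optional peak systolic flow in mL/s.
#' @param systolic_fraction fraction of the cycle occupied by the systolic
#'   lobe, in (0, 1); default 1/3.
#' @return an object of class `waveform_spec`.
#' @export
waveform_spec <- function(period, mean_flow = NULL, stroke_volume = NULL,
                          peak_flow = NULL, systolic_fraction = 1 / 3) {
  if (period <= 0) stop("period must be positive")
  if (is.null(mean_flow) && is.null(stroke_volume))
    stop("one of mean_flow or stroke_volume is required")
  if (!is.null(mean_flow) && mean_flow < 0) stop("mean_flow must be >= 0")
  if (is.null(stroke_volume)) stroke_volume <- mean_flow * period
  if (is.null(mean_flow)) mean_flow <- stroke_volume / period
  if (stroke_volume > 0 &&
      abs(stroke_volume - mean_flow * period) > 0.005 * stroke_volume)
    stop("stroke_volume and mean_flow * period disagree by more than 0.5%")
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    stop("systolic_fraction must be in (0, 1)")
  structure(list(period = period, mean_flow = mean_flow,
                 stroke_volume = stroke_volume, peak_flow = peak_flow,
                 systolic_fraction = systolic_fraction),
            class = "waveform_spec")
}

#' Synthesise a personalised aortic inlet waveform
#'
#' Builds an analytical, strictly non-negative pulsatile waveform matching the
#' clinical parameters of a `waveform_spec`. The template is the sum of two
#' periodic raised-cosine-power lobes,
#' `q(t) = A ((1 + cos(2 pi (t - t0)/T))/2)^m + b ((1 + cos(2 pi (t - t1)/T))/2)^m2`,
#' a sharp systolic ejection lobe centred mid-systole and a wide, low
#' diastolic bump centred mid-diastole. The lobe power `m` is chosen so the
#' systolic lobe decays to 5% of its peak at the edges of
#' `systolic_fraction * T` (m = 10 for the default 1/3). Each lobe is a
#' trigonometric polynomial, so the waveform is exactly band-limited to
#' `max(m, m2)` harmonics — the Womersley field generator with K >= m
#' harmonics reproduces it without truncation error. Amplitudes are solved in
#' closed form so that the net ejected volume equals the stroke volume exactly
#' and, when `peak_flow` is supplied, the waveform maximum equals it.
#'
#' @param spec a [waveform_spec()].
#' @param dt sampling interval in seconds (default 1 ms).
#' @param diastolic_fraction fraction of the stroke volume carried by the
#'   diastolic bump when `peak_flow` is not prescribed; default 0.1.
#' @return a [flow_waveform()] over one period, with attribute `n_harmonics`
#'   (the exact band limit).
#' @export
synthesise_inlet_waveform <- function(spec, dt = 1e-3, diastolic_fraction = 0.1) {
  stopifnot(inherits(spec, "waveform_spec"))
  T <- spec$period
  SV <- spec$stroke_volume
  time <- seq(0, T - dt, by = dt)
  if (SV == 0) return(flow_waveform(time, rep(0, length(time)), T))
  s <- spec$systolic_fraction
  # lobe power: 5% of peak at the nominal systole edges +- s*T/2
  m <- max(2L, as.integer(round(log(0.05) / log((1 + cos(pi * s)) / 2))))
  m2 <- max(2L, as.integer(round(0.3 * m)))
  t0 <- s * T / 2                  # mid-systole
  t1 <- s * T + (1 - s) * T / 2    # mid-diastole
  lobe <- function(t, tc, mm) ((1 + cos(2 * pi * (t - tc) / T)) / 2)^mm
  # exact mean of ((1+cos)/2)^m over one period: C(2m, m) / 4^m
  c1 <- choose(2 * m, m) / 4^m
  c2 <- choose(2 * m2, m2) / 4^m2
  if (!is.null(spec$peak_flow)) {
    Qp <- spec$peak_flow
    if (Qp < spec$mean_flow)
      stop("infeasible waveform: peak_flow below mean flow")
    # peak sits at t0 (diastolic bump is ~0 there): solve the 2x2 system
    #   A * 1 + b * g = Qp ; A * c1 * T + b * c2 * T = SV
    g <- lobe(t0, t1, m2)
    det <- c2 * T - g * c1 * T
    A <- (Qp * c2 * T - g * SV) / det
    b <- (SV - A * c1 * T) / (c2 * T)
    if (A <= 0 || b < -1e-9 || b > A)
      stop("infeasible waveform: peak_flow incompatible with stroke volume and systolic fraction")
    b <- max(b, 0)
  } else {
    A <- (1 - diastolic_fraction) * SV / (c1 * T)
    b <- diastolic_fraction * SV / (c2 * T)
  }
  q <- A * lobe(time, t0, m) + b * lobe(time, t1, m2)
  w <- flow_waveform(time, q, T)
  attr(w, "n_harmonics") <- max(m, m2)
  w
}

#' Adjust the cycle length for compatibility with an acquisition frame rate
#'
#' Increases the period to the smallest multiple of `1/f` not shorter than the
#' requested period, so that a whole number of image frames fits in one cycle.
#'
#' @param period requested cycle length in seconds.
#' @param frame_rate acquisition frame rate f in Hz.
#' @return list with `T_exact` (= n/f), `T_rounded` (2 decimals) and
#'   `frames_per_cycle` (n).
#' @export
adjust_period_to_frame_rate <- function(period, frame_rate) {
  if (period <= 0 || frame_rate <= 0) stop("period and frame_rate must be positive")
  n <- ceiling(period * frame_rate - 1e-9)
  T_exact <- n / frame_rate
  list(T_exact = T_exact, T_rounded = round(T_exact, 2L), frames_per_cycle = as.integer(n))
}

#' Heart rate from the cycle length
#'
#' @param period cycle length in seconds.
#' @return heart rate in beats per minute, rounded to the nearest integer.
#' @export
heart_rate_bpm <- function(period) {
  if (period <= 0) stop("period must be positive")
  as.integer(round(60 / period))
}

#' Summary statistics of a flow waveform
#'
#' Mean flow is the time average over one period (periodic rectangle rule,
#' exact to trapezoid accuracy on the uniform one-cycle grid); net volume is
#' mean x T; forward volume integrates only the positive part of the signal.
#'
#' @param w a [flow_waveform()].
#' @return list with `mean`, `peak`, `min` (mL/s), `net_volume` and
#'   `forward_volume` (mL).
#' @export
waveform_stats <- function(w) {
  stopifnot(inherits(w, "flow_waveform"))
  if (length(w$flow) == 0L) stop("empty waveform")
  m <- mean(w$flow)
  list(mean = m, peak = max(w$flow), min = min(w$flow),
       net_volume = m * w$period,
       forward_volume = mean(pmax(w$flow, 0)) * w$period)
}

#' Systolic/diastolic pressure indices
#'
#' Extracts systolic (max) and diastolic (min) pressure over the final full
#' cycle of the series, the pulse pressure, and the mean arterial pressure
#' under the standard brachial estimate MAP = P_dia + PP/3.
#'
#' @param p a [pressure_waveform()] covering at least one full cycle.
#' @return list with `P_sys`, `P_dia`, `MAP`, `pulse_pressure` (mmHg).
#' @export
extract_pressure_indices <- function(p) {
  stopifnot(inherits(p, "pressure_waveform"))
  if (any(!is.finite(p$pressure))) stop("pressure series contains non-finite values")
  n_cycle <- max(1L, round(p$period / p$dt))
  n <- length(p$pressure)
  if (n < n_cycle) stop("pressure series shorter than one cycle")
  final <- p$pressure[(n - n_cycle + 1L):n]
  P_sys <- max(final); P_dia <- min(final)
  pp <- P_sys - P_dia
  list(P_sys = P_sys, P_dia = P_dia, MAP = P_dia + pp / 3, pulse_pressure = pp)
}

#' Fit the diastolic pressure decay time
#'
#' Log-linear least-squares fit of P(t) ~ P0 * exp(-t/tau) over a time window,
#' estimating the Windkessel time constant tau = R*C that governs the
#' exponential diastolic pressure fall (venous reference pressure assumed 0).
#'
#' @param p a [pressure_waveform()].
#' @param window numeric length-2 vector, start/end time of the fit window in
#'   seconds (inside the series).
#' @return list with `tau` (s), `P0` (mmHg) and `rss` (residual sum of squares
#'   of log-pressure).
#' @export
fit_decay_time <- function(p, window) {
  stopifnot(inherits(p, "pressure_waveform"), length(window) == 2L)
  sel <- p$time >= window[1L] - 1e-12 & p$time <= window[2L] + 1e-12
  if (sum(sel) < 3L) stop("fit window must contain at least 3 samples")
  t <- p$time[sel]; y <- p$pressure[sel]
  if (any(y <= 0)) stop("fit window contains non-positive pressures")
  fit <- stats::lm.fit(cbind(1, t), log(y))
  tau <- -1 / fit$coefficients[2L]
  list(tau = unname(tau), P0 = unname(exp(fit$coefficients[1L])),
       rss = sum(fit$residuals^2))
}

#' Savitzky-Golay smoothing of a pressure signal
#'
#' Local polynomial least-squares smoothing used to attenuate high-frequency
#' components (e.g. mechanical-valve ringing) in measured pressure signals.
#' Length-preserving; polynomials of degree <= `poly_order` pass unchanged.
#' Defaults assume the 200 Hz acquisition of the pressure transducers: a
#' 31-sample window (155 ms) with cubic fits.
#'
#' @param p a [pressure_waveform()].
#' @param window_samples odd window length in samples (default 31).
#' @param poly_order polynomial order (default 3), must be < `window_samples`.
#' @return a smoothed [pressure_waveform()] on the same grid.
#' @export
savitzky_golay_filter <- function(p, window_samples = 31L, poly_order = 3L) {
  stopifnot(inherits(p, "pressure_waveform"))
  if (window_samples %% 2L != 1L) stop("window_samples must be odd")
  if (poly_order >= window_samples) stop("poly_order must be smaller than window_samples")
  sm <- signal::sgolayfilt(p$pressure, p = poly_order, n = window_samples)
  pressure_waveform(p$time, sm, p$period)
}
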