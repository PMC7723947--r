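#' Three-element Windkessel parameters
#'
#' Lumped model of the distal vasculature seen by an aortic outlet: a proximal
#' resistance R1 in series with the parallel combination of a distal
#' resistance R2 and a compliance C. The time constant tau = R2*C sets the
#' diastolic pressure decay.
#'
#' @param R1 proximal resistance, mmHg s/mL (> 0).
#' @param R2 distal resistance, mmHg s/mL (> 0).
#' @param C compliance, mL/mmHg (> 0).
#' @return object of class `windkessel_params`.
#' @export
windkessel_params <- function(R1, R2, C) {
  if (any(c(R1, R2, C) <= 0)) stop("R1, R2 and C must all be positive")
  structure(list(R1 = R1, R2 = R2, C = C, tau = R2 * C),
            class = "windkessel_params")
}

#' Aortic branch specification
#'
#' One outlet of the network: a label (e.g. BT, LCC, LSA, DA), its
#' three-element Windkessel, and an optional series connector resistance
#' accounting for tubing between the aortic domain and the Windkessel.
#'
#' @param label branch identifier.
#' @param wk a [windkessel_params()].
#' @param R_s series connector resistance, mmHg s/mL (>= 0, default 0).
#' @return object of class `branch_spec`.
#' @export
branch_spec <- function(label, wk, R_s = 0) {
  stopifnot(is.character(label), length(label) == 1L,
            inherits(wk, "windkessel_params"))
  if (R_s < 0) stop("R_s must be >= 0")
  structure(list(label = label, wk = wk, R_s = R_s), class = "branch_spec")
}

#' 0D aortic network
#'
#' A single zero-volume junction node fed by the inlet flow and draining into
#' one three-element Windkessel per branch. The rigid aortic domain itself is
#' lumped into the optional per-branch series resistances.
#'
#' @param branches list of [branch_spec()] with unique labels.
#' @param P_v venous (outflow reference) pressure in mmHg, default 0.
#' @return object of class `aortic_network`.
#' @export
aortic_network <- function(branches, P_v = 0) {
  stopifnot(length(branches) >= 1L,
            all(vapply(branches, inherits, TRUE, "branch_spec")))
  labels <- vapply(branches, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("branch labels must be unique")
  names(branches) <- labels
  structure(list(branches = branches, P_v = P_v), class = "aortic_network")
}

#' @export
print.aortic_network <- function(x, ...) {
  cat(sprintf("<aortic_network> %d branches, P_v = %g mmHg\n",
              length(x$branches), x$P_v))
  for (b in x$branches)
    cat(sprintf("  %-4s R1 = %-7.4g R2 = %-7.4g C = %-7.4g R_s = %-7.4g (tau = %.3g s)\n",
                b$label, b$wk$R1, b$wk$R2, b$wk$C, b$R_s, b$wk$tau))
  invisible(x)
}

# Capacitor-state derivative for all branches at once. Given the capacitor
# pressures Pc and the instantaneous inlet flow q, the junction pressure
# solves sum_i (P_ao - Pc_i)/Rp_i = q algebraically (zero-volume node).
.network_rhs <- function(Pc, q, Rp, R2, C, P_v) {
  P_ao <- (q + sum(Pc / Rp)) / sum(1 / Rp)
  Qb <- (P_ao - Pc) / Rp
  list(dPc = (Qb - (Pc - P_v) / R2) / C, P_ao = P_ao, Qb = Qb)
}

#' Proximal pressure response of a single three-element Windkessel
#'
#' Integrates the capacitor state C dPc/dt = Q - (Pc - P_v)/R2 with a
#' classical fixed-step 4th-order Runge-Kutta scheme, the inflow linearly
#' interpolated between samples, and returns the proximal pressure
#' P = Q*R1 + Pc on the inflow grid.
#'
#' @param params a [windkessel_params()].
#' @param inflow a [flow_waveform()] giving Q(t) over the integration span.
#' @param dt integration step in seconds; defaults to the inflow sampling
#'   interval, and must not exceed it.
#' @param P_c0 initial capacitor pressure, mmHg (default 0).
#' @param P_v venous reference pressure, mmHg (default 0).
#' @return a [pressure_waveform()] of the proximal pressure on the inflow grid.
#' @export
wk3_response <- function(params, inflow, dt = NULL, P_c0 = 0, P_v = 0) {
  stopifnot(inherits(params, "windkessel_params"), inherits(inflow, "flow_waveform"))
  if (is.null(dt)) dt <- inflow$dt
  if (dt > inflow$dt + 1e-12) stop("dt must not exceed the inflow sampling interval")
  n_sub <- max(1L, round(inflow$dt / dt))
  h <- inflow$dt / n_sub
  q <- inflow$flow
  n <- length(q)
  Pc <- numeric(n)
  Pc[1L] <- P_c0
  state <- P_c0
  rhs <- function(Pc_, q_) (q_ - (Pc_ - P_v) / params$R2) / params$C
  for (j in seq_len(n - 1L)) {
    for (s in seq_len(n_sub)) {
      f0 <- (s - 1) / n_sub; f1 <- s / n_sub; fm <- (f0 + f1) / 2
      q0 <- q[j] + f0 * (q[j + 1L] - q[j])
      qm <- q[j] + fm * (q[j + 1L] - q[j])
      q1 <- q[j] + f1 * (q[j + 1L] - q[j])
      k1 <- rhs(state, q0)
      k2 <- rhs(state + h / 2 * k1, qm)
      k3 <- rhs(state + h / 2 * k2, qm)
      k4 <- rhs(state + h * k3, q1)
      state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (!is.finite(state))
        stop(sprintf("windkessel solver became non-finite at t = %.6g s", inflow$time[j] + s * h))
    }
    Pc[j + 1L] <- state
  }
  pressure_waveform(inflow$time, q * params$R1 + Pc, inflow$period)
}

#' Simulate the 0D aortic network to periodic steady state
#'
#' Cycles the periodic inlet waveform through the network, advancing the
#' branch capacitor pressures with a fixed-step 4th-order Runge-Kutta scheme
#' in which the junction pressure is resolved algebraically at every stage.
#' The run stops when consecutive cycles of the inlet pressure agree within
#' `tol` (relative to the cycle pressure range) or after `max_cycles`.
#'
#' @param network an [aortic_network()].
#' @param inlet a periodic [flow_waveform()] (one cycle).
#' @param dt integration step in seconds, default 1e-3; internally snapped so
#'   that a whole number of steps fits one period.
#' @param max_cycles maximum number of cycles to run (default 30).
#' @param tol periodicity tolerance on the inlet pressure (default 1e-3).
#' @param init_states optional vector of initial capacitor pressures (mmHg),
#'   one per branch; defaults to `P_v` (supports warm starts).
#' @return object of class `simulation_result` with the final-cycle series:
#'   `time`, `inlet_flow`, `inlet_pressure` ([pressure_waveform()]),
#'   `branch_flows` and `branch_pressures` (matrices, one column per branch),
#'   `capacitor_states` (final), `cycle_pressures` (inlet-pressure matrix, one
#'   column per cycle), `cycles_run`, `periodic`, `convergence` (per-cycle
#'   periodicity metric).
#' @export
simulate_network <- function(network, inlet, dt = 1e-3, max_cycles = 30L,
                             tol = 1e-3, init_states = NULL) {
  stopifnot(inherits(network, "aortic_network"), inherits(inlet, "flow_waveform"))
  br <- network$branches
  nb <- length(br)
  Rp <- vapply(br, function(b) b$wk$R1 + b$R_s, 0)
  R2 <- vapply(br, function(b) b$wk$R2, 0)
  C <- vapply(br, function(b) b$wk$C, 0)
  P_v <- network$P_v
  T <- inlet$period
  n <- max(4L, round(T / dt))
  h <- T / n
  tgrid <- (0:(n - 1L)) * h
  # inlet flow at step and half-step times (periodic linear interpolation)
  qfun <- .periodic_interp(inlet)
  q0 <- qfun(tgrid)
  qh <- qfun(tgrid + h / 2)
  q1 <- qfun(tgrid + h)

  Pc <- if (is.null(init_states)) rep(P_v, nb) else {
    stopifnot(length(init_states) == nb); as.numeric(init_states)
  }
  cycle_P <- matrix(NA_real_, n, 0L)
  conv <- numeric(0)
  Pao <- Qb <- NULL
  for (cyc in seq_len(max_cycles)) {
    Pao <- numeric(n)
    Qb <- matrix(0, n, nb, dimnames = list(NULL, names(br)))
    for (j in seq_len(n)) {
      st <- .network_rhs(Pc, q0[j], Rp, R2, C, P_v)
      Pao[j] <- st$P_ao
      Qb[j, ] <- st$Qb
      k1 <- st$dPc
      k2 <- .network_rhs(Pc + h / 2 * k1, qh[j], Rp, R2, C, P_v)$dPc
      k3 <- .network_rhs(Pc + h / 2 * k2, qh[j], Rp, R2, C, P_v)$dPc
      k4 <- .network_rhs(Pc + h * k3, q1[j], Rp, R2, C, P_v)$dPc
      Pc <- Pc + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(!is.finite(Pc)))
        stop(sprintf("network solver became non-finite at cycle %d, step %d", cyc, j))
    }
    cycle_P <- cbind(cycle_P, Pao)
    if (cyc >= 2L) {
      rng <- diff(range(Pao))
      metric <- max(abs(cycle_P[, cyc] - cycle_P[, cyc - 1L])) / max(rng, 1e-12)
      conv <- c(conv, metric)
      if (metric < tol) break
    }
  }
  cycles_run <- ncol(cycle_P)
  periodic <- length(conv) > 0 && conv[length(conv)] < tol
  # branch pressure at the 3WK entrance: junction pressure minus connector drop
  Rs <- vapply(br, `[[`, 0, "R_s")
  Pb <- matrix(Pao, n, nb) - sweep(Qb, 2L, Rs, `*`)
  colnames(Pb) <- names(br)
  structure(list(time = tgrid, dt = h,
                 inlet_flow = q0,
                 inlet_pressure = pressure_waveform(tgrid, Pao, T),
                 branch_flows = Qb, branch_pressures = Pb,
                 capacitor_states = Pc,
                 cycle_pressures = cycle_P,
                 cycles_run = cycles_run, periodic = periodic,
                 convergence = conv, period = T),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d cycles, periodic = %s\n", x$cycles_run, x$periodic))
  cat(sprintf("  inlet pressure [%.1f, %.1f] mmHg; branch mean flows: %s mL/s\n",
              min(x$inlet_pressure$pressure), max(x$inlet_pressure$pressure),
              paste(sprintf("%s=%.1f", colnames(x$branch_flows), colMeans(x$branch_flows)),
                    collapse = ", ")))
  invisible(x)
}

# periodic linear interpolator for a one-cycle flow waveform
.periodic_interp <- function(w) {
  tt <- c(w$time, w$period)
  qq <- c(w$flow, w$flow[1L])
  function(t) {
    tm <- t %% w$period
    stats::approx(tt, qq, xout = tm, rule = 2)$y
  }
}

#' Periodic steady-state diagnosis of a simulation
#'
#' Checks, cycle by cycle, when the inlet pressure stopped changing: the run
#' is converged at cycle k when max |P_k - P_{k-1}| / range(P_k) < tol.
#'
#' @param result a [simulate_network()] result with >= 2 cycles.
#' @param tol relative tolerance (default 1e-3).
#' @return list with `converged` and `at_cycle` (NA when not converged).
#' @export
periodic_steady_state <- function(result, tol = 1e-3) {
  stopifnot(inherits(result, "simulation_result"))
  cp <- result$cycle_pressures
  if (ncol(cp) < 2L) stop("at least 2 simulated cycles are required")
  for (k in 2:ncol(cp)) {
    rng <- max(diff(range(cp[, k])), 1e-12)
    if (max(abs(cp[, k] - cp[, k - 1L])) / rng < tol)
      return(list(converged = TRUE, at_cycle = k))
  }
  list(converged = FALSE, at_cycle = NA_integer_)
}
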