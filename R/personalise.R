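#' Clinical calibration targets
#'
#' Patient-specific targets for the personalisation procedure: brachial
#' systolic/diastolic pressures and the cycle-averaged flow through each
#' aortic branch, which together define the cardiac-output distribution.
#'
#' @param P_sys systolic pressure, mmHg.
#' @param P_dia diastolic pressure, mmHg (0 < P_dia < P_sys).
#' @param flows named numeric vector of branch mean flows, mL/s (all > 0).
#' @param Q_in inlet mean flow, mL/s; must equal `sum(flows)` within 0.5%.
#' @return object of class `target_set`.
#' @export
target_set <- function(P_sys, P_dia, flows, Q_in = sum(flows)) {
  if (!(P_sys > P_dia && P_dia > 0)) stop("require P_sys > P_dia > 0")
  if (is.null(names(flows)) || any(names(flows) == ""))
    stop("flows must be a named vector")
  if (any(flows <= 0)) stop("all branch target flows must be positive")
  if (abs(sum(flows) - Q_in) > 0.005 * Q_in)
    stop("branch flows must sum to the inlet mean flow within 0.5%")
  pp <- P_sys - P_dia
  structure(list(P_sys = P_sys, P_dia = P_dia, flows = flows, Q_in = Q_in,
                 pulse_pressure = pp, MAP = P_dia + pp / 3),
            class = "target_set")
}

#' Calibration configuration
#'
#' Tuning knobs of the Windkessel calibration loop.
#'
#' @param kappa fraction of each branch's total resistance assigned to the
#'   proximal element R1 (default 0.05; typical aortic 3WK ratios are a few
#'   percent).
#' @param P_v venous reference pressure, mmHg (default 0).
#' @param tol_P absolute tolerance on systolic and diastolic pressure, mmHg
#'   (default 0.5).
#' @param tol_Q relative tolerance on branch mean flows (default 0.005).
#' @param max_iterations calibration iterations (default 50).
#' @param dt simulation time step, s (default 1e-3).
#' @param max_cycles cycles per simulation (default 30).
#' @param ss_tol periodic-steady-state tolerance (default 1e-3).
#' @return object of class `calibration_config`.
#' @export
calibration_config <- function(kappa = 0.05, P_v = 0, tol_P = 0.5,
                               tol_Q = 0.005, max_iterations = 50L,
                               dt = 1e-3, max_cycles = 30L, ss_tol = 1e-3) {
  if (kappa <= 0 || kappa >= 0.5) stop("kappa must be in (0, 0.5)")
  if (tol_P <= 0 || tol_Q <= 0) stop("tolerances must be positive")
  structure(list(kappa = kappa, P_v = P_v, tol_P = tol_P, tol_Q = tol_Q,
                 max_iterations = as.integer(max_iterations), dt = dt,
                 max_cycles = as.integer(max_cycles), ss_tol = ss_tol),
            class = "calibration_config")
}

#' Initial Windkessel estimates from clinical targets
#'
#' Per branch, the total resistance is (MAP - P_v) / target mean flow, split
#' R1 = kappa * R_tot, R2 = (1 - kappa) * R_tot; the total compliance is the
#' classical SV / pulse-pressure estimate, distributed across branches in
#' proportion to their target flows.
#'
#' @param targets a [target_set()].
#' @param waveform the inlet [flow_waveform()] (supplies the stroke volume).
#' @param config a [calibration_config()].
#' @return an [aortic_network()].
#' @export
initial_guess <- function(targets, waveform, config = calibration_config()) {
  stopifnot(inherits(targets, "target_set"), inherits(waveform, "flow_waveform"))
  if (any(targets$flows == 0)) {
    bad <- names(targets$flows)[targets$flows == 0][1L]
    stop(sprintf("zero target flow for branch %s", bad))
  }
  SV <- waveform_stats(waveform)$net_volume
  C_tot <- SV / targets$pulse_pressure
  R_tot <- (targets$MAP - config$P_v) / targets$flows
  Cb <- C_tot * targets$flows / sum(targets$flows)
  branches <- mapply(function(lbl, Rt, Ci) {
    branch_spec(lbl, windkessel_params(R1 = config$kappa * Rt,
                                       R2 = (1 - config$kappa) * Rt, C = Ci))
  }, names(targets$flows), R_tot, Cb, SIMPLIFY = FALSE)
  aortic_network(unname(branches), P_v = config$P_v)
}

#' Calibrate the Windkessel network to clinical targets
#'
#' Deterministic fixed-point loop: simulate the current network to periodic
#' steady state, then (i) rescale each branch's total resistance by its
#' achieved/target mean-flow ratio (fixing the flow split), (ii) rescale all
#' resistances by target/achieved mean arterial pressure (fixing the pressure
#' level), and (iii) rescale the total compliance by achieved/target pulse
#' pressure (fixing the pressure range), redistributing compliance in
#' proportion to target flows. MAP is evaluated on both sides with the same
#' P_dia + PP/3 convention, so that convergence of (MAP, PP) implies
#' convergence of P_sys and P_dia themselves. Simulations warm-start from the
#' previous iteration's capacitor states.
#'
#' @param targets a [target_set()].
#' @param waveform the periodic inlet [flow_waveform()].
#' @param config a [calibration_config()].
#' @param network optional starting [aortic_network()]; defaults to
#'   [initial_guess()].
#' @return object of class `calibration_result`: `network`, `achieved` (list
#'   with P_sys, P_dia and branch mean flows), `iterations`, `converged`,
#'   `history` (per-iteration error data.frame) and the final `simulation`.
#' @export
calibrate <- function(targets, waveform, config = calibration_config(),
                      network = NULL) {
  stopifnot(inherits(targets, "target_set"), inherits(waveform, "flow_waveform"))
  if (is.null(network)) network <- initial_guess(targets, waveform, config)
  labels <- names(targets$flows)
  stopifnot(setequal(labels, names(network$branches)))
  network$branches <- network$branches[labels]

  R_tot <- vapply(network$branches, function(b) b$wk$R1 + b$wk$R2, 0)
  C_tot <- sum(vapply(network$branches, function(b) b$wk$C, 0))
  kappa <- config$kappa
  states <- NULL
  history <- data.frame()
  converged <- FALSE
  sim <- NULL
  achieved <- NULL
  for (it in seq_len(config$max_iterations)) {
    net <- .build_network(labels, R_tot, C_tot, targets$flows, kappa, config$P_v)
    sim <- simulate_network(net, waveform, dt = config$dt,
                            max_cycles = config$max_cycles, tol = config$ss_tol,
                            init_states = states)
    states <- sim$capacitor_states
    idx <- extract_pressure_indices(sim$inlet_pressure)
    Qa <- colMeans(sim$branch_flows)
    achieved <- list(P_sys = idx$P_sys, P_dia = idx$P_dia, flows = Qa)
    errP <- max(abs(idx$P_sys - targets$P_sys), abs(idx$P_dia - targets$P_dia))
    errQ <- max(abs(Qa - targets$flows) / targets$flows)
    history <- rbind(history, data.frame(iteration = it, err_P = errP, err_Q = errQ,
                                         P_sys = idx$P_sys, P_dia = idx$P_dia))
    if (errP <= config$tol_P && errQ <= config$tol_Q) { converged <- TRUE; break }
    map_a <- idx$P_dia + idx$pulse_pressure / 3
    R_tot <- R_tot * (Qa / targets$flows) * (targets$MAP - config$P_v) /
      max(map_a - config$P_v, 1e-9)
    C_tot <- C_tot * idx$pulse_pressure / targets$pulse_pressure
  }
  structure(list(network = .build_network(labels, R_tot, C_tot, targets$flows,
                                          kappa, config$P_v),
                 achieved = achieved, iterations = it, converged = converged,
                 history = history, simulation = sim, targets = targets,
                 config = config),
            class = "calibration_result")
}

.build_network <- function(labels, R_tot, C_tot, flows, kappa, P_v) {
  Cb <- C_tot * flows / sum(flows)
  branches <- mapply(function(lbl, Rt, Ci) {
    branch_spec(lbl, windkessel_params(R1 = kappa * Rt, R2 = (1 - kappa) * Rt,
                                       C = Ci))
  }, labels, R_tot, Cb, SIMPLIFY = FALSE)
  aortic_network(unname(branches), P_v = P_v)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> converged = %s after %d iterations\n",
              x$converged, x$iterations))
  cat(sprintf("  achieved P_sys/P_dia = %.2f/%.2f mmHg (targets %.1f/%.1f)\n",
              x$achieved$P_sys, x$achieved$P_dia, x$targets$P_sys, x$targets$P_dia))
  cat("  branch mean flows (achieved vs target, mL/s):\n")
  for (lbl in names(x$targets$flows))
    cat(sprintf("    %-4s %.2f vs %.2f\n", lbl, x$achieved$flows[[lbl]],
                x$targets$flows[[lbl]]))
  invisible(x)
}

#' Working-fluid properties
#'
#' @param density fluid density rho, kg/m^3.
#' @param viscosity dynamic viscosity mu, Pa s.
#' @return object of class `fluid_properties`.
#' @export
fluid_properties <- function(density, viscosity) {
  if (density <= 0 || viscosity <= 0) stop("density and viscosity must be positive")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Flow-regime characterisation
#'
#' Mean and peak Reynolds numbers Re = 4 rho Q / (pi mu D) from the waveform's
#' mean and peak flow, the Womersley number Wo = (D/2) sqrt(2 pi rho / (T mu)),
#' and the transition criterion Re_c = 250 * Wo: the flow is flagged
#' transitional when the peak Reynolds number exceeds Re_c.
#'
#' @param waveform a [flow_waveform()] (flow in mL/s).
#' @param diameter vessel diameter D in metres.
#' @param fluid a [fluid_properties()].
#' @return list with `Re_m`, `Re_p`, `Wo`, `Re_c`, `transitional`.
#' @export
flow_regime <- function(waveform, diameter, fluid) {
  stopifnot(inherits(waveform, "flow_waveform"), inherits(fluid, "fluid_properties"))
  if (diameter <= 0) stop("diameter must be positive")
  st <- waveform_stats(waveform)
  re <- function(Q_ml_s) 4 * fluid$density * (Q_ml_s * 1e-6) /
    (pi * fluid$viscosity * diameter)
  Wo <- (diameter / 2) * sqrt(2 * pi * fluid$density /
                                (waveform$period * fluid$viscosity))
  Re_c <- 250 * Wo
  Re_p <- re(st$peak)
  list(Re_m = re(st$mean), Re_p = Re_p, Wo = Wo, Re_c = Re_c,
       transitional = Re_p > Re_c)
}
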