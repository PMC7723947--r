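# Shared fixtures, computed once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# patient inlet waveform on the frame-rate-adjusted period (T = 18/22 s)
patient_waveform_adjusted <- function() {
  cached("waveform_adj", function() {
    adj <- adjust_period_to_frame_rate(0.8, 22)
    synthesise_inlet_waveform(waveform_spec(period = adj$T_exact,
                                            stroke_volume = 107.6))
  })
}

# calibration of the clinical target set with the patient waveform (T = 0.8 s)
patient_calibration <- function() {
  cached("calibration", function() {
    sc <- patient_scenario()
    w <- synthesise_inlet_waveform(sc$waveform_spec)
    calibrate(sc$targets, w)
  })
}

# Womersley evaluator for the adjusted patient waveform in the scenario tube
patient_womersley <- function() {
  cached("womersley", function() {
    sc <- patient_scenario()
    womersley_velocity(patient_waveform_adjusted(), sc$tube, sc$fluid, K = 10)
  })
}

# noise-free planar ensemble at the generator's default grid, 10 cycles
patient_field_ensemble <- function() {
  cached("ensemble", function() {
    sc <- patient_scenario()
    plane_field_ensemble(patient_womersley(), sc$tube,
                         frame_rate = sc$acquisition$piv_frame_rate,
                         n_cycles = 10)
  })
}

# normalized-median-test performance on the labelled-outlier fixture
# (default generator grid, 5% outliers, no Gaussian noise, seed 42)
outlier_filter_stats <- function() {
  cached("outlier_stats", function() {
    sc <- patient_scenario()
    ens <- plane_field_ensemble(patient_womersley(), sc$tube,
                                frame_rate = 22, n_cycles = 1)
    noisy <- add_measurement_noise(ens, noise_spec(sigma = 0,
                                                   outlier_fraction = 0.05,
                                                   cycle_gain_sd = 0, seed = 42))
    truth <- attr(noisy, "outlier_truth")
    do.call(rbind, lapply(c(2, 5, 11), function(k) {
      res <- normalized_median_filter(noisy$frames[[k]])
      data.frame(frame = k,
                 recall = sum(res$flags & truth[[k]]) / sum(truth[[k]]),
                 fpr = sum(res$flags & !truth[[k]]) /
                   sum(!truth[[k]] & noisy$frames[[k]]$valid))
    }))
  })
}

# trapezoid rule with periodic wrap-around, independent of waveform_stats()
trapz_volume <- function(w) {
  q <- c(w$flow, w$flow[1L])
  t <- c(w$time, w$period)
  sum((q[-1L] + q[-length(q)]) / 2 * diff(t))
}
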