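# In-code fixtures shared across the suite.

# clean tachogram with constant or supplied intervals
clean_rri <- function(n = 150, rri_ms = 800, t0_ms = 0) {
  rri_series(rep_len(rri_ms, n), t0_ms = t0_ms)
}

# flat 1 Hz telemetry at a fixed speed
flat_telemetry <- function(duration_s, speed_kmh, t0_s = 0) {
  data.frame(t_s = t0_s + seq_len(duration_s) - 1,
             speed_kmh = rep(speed_kmh, duration_s),
             acc_x_ms2 = 0, acc_y_ms2 = 0)
}

# telemetry from a per-second speed vector
telemetry_from_speeds <- function(speed_kmh, t0_s = 0) {
  n <- length(speed_kmh)
  data.frame(t_s = t0_s + seq_len(n) - 1, speed_kmh = speed_kmh,
             acc_x_ms2 = c(0, diff(speed_kmh)) / 3.6, acc_y_ms2 = 0)
}

# small shared scenario for telemetry tests
mixed_scenario <- function() {
  data.frame(regime = c("high", "medium", "low", "stopped"),
             duration_s = c(1800, 1800, 900, 120))
}

# independent brute-force time-domain HRV (oracle for property tests)
brute_time_domain <- function(rri_vec) {
  n <- length(rri_vec)
  m <- sum(rri_vec) / n
  sdnn <- sqrt(sum((rri_vec - m)^2) / (n - 1))
  d <- rri_vec[-1] - rri_vec[-n]
  c(avghr = 60000 / m, sdnn = sdnn, nn50 = sum(abs(d) > 50),
    rmssd = sqrt(sum(d^2) / (n - 1)))
}

# independent periodogram band-power oracle on a 4 Hz resampled tachogram
periodogram_band_frac <- function(rri, f_lo, f_hi) {
  t_s <- rri$t_ms / 1000
  grid <- seq(t_s[1], t_s[length(t_s)], by = 0.25)
  x <- stats::spline(t_s, rri$rri_ms, xout = grid)$y
  sp <- stats::spec.pgram(stats::ts(x, frequency = 4), detrend = TRUE,
                          taper = 0, plot = FALSE)
  band <- sp$freq >= f_lo & sp$freq < f_hi
  sum(sp$spec[band]) / sum(sp$spec)
}
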