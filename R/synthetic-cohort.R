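#' Default configuration of the synthetic driver cohort
#'
#' The generator emulates a naturalistic truck-fleet study: middle-aged
#' drivers (ages about 35-63), shifts with a pre-shift rest, a long driving
#' mid-shift and a post-shift rest, 1 Hz vehicle telemetry spanning
#' high/medium/low/stopped speed regimes, rare validated near-miss warnings
#' whose hazard depends on 20-s speed dynamics and a latent per-second stress
#' state, and beat-to-beat R-R series whose LF (0.10 Hz) and HF (0.25 Hz)
#' modulation amplitudes shift with that same stress state (stress raises
#' LF/HF and lowers the HF-driven indices).
#'
#' @param pre_min,mid_min,post_min phase durations in minutes (default
#'   30 / 360 / 30: rest, driving/loading mix, rest).
#' @param stress stress-trace parameters for the rest and driving phases.
#' @param rri R-R generator parameters, see \code{\link{generate_rri}}.
#' @param hazard warning-hazard logistic coefficients, see
#'   \code{\link{generate_warnings}}.
#' @param artifact_miss_rate,artifact_ectopic_rate beat-detection artifact
#'   rates injected into the generated tachograms.
#' @param telemetry_noise_kmh AR(1) innovation SD of the speed noise.
#' @return a configuration list for \code{\link{generate_cohort}}.
#' @export
cohort_config <- function(pre_min = 30, mid_min = 360, post_min = 30,
                          stress = list(rest_baseline = 0.15,
                                        drive_baseline = 0.35,
                                        drift_amp = 0.08,
                                        drift_period_s = 5400,
                                        event_rate_per_hr = 5,
                                        event_amp = 0.25,
                                        event_decay_s = 180,
                                        noise_sd = 0.01,
                                        max_step = 0.05,
                                        telemetry_coupling = 0.8),
                          rri = list(f_lf = 0.10, f_hf = 0.25,
                                     a_lf0 = 0.030, a_lf_slope = 0.030,
                                     a_hf0 = 0.045, a_hf_slope = 0.025,
                                     noise_sd_ms = 12),
                          hazard = list(b0 = -7.2, b_sd = 0.45,
                                        b_speed = 0.012, b_stress = 2.2),
                          artifact_miss_rate = 0.01,
                          artifact_ectopic_rate = 0.005,
                          telemetry_noise_kmh = 4) {
  if (pre_min <= 0 || mid_min <= 0 || post_min <= 0) {
    stop("phase durations must be positive")
  }
  list(pre_min = pre_min, mid_min = mid_min, post_min = post_min,
       stress = stress, rri = rri, hazard = hazard,
       artifact_miss_rate = artifact_miss_rate,
       artifact_ectopic_rate = artifact_ectopic_rate,
       telemetry_noise_kmh = telemetry_noise_kmh)
}

speed_regimes <- function() {
  c(high = 85, medium = 40, low = 10, stopped = 0)
}

#' Generate 1 Hz vehicle telemetry from a scenario specification
#'
#' Speeds follow per-segment regime means (high ~85, medium ~40, low ~10,
#' stopped = 0 km/h) with AR(1) noise, clipped at 0; longitudinal
#' acceleration is the per-second speed difference converted to m/s^2 (plus
#' noise scaled with the speed noise), lateral acceleration is zero-mean
#' noise while moving.
#'
#' @param scenario_spec data.frame with columns \code{regime} (one of
#'   "high", "medium", "low", "stopped") and \code{duration_s}; an optional
#'   \code{mean_kmh} column overrides the regime mean.
#' @param noise_kmh AR(1) innovation SD of the speed noise (default 4; 0
#'   gives exact regime means).
#' @param seed RNG seed.
#' @param t0_s timestamp of the first sample (default 0).
#' @param noise_scale optional per-second multiplier on the speed-noise
#'   innovations (length 1 or the total duration).  The cohort generator
#'   uses it to let the latent stress state drive erratic speed-keeping,
#'   the behavioural channel through which stress becomes visible to the
#'   behaviour-only risk index.
#' @return data.frame of class \code{"telemetry"}: \code{t_s},
#'   \code{speed_kmh}, \code{acc_x_ms2}, \code{acc_y_ms2}.
#' @export
generate_telemetry <- function(scenario_spec, noise_kmh = 4, seed = 1,
                               t0_s = 0, noise_scale = 1) {
  stopifnot(all(c("regime", "duration_s") %in% names(scenario_spec)))
  regs <- speed_regimes()
  if (!all(scenario_spec$regime %in% names(regs))) {
    stop("unknown regime: ",
         paste(setdiff(scenario_spec$regime, names(regs)), collapse = ", "))
  }
  if (any(scenario_spec$duration_s <= 0)) stop("non-positive segment duration")
  set.seed(seed)
  means <- if ("mean_kmh" %in% names(scenario_spec)) {
    ifelse(is.na(scenario_spec$mean_kmh), regs[scenario_spec$regime],
           scenario_spec$mean_kmh)
  } else regs[scenario_spec$regime]
  target <- rep(means, scenario_spec$duration_s)
  moving <- rep(scenario_spec$regime != "stopped", scenario_spec$duration_s)
  n <- length(target)
  if (!length(noise_scale) %in% c(1L, n)) {
    stop("noise_scale must have length 1 or the total duration")
  }
  noise <- numeric(n)
  if (noise_kmh > 0) {
    e <- stats::rnorm(n, 0, noise_kmh) * noise_scale
    for (t in 2:n) noise[t] <- 0.9 * noise[t - 1] + e[t]
    noise[1] <- e[1]
  }
  speed <- pmax(target + noise, 0)
  speed[!moving] <- 0
  acc_x <- c(0, diff(speed)) / 3.6
  if (noise_kmh > 0) {
    acc_x <- acc_x + stats::rnorm(n, 0, 0.02 * noise_kmh)
    acc_y <- stats::rnorm(n, 0, 0.2) * moving
  } else {
    acc_y <- numeric(n)
  }
  out <- data.frame(t_s = t0_s + seq_len(n) - 1, speed_kmh = speed,
                    acc_x_ms2 = acc_x, acc_y_ms2 = acc_y)
  class(out) <- c("telemetry", "data.frame")
  out
}

#' Generate a latent per-second stress trace
#'
#' A scalar stand-in for the driver's acute stress level: baseline plus a
#' slow sinusoidal drift with random phase, Poisson-arriving stress events
#' with exponential decay, and smoothed noise; clamped to [0, 1] with a
#' bounded per-second change.
#'
#' @param duration_s trace length in seconds.
#' @param params list with \code{baseline}, \code{drift_amp},
#'   \code{drift_period_s}, \code{event_rate_per_hr}, \code{event_amp},
#'   \code{event_decay_s}, \code{noise_sd}, \code{max_step}.
#' @param seed RNG seed.
#' @return numeric vector \code{s(t)} in [0, 1], one value per second.
#' @export
generate_stress_trace <- function(duration_s,
                                  params = list(baseline = 0.3,
                                                drift_amp = 0.1,
                                                drift_period_s = 3600,
                                                event_rate_per_hr = 6,
                                                event_amp = 0.3,
                                                event_decay_s = 120,
                                                noise_sd = 0.02,
                                                max_step = 0.05),
                                  seed = 1) {
  if (duration_s <= 0) stop("duration must be positive")
  set.seed(seed)
  t <- seq_len(duration_s) - 1
  phase <- stats::runif(1, 0, 2 * pi)
  s <- params$baseline +
    params$drift_amp * sin(2 * pi * t / params$drift_period_s + phase)
  n_ev <- stats::rpois(1, params$event_rate_per_hr * duration_s / 3600)
  if (n_ev > 0) {
    ev_t <- sort(stats::runif(n_ev, 0, duration_s))
    for (te in ev_t) {
      after <- t >= te
      s[after] <- s[after] +
        params$event_amp * exp(-(t[after] - te) / params$event_decay_s)
    }
  }
  if (params$noise_sd > 0) {
    e <- stats::rnorm(duration_s, 0, params$noise_sd)
    s <- s + as.numeric(stats::filter(e, rep(1 / 5, 5), sides = 2))
    s[is.na(s)] <- params$baseline
  }
  # bounded per-second change, then clamp to [0, 1]
  out <- numeric(duration_s)
  out[1] <- min(max(s[1], 0), 1)
  for (i in seq_len(duration_s)[-1]) {
    d <- max(min(s[i] - out[i - 1], params$max_step), -params$max_step)
    out[i] <- min(max(out[i - 1] + d, 0), 1)
  }
  out
}

#' Generate a beat-to-beat R-R series from a stress trace
#'
#' Beats are laid down from the instantaneous interval
#' \deqn{RR(t) = m [1 + a_{LF}(s)\sin(2\pi f_{LF} t + \phi)
#'                  + a_{HF}(s)\sin(2\pi f_{HF} t + \psi)] + noise}
#' with \eqn{m = 60000 / baseline\_hr} ms, \eqn{f_{LF} = 0.10} Hz and
#' \eqn{f_{HF} = 0.25} Hz by default — amplitude-modulated sinusoids placing
#' power exactly in the LF and HF analysis bands.  The LF amplitude
#' increases and the HF amplitude decreases with the stress level, so stress
#' raises LF/HF and suppresses the HF-driven time-domain indices.  Beat
#' timestamps are the cumulative sums of the intervals.
#'
#' @param profile list with \code{baseline_hr} (beats/min) and optionally
#'   \code{stress_reactivity} scaling the stress-amplitude coupling.
#' @param stress_trace per-second stress values in [0, 1].
#' @param duration_s series length in seconds (>= 120).
#' @param params list with \code{f_lf}, \code{f_hf}, \code{a_lf0},
#'   \code{a_lf_slope}, \code{a_hf0}, \code{a_hf_slope}, \code{noise_sd_ms}.
#' @param seed RNG seed.
#' @return an \code{\link{rri_series}}.
#' @export
generate_rri <- function(profile, stress_trace, duration_s,
                         params = cohort_config()$rri, seed = 1) {
  if (duration_s < 120) stop("duration must be at least 120 s")
  if (length(stress_trace) < duration_s) {
    stop("stress trace shorter than requested duration")
  }
  set.seed(seed)
  m <- 60000 / profile$baseline_hr
  react <- if (is.null(profile$stress_reactivity)) 1 else
    profile$stress_reactivity
  phi <- stats::runif(1, 0, 2 * pi)
  psi <- stats::runif(1, 0, 2 * pi)
  # generous upper bound on beat count for preallocation
  n_max <- ceiling(duration_s * 1000 / (m * 0.5)) + 8
  rr <- numeric(n_max)
  t <- 0
  k <- 0
  while (t < duration_s) {
    s <- stress_trace[min(floor(t) + 1, length(stress_trace))]
    a_lf <- params$a_lf0 + react * params$a_lf_slope * s
    a_hf <- max(params$a_hf0 - react * params$a_hf_slope * s, 0)
    rri <- m * (1 + a_lf * sin(2 * pi * params$f_lf * t + phi) +
                  a_hf * sin(2 * pi * params$f_hf * t + psi)) +
      stats::rnorm(1, 0, params$noise_sd_ms)
    if (rri <= 0) stop("parameters produced a non-positive R-R interval")
    k <- k + 1
    rr[k] <- rri
    t <- t + rri / 1000
  }
  rri_series(rr[seq_len(k)])
}

#' Generate validated near-miss warnings from telemetry and stress
#'
#' For every 20-s window containing driving (speed > 0), a warning fires with
#' probability \code{plogis(b0 + b_sd * sd(speed) + b_speed * mean(speed) +
#' b_stress * mean(stress))}.  A fired warning gets a timestamp drawn
#' uniformly among the window's moving seconds (never at speed 0) and a
#' random source system.  The positive stress coefficient plants the
#' headline association between the latent stress state and near-miss risk.
#'
#' @param telemetry a \code{\link{generate_telemetry}} result.
#' @param stress_trace stress values indexed by shift second (the telemetry
#'   \code{t_s} values index into it).
#' @param hazard_params logistic coefficients \code{b0}, \code{b_sd},
#'   \code{b_speed}, \code{b_stress}.
#' @param seed RNG seed.
#' @return data.frame of class \code{"warning_events"}: \code{t_s},
#'   \code{source} ("inter_vehicle" or "rear_end"), \code{validated}.
#' @export
generate_warnings <- function(telemetry, stress_trace,
                              hazard_params = cohort_config()$hazard,
                              seed = 1) {
  set.seed(seed)
  n <- nrow(telemetry)
  n_win <- floor(n / 20)
  events <- list()
  for (k in seq_len(n_win)) {
    i <- ((k - 1) * 20 + 1):(k * 20)
    sp <- telemetry$speed_kmh[i]
    moving <- which(sp > 0)
    if (!length(moving)) next
    s_idx <- pmin(telemetry$t_s[i] + 1, length(stress_trace))
    s_bar <- mean(stress_trace[s_idx])
    eta <- hazard_params$b0 + hazard_params$b_sd * stats::sd(sp) +
      hazard_params$b_speed * mean(sp) + hazard_params$b_stress * s_bar
    if (stats::runif(1) < stats::plogis(eta)) {
      tw <- telemetry$t_s[i][sample(moving, 1)]
      events[[length(events) + 1]] <- data.frame(
        t_s = tw,
        source = sample(c("inter_vehicle", "rear_end"), 1),
        validated = TRUE)
    }
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(t_s = numeric(0), source = character(0),
               validated = logical(0))
  class(out) <- c("warning_events", "data.frame")
  out
}

#' Inject beat-detection artifacts into a tachogram
#'
#' Emulates the two common sensor failure modes: missed beats (two adjacent
#' intervals merge into their sum) and ectopic/spurious detections (one
#' interval splits into a short/long pair at 40/60%).  Affected beats are
#' flagged; total elapsed time is preserved exactly.
#'
#' @param rri an \code{\link{rri_series}}.
#' @param miss_rate,ectopic_rate per-beat artifact probabilities, each in
#'   [0, 1) and summing below 1.
#' @param seed RNG seed.
#' @return an \code{\link{rri_series}} with artifacts and flags.
#' @export
inject_artifacts <- function(rri, miss_rate = 0.02, ectopic_rate = 0.01,
                             seed = 1) {
  if (miss_rate < 0 || ectopic_rate < 0 || miss_rate + ectopic_rate >= 1) {
    stop("artifact rates must be in [0, 1) and sum below 1")
  }
  if (miss_rate == 0 && ectopic_rate == 0) return(rri)
  set.seed(seed)
  n <- nrow(rri)
  u <- stats::runif(n)
  kind <- ifelse(u < miss_rate, "miss",
                 ifelse(u < miss_rate + ectopic_rate, "ectopic", "clean"))
  new_rri <- list()
  new_flag <- list()
  i <- 1
  while (i <= n) {
    if (kind[i] == "miss" && i < n) {
      new_rri[[length(new_rri) + 1]] <- rri$rri_ms[i] + rri$rri_ms[i + 1]
      new_flag[[length(new_flag) + 1]] <- TRUE
      i <- i + 2
    } else if (kind[i] == "ectopic") {
      r <- rri$rri_ms[i]
      new_rri[[length(new_rri) + 1]] <- c(0.4 * r, 0.6 * r)
      new_flag[[length(new_flag) + 1]] <- c(TRUE, TRUE)
      i <- i + 1
    } else {
      new_rri[[length(new_rri) + 1]] <- rri$rri_ms[i]
      new_flag[[length(new_flag) + 1]] <- rri$flag[i]
      i <- i + 1
    }
  }
  t0 <- rri$t_ms[1] - rri$rri_ms[1]
  rri_series(unlist(new_rri), t0_ms = t0, flag = unlist(new_flag))
}

#' Generate a synthetic driver cohort
#'
#' Produces fully synthetic shifts with known planted effect sizes: each
#' driver gets a profile (age, baseline heart rate, stress reactivity), a
#' latent stress trace low at rest and elevated while driving, mid-shift
#' telemetry over a high/medium/low/stopped regime mix, stress- and
#' dynamics-dependent validated warnings, and a full-shift R-R series with
#' injected beat-detection artifacts.  All outputs are deterministic
#' functions of \code{(config, seed)}.
#'
#' @param n_drivers number of drivers (>= 1).
#' @param config a \code{\link{cohort_config}}.
#' @param seed RNG seed.
#' @return list of class \code{"driver_cohort"}; each element has
#'   \code{profile}, \code{phases} (pre/mid/post boundaries, s),
#'   \code{stress}, \code{telemetry} (mid-shift, shift-second timestamps),
#'   \code{warnings}, \code{rri} (whole shift), and \code{ground_truth}
#'   (planted hazard coefficients, stress-to-amplitude mapping, seed).
#' @export
generate_cohort <- function(n_drivers, config = cohort_config(), seed = 1) {
  if (n_drivers < 1) stop("need at least one driver")
  set.seed(seed)
  driver_seeds <- sample.int(2^30, n_drivers)
  lapply(seq_len(n_drivers), function(d) {
    generate_driver_shift(sprintf("D%03d", d), config, driver_seeds[d])
  }) -> cohort
  class(cohort) <- "driver_cohort"
  cohort
}

generate_driver_shift <- function(driver_id, config, seed) {
  set.seed(seed)
  profile <- list(
    driver_id = driver_id,
    age = round(min(max(stats::rnorm(1, 49, 8.2), 35), 63)),
    baseline_hr = min(max(stats::rnorm(1, 72, 6), 55), 90),
    stress_reactivity = exp(stats::rnorm(1, 0, 0.25)))

  pre_s <- config$pre_min * 60
  mid_s <- config$mid_min * 60
  post_s <- config$post_min * 60
  phases <- c(pre_end_s = pre_s, mid_end_s = pre_s + mid_s,
              total_s = pre_s + mid_s + post_s)

  sp <- config$stress
  rest_par <- list(baseline = sp$rest_baseline, drift_amp = 0,
                   drift_period_s = sp$drift_period_s, event_rate_per_hr = 0,
                   event_amp = 0, event_decay_s = sp$event_decay_s,
                   noise_sd = sp$noise_sd, max_step = sp$max_step)
  drive_par <- list(baseline = sp$drive_baseline, drift_amp = sp$drift_amp,
                    drift_period_s = sp$drift_period_s,
                    event_rate_per_hr = sp$event_rate_per_hr,
                    event_amp = sp$event_amp * profile$stress_reactivity,
                    event_decay_s = sp$event_decay_s,
                    noise_sd = sp$noise_sd, max_step = sp$max_step)
  stress <- c(generate_stress_trace(pre_s, rest_par, seed = seed + 1),
              generate_stress_trace(mid_s, drive_par, seed = seed + 2),
              generate_stress_trace(post_s, rest_par, seed = seed + 3))

  scenario <- mid_shift_scenario(mid_s, seed = seed + 4)
  # stressed drivers keep speed less steadily: the behavioural channel that
  # makes the latent state visible to the behaviour-only risk index
  coupling <- if (is.null(sp$telemetry_coupling)) 0 else sp$telemetry_coupling
  mid_stress <- stress[(pre_s + 1):(pre_s + mid_s)]
  telemetry <- generate_telemetry(scenario,
                                  noise_kmh = config$telemetry_noise_kmh,
                                  seed = seed + 5, t0_s = pre_s,
                                  noise_scale = 1 + coupling * mid_stress)
  warnings <- generate_warnings(telemetry, stress, config$hazard,
                                seed = seed + 6)
  rri <- generate_rri(profile, stress, phases["total_s"], config$rri,
                      seed = seed + 7)
  rri <- inject_artifacts(rri, config$artifact_miss_rate,
                          config$artifact_ectopic_rate, seed = seed + 8)

  list(profile = profile, phases = phases, stress = stress,
       telemetry = telemetry, warnings = warnings, rri = rri,
       ground_truth = list(hazard = config$hazard, rri_params = config$rri,
                           stress_params = config$stress, seed = seed,
                           phases = phases))
}

# Driving/loading mix for the mid-shift: repeated blocks of medium and
# high-speed driving interspersed with low-speed premises driving and stops,
# in randomized order, cut to the requested duration.
mid_shift_scenario <- function(duration_s, seed = 1) {
  set.seed(seed)
  template <- data.frame(
    regime = c("medium", "high", "medium", "low", "stopped", "medium",
               "high", "stopped"),
    duration_s = c(900, 1200, 600, 360, 300, 900, 1500, 240))
  segs <- template[sample(nrow(template)), ]
  out <- segs[0, ]
  total <- 0
  while (total < duration_s) {
    for (i in seq_len(nrow(segs))) {
      if (total >= duration_s) break
      d <- min(segs$duration_s[i], duration_s - total)
      out <- rbind(out, data.frame(regime = segs$regime[i], duration_s = d))
      total <- total + d
    }
  }
  out
}

#' @export
print.driver_cohort <- function(x, ...) {
  cat(sprintf("Synthetic driver cohort: %d drivers\n", length(x)))
  for (d in x[seq_len(min(5, length(x)))]) {
    cat(sprintf("  %s: age %d, baseline HR %.0f, %d beats, %d warnings\n",
                d$profile$driver_id, d$profile$age, d$profile$baseline_hr,
                nrow(d$rri), nrow(d$warnings)))
  }
  if (length(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Simulate regression-ready analysis records with planted effects
#'
#' Draws 2-min analysis records directly from a known logistic-quantile
#' generating process, for testing the regression stage at scale without
#' running the full pipeline: a latent stress level drives a
#' sympathetic-reflecting cluster (LF_score, LF/HF, SDNN, positively) and a
#' parasympathetic-reflecting cluster (HF_score, NN50, RMSSD, negatively),
#' and the logit of the bounded risk index is linear in the predictors with
#' i.i.d. logistic noise.
#'
#' @param n number of records.
#' @param beta named coefficients of the logit-scale linear predictor; any of
#'   \code{intercept, lfhf_ratio, nn50, avghr, age, mean_speed} (defaults
#'   plant a positive LF/HF and negative NN50 effect).
#' @param error_scale scale of the logistic error on the logit scale.
#' @param seed RNG seed.
#' @param bounds response bounds (default 0-100, percent).
#' @return data.frame shaped like \code{\link{build_analysis_dataset}}
#'   output, with the generating coefficients attached as
#'   \code{attr(, "ground_truth")}.
#' @export
simulate_analysis_records <- function(n,
                                      beta = c(intercept = -4.5,
                                               lfhf_ratio = 0.45,
                                               nn50 = -0.035,
                                               avghr = -0.02,
                                               age = 0.03,
                                               mean_speed = 0.04),
                                      error_scale = 0.8, seed = 1,
                                      bounds = c(0, 100)) {
  set.seed(seed)
  s <- stats::rbeta(n, 2, 3)
  avghr <- stats::rnorm(n, 75, 8)
  age <- sample(35:63, n, replace = TRUE)
  mean_speed <- pmin(pmax(stats::rnorm(n, 55, 15), 20), 95)
  lfhf_ratio <- exp(0.2 + 1.1 * s + stats::rnorm(n, 0, 0.35))
  nn50 <- round(pmax(55 - 45 * s + stats::rnorm(n, 0, 8), 0))
  lf_score <- 45 + 16 * s + stats::rnorm(n, 0, 4)
  hf_score <- 57 - 15 * s + stats::rnorm(n, 0, 4)
  sdnn <- pmax(62 - 22 * s + stats::rnorm(n, 0, 8), 5)
  rmssd <- pmax(38 - 20 * s + stats::rnorm(n, 0, 6), 2)
  z <- beta["intercept"] +
    beta["lfhf_ratio"] * lfhf_ratio + beta["nn50"] * nn50 +
    beta["avghr"] * avghr + beta["age"] * age +
    beta["mean_speed"] * mean_speed +
    stats::rlogis(n) * error_scale
  risk_pct <- inverse_logistic_transform(z, bounds[1], bounds[2])
  out <- data.frame(driver_id = "SIM", t_start_s = 120 * (seq_len(n) - 1),
                    risk_pct = risk_pct, lf_score = lf_score,
                    hf_score = hf_score, lfhf_ratio = lfhf_ratio,
                    sdnn = sdnn, nn50 = nn50, rmssd = rmssd, avghr = avghr,
                    mean_speed = mean_speed, age = age)
  attr(out, "ground_truth") <- list(beta = beta, error_scale = error_scale,
                                    seed = seed, bounds = bounds)
  out
}
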