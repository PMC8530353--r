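small_config <- function() cohort_config(pre_min = 5, mid_min = 30,
                                         post_min = 5)

test_that("cohort generation is a pure function of (config, seed)", {
  a <- generate_cohort(2, small_config(), seed = 1)
  b <- generate_cohort(2, small_config(), seed = 1)
  expect_identical(a, b)
  c2 <- generate_cohort(2, small_config(), seed = 2)
  expect_false(identical(a, c2))
})

test_that("telemetry length is 1 Hz times the mid-shift duration", {
  coh <- generate_cohort(1, cohort_config(mid_min = 240), seed = 3)
  expect_equal(nrow(coh[[1]]$telemetry), 14400)
})

test_that("driver profiles respect the cohort's age and heart-rate ranges", {
  coh <- generate_cohort(15, small_config(), seed = 4)
  ages <- vapply(coh, function(d) d$profile$age, numeric(1))
  hrs <- vapply(coh, function(d) d$profile$baseline_hr, numeric(1))
  expect_true(all(ages >= 35 & ages <= 63))
  expect_true(all(hrs >= 40 & hrs <= 100))
})

test_that("non-positive phase durations are a configuration error", {
  expect_error(cohort_config(mid_min = 0), "positive")
})

test_that("telemetry follows its regime means", {
  stopped <- generate_telemetry(data.frame(regime = "stopped",
                                           duration_s = 60), seed = 1)
  expect_true(all(stopped$speed_kmh == 0))

  exact <- generate_telemetry(
    data.frame(regime = "high", duration_s = 60, mean_kmh = 80),
    noise_kmh = 0, seed = 1)
  expect_true(all(exact$speed_kmh == 80))
  expect_true(all(exact$acc_x_ms2 == 0))

  mixed <- generate_telemetry(mixed_scenario(), noise_kmh = 2, seed = 2)
  lab <- rep(mixed_scenario()$regime, mixed_scenario()$duration_s)
  means <- tapply(mixed$speed_kmh, lab, mean)
  expect_lt(abs(means["high"] - 85), 2)
  expect_lt(abs(means["medium"] - 40), 2)
  expect_error(generate_telemetry(data.frame(regime = "warp",
                                             duration_s = 10)), "unknown")
})

test_that("longitudinal acceleration tracks the per-second speed change", {
  tel <- generate_telemetry(mixed_scenario(), noise_kmh = 0, seed = 1)
  expect_equal(tel$acc_x_ms2[-1], diff(tel$speed_kmh) / 3.6)
})

test_that("stress traces are bounded, smooth and mean-accurate", {
  flatp <- list(baseline = 0.4, drift_amp = 0, drift_period_s = 3600,
                event_rate_per_hr = 0, event_amp = 0, event_decay_s = 60,
                noise_sd = 0, max_step = 0.05)
  s <- generate_stress_trace(600, flatp, seed = 1)
  expect_true(all(s == 0.4))

  p <- list(baseline = 0.2, drift_amp = 0.1, drift_period_s = 1800,
            event_rate_per_hr = 4, event_amp = 0.3, event_decay_s = 120,
            noise_sd = 0.02, max_step = 0.05)
  s2 <- generate_stress_trace(7200, p, seed = 2)
  expect_true(all(s2 >= 0 & s2 <= 1))
  expect_true(all(abs(diff(s2)) <= 0.05 + 1e-12))

  # with events off, the long-run mean sits near the baseline
  p$event_rate_per_hr <- 0; p$event_amp <- 0
  s3 <- generate_stress_trace(20000, p, seed = 3)
  expect_lt(abs(mean(s3) - 0.2), 0.05)
})

test_that("an unmodulated noiseless tachogram is constant at 60000/HR", {
  prof <- list(baseline_hr = 60)
  par <- list(f_lf = 0.1, f_hf = 0.25, a_lf0 = 0, a_lf_slope = 0,
              a_hf0 = 0, a_hf_slope = 0, noise_sd_ms = 0)
  rri <- generate_rri(prof, rep(0.5, 130), 125, par, seed = 1)
  expect_true(all(rri$rri_ms == 1000))
  expect_error(generate_rri(prof, rep(0.5, 130), 60, par), "120")
})

test_that("HF-only modulation puts at least 9x more power in the HF band", {
  prof <- list(baseline_hr = 75)
  par <- list(f_lf = 0.1, f_hf = 0.25, a_lf0 = 0, a_lf_slope = 0,
              a_hf0 = 0.05, a_hf_slope = 0, noise_sd_ms = 0)
  rri <- generate_rri(prof, rep(0.5, 310), 300, par, seed = 2)
  # independent periodogram oracle
  expect_gt(periodogram_band_frac(rri, 0.15, 0.40),
            9 * periodogram_band_frac(rri, 0.04, 0.15))
})

test_that("beat timestamps are the cumulative sums of the intervals", {
  prof <- list(baseline_hr = 70)
  rri <- generate_rri(prof, rep(0.4, 200), 150, seed = 3)
  expect_equal(rri$t_ms, cumsum(rri$rri_ms))
})

test_that("high-stress cohorts show higher LF/HF than low-stress cohorts", {
  prof <- list(baseline_hr = 72, stress_reactivity = 1)
  lfhf <- function(level, seed) {
    rri <- generate_rri(prof, rep(level, 610), 605, seed = seed)
    anf <- compute_anf_series(rri, age = 50)
    mean(anf$lfhf_ratio[anf$quality_pass])
  }
  hi <- vapply(1:4, function(s) lfhf(0.9, s), numeric(1))
  lo <- vapply(1:4, function(s) lfhf(0.1, s + 100), numeric(1))
  expect_gt(min(hi), max(lo))
})

test_that("warning generation honours its logistic hazard", {
  tel <- flat_telemetry(2000, 50)
  none <- generate_warnings(tel, rep(0.5, 2000),
                            list(b0 = -50, b_sd = 0, b_speed = 0,
                                 b_stress = 0), seed = 1)
  expect_equal(nrow(none), 0)

  # intercept-only hazard at p = 0.5 over 10^4 windows
  tel2 <- flat_telemetry(200000, 50)
  half <- generate_warnings(tel2, rep(0, 200000),
                            list(b0 = 0, b_sd = 0, b_speed = 0,
                                 b_stress = 0), seed = 2)
  expect_lt(abs(nrow(half) / 10000 - 0.5), 0.02)
})

test_that("a positive stress coefficient raises the warning rate with stress", {
  tel <- flat_telemetry(100000, 50)
  stress <- rep(seq(0.05, 0.95, length.out = 100), each = 1000)
  w <- generate_warnings(tel, stress,
                         list(b0 = -4, b_sd = 0, b_speed = 0,
                              b_stress = 3), seed = 3)
  win_stress <- stress[seq(1, 100000, by = 20)]
  fired <- seq(0, 99980, by = 20) %in% (w$t_s - w$t_s %% 20)
  top <- fired[win_stress >= quantile(win_stress, 0.9)]
  bottom <- fired[win_stress <= quantile(win_stress, 0.1)]
  expect_gt(mean(top), mean(bottom))
})

test_that("warnings never occur at a stopped second", {
  coh <- generate_cohort(4, small_config(), seed = 6)
  for (d in coh) {
    if (nrow(d$warnings) == 0) next
    sp <- d$telemetry$speed_kmh[match(d$warnings$t_s, d$telemetry$t_s)]
    expect_true(all(sp > 0))
  }
})

test_that("artifact injection conserves elapsed time and flags its beats", {
  rri <- clean_rri(1000, 800)
  expect_identical(inject_artifacts(rri, 0, 0, seed = 1), rri)

  merged <- inject_artifacts(rri_series(c(800, 800)), miss_rate = 0.999,
                             ectopic_rate = 0, seed = 1)
  expect_equal(merged$rri_ms, 1600)
  expect_true(merged$flag)

  out <- inject_artifacts(rri, 0.05, 0.03, seed = 2)
  expect_equal(sum(out$rri_ms), sum(rri$rri_ms))
  expect_equal(out$t_ms[nrow(out)], rri$t_ms[nrow(rri)])
  expect_gt(sum(out$flag), 0)
  expect_error(inject_artifacts(rri, 0.6, 0.5), "rates")
})

test_that("heavy artifact injection trips the downstream quality gate", {
  rri <- clean_rri(160, 800)
  bad <- inject_artifacts(rri, miss_rate = 0.15, ectopic_rate = 0, seed = 3)
  expect_false(assess_window_quality(bad)$pass)
})

test_that("cohort CSVs round-trip through the writers and readers", {
  dir <- tempfile("cohort")
  coh <- generate_cohort(1, small_config(), seed = 7)
  write_cohort(coh, dir)
  id <- coh[[1]]$profile$driver_id
  rri2 <- read_rri_csv(file.path(dir, paste0("rri_", id, ".csv")))
  expect_equal(rri2$rri_ms, coh[[1]]$rri$rri_ms)
  tel2 <- read_telemetry_csv(file.path(dir, paste0("telemetry_", id, ".csv")))
  expect_equal(tel2$speed_kmh, coh[[1]]$telemetry$speed_kmh)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  unlink(dir, recursive = TRUE)
})

test_that("default cohorts produce plausibly rare near-miss windows", {
  coh <- generate_cohort(20, cohort_config(), seed = 99)
  fracs <- vapply(coh, function(d) {
    fw <- label_windows(build_features(d$telemetry), d$warnings)
    mean(fw$near_miss[fw$max_speed > 0])
  }, numeric(1))
  # warning-positive fraction of driving windows, pooled over the cohort
  expect_gte(mean(fracs), 0.01)
  expect_lte(mean(fracs), 0.20)
})
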