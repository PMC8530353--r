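test_that("tumbling windows are half-open and complete-only", {
  rri <- clean_rri(n = 750, rri_ms = 800)  # 600 s
  wins <- window_rri(rri, 120)
  expect_length(wins, 5)
  expect_equal(attr(wins[[1]], "win_start_ms"), 0)
  expect_equal(attr(wins[[5]], "win_end_ms"), 600000)

  short <- clean_rri(n = 119, rri_ms = 1000)  # 119 s
  expect_length(window_rri(short, 120), 0)

  # beat exactly on the 120 s boundary belongs to the next window
  rri2 <- rri_series(c(rep(1000, 119), 1000, rep(1000, 121)))
  wins2 <- window_rri(rri2, 120)
  expect_false(120000 %in% wins2[[1]]$t_ms)
  expect_true(120000 %in% wins2[[2]]$t_ms)
})

test_that("resting mode returns the single leading 90-s span", {
  rri <- clean_rri(n = 300, rri_ms = 800)
  wins <- window_rri(rri, mode = "resting")
  expect_length(wins, 1)
  expect_lt(max(wins[[1]]$t_ms), 800 + 90000)
})

test_that("quality gate rejects only above 10% bad beats", {
  w <- clean_rri(150, 800)
  expect_true(assess_window_quality(w)$pass)

  flag_k <- function(k) {
    f <- rep(FALSE, 150); f[seq_len(k)] <- TRUE
    rri_series(rep(800, 150), flag = f)
  }
  expect_true(assess_window_quality(flag_k(15))$pass)    # exactly 10%
  expect_false(assess_window_quality(flag_k(17))$pass)   # 11% (rounded up)
})

test_that("quality gate flags abnormal intervals and heart-rate outliers", {
  # 25% jumps exceed the 20% successive-change rule
  jumpy <- rri_series(rep(c(800, 1000), 30))
  expect_false(assess_window_quality(jumpy)$pass)
  # intervals outside [300, 2000] ms are abnormal
  spik <- rri_series(c(rep(800, 140), rep(150, 20)))
  expect_gt(assess_window_quality(spik)$bad_frac, 0.10)
  # 25 bpm average heart rate is outside the physiological band
  slow <- rri_series(rep(2400, 60))
  expect_false(assess_window_quality(slow)$pass)
})

test_that("quality gate is monotone in flagged beats", {
  base <- rep(800, 150)
  for (k in 16:40) {
    f <- rep(FALSE, 150); f[seq_len(k)] <- TRUE
    expect_false(assess_window_quality(rri_series(base, flag = f))$pass)
  }
})

test_that("MEM PSD localizes a pure 0.10 Hz modulation", {
  prof <- list(baseline_hr = 75)
  par <- list(f_lf = 0.10, f_hf = 0.25, a_lf0 = 0.04, a_lf_slope = 0,
              a_hf0 = 0, a_hf_slope = 0, noise_sd_ms = 0)
  rri <- generate_rri(prof, rep(0.5, 130), 125, par, seed = 1)
  w <- window_rri(rri, 120)[[1]]
  psd <- mem_psd(w)
  peak <- psd$freq_hz[which.max(psd$density)]
  expect_lt(abs(peak - 0.10), 0.01)
})

test_that("MEM PSD of a constant tachogram is essentially zero power", {
  w <- window_rri(clean_rri(160, 800), 120)[[1]]
  psd0 <- mem_psd(w)
  prof <- list(baseline_hr = 75)
  par <- list(f_lf = 0.10, f_hf = 0.25, a_lf0 = 0.04, a_lf_slope = 0,
              a_hf0 = 0.04, a_hf_slope = 0, noise_sd_ms = 0)
  mod <- generate_rri(prof, rep(0.5, 130), 125, par, seed = 1)
  psd1 <- mem_psd(window_rri(mod, 120)[[1]])
  expect_lte(psd0$var_ms2, 1e-6 * psd1$var_ms2)
})

test_that("PSD integral matches the detrended variance within 5%", {
  set.seed(42)
  for (rep in 1:5) {
    rr <- 800 + cumsum(rnorm(180, 0, 8))
    rr <- pmin(pmax(rr, 500), 1200)
    w <- window_rri(rri_series(rr), 120)[[1]]
    psd <- mem_psd(w)
    total <- band_power(psd, 0, 2)
    expect_lt(abs(total - psd$var_ms2) / psd$var_ms2, 0.05)
  }
})

test_that("white-noise tachogram spreads power roughly flat across bands", {
  set.seed(7)
  fracs <- replicate(20, {
    rr <- 800 + rnorm(170, 0, 20)
    psd <- mem_psd(window_rri(rri_series(rr), 120)[[1]])
    band_power(psd, 0.04, 0.15) / band_power(psd, 0.04, 0.40)
  })
  # LF share of [0.04, 0.40): width ratio 0.11/0.36 = 0.3056, within 20%
  expect_lt(abs(mean(fracs) - 0.11 / 0.36), 0.2 * 0.11 / 0.36)
})

test_that("band power integrates flat and zero densities exactly", {
  psd <- structure(list(freq_hz = seq(0, 2, length.out = 2049),
                        density = rep(3, 2049), order = 0L,
                        var_ms2 = 6, n_beats = 100), class = "mem_psd")
  expect_equal(band_power(psd, 0.04, 0.15), 3 * 0.11)
  psd$density <- rep(0, 2049)
  expect_equal(band_power(psd, 0.15, 0.40), 0)
  expect_error(band_power(psd, 1.5, 2.5), "outside")
})

test_that("band power is additive over a band partition", {
  set.seed(11)
  rr <- 800 + cumsum(rnorm(170, 0, 6))
  psd <- mem_psd(window_rri(rri_series(rr), 120)[[1]])
  vlf <- band_power(psd, 0.0033, 0.04)
  lf <- band_power(psd, 0.04, 0.15)
  hf <- band_power(psd, 0.15, 0.40)
  expect_equal(vlf + lf + hf, band_power(psd, 0.0033, 0.40),
               tolerance = 1e-10)
})

test_that("deviation scores center at 50 and move 10 per SD", {
  tab <- data.frame(age = 50, mu_lf = 3.0, sigma_lf = 0.5,
                    mu_hf = 0.3, sigma_hf = 0.1)
  rri_avg <- 800
  # log(LF/RRI_avg) at the normative mean -> 50
  sc <- deviation_scores(lf = rri_avg * exp(3.0), hf = 0.3 * rri_avg,
                         rri_average = rri_avg, age = 50, table = tab)
  expect_equal(unname(sc["lf_score"]), 50)
  expect_equal(unname(sc["hf_score"]), 50)
  # one SD above the HF mean -> 60
  sc2 <- deviation_scores(lf = rri_avg * exp(3.0), hf = 0.4 * rri_avg,
                          rri_average = rri_avg, age = 50, table = tab)
  expect_equal(unname(sc2["hf_score"]), 60)
  # hand evaluation: log input e^3.8 -> (3.8 - 3)/0.5 * 10 + 50 = 66
  sc3 <- deviation_scores(lf = rri_avg * exp(3.8), hf = 0.3 * rri_avg,
                          rri_average = rri_avg, age = 50, table = tab)
  expect_equal(unname(sc3["lf_score"]), 66)
})

test_that("deviation scores are affine: +1 sigma adds exactly 10", {
  tab <- synthetic_normative_table()
  set.seed(3)
  for (i in 1:20) {
    age <- sample(20:70, 1)
    row <- tab[tab$age == age, ]
    rri_avg <- runif(1, 600, 1100)
    base <- runif(1, -2, 1)
    s1 <- deviation_scores(rri_avg * exp(base), 0.2 * rri_avg, rri_avg,
                           age, tab)
    s2 <- deviation_scores(rri_avg * exp(base + row$sigma_lf),
                           (0.2 + row$sigma_hf) * rri_avg, rri_avg, age, tab)
    expect_equal(unname(s2["lf_score"] - s1["lf_score"]), 10,
                 tolerance = 1e-10)
    expect_equal(unname(s2["hf_score"] - s1["hf_score"]), 10,
                 tolerance = 1e-10)
  }
})

test_that("deviation scores reject invalid inputs", {
  tab <- synthetic_normative_table()
  expect_error(deviation_scores(0, 10, 800, 50, tab), "log")
  expect_error(deviation_scores(100, 10, 800, 19, tab), "coverage")
})

test_that("time-domain indices match hand arithmetic on the toy series", {
  w <- rri_series(c(800, 810, 790, 860))
  td <- time_domain_features(w)
  expect_equal(unname(td["nn50"]), 1)
  expect_equal(unname(td["rmssd"]), sqrt(1800), tolerance = 1e-10)
  expect_equal(unname(td["sdnn"]), sqrt(2900 / 3), tolerance = 1e-10)
  expect_equal(unname(td["avghr"]), 60000 / 815, tolerance = 1e-10)

  const <- time_domain_features(clean_rri(10, 1000))
  expect_equal(unname(const), c(60, 0, 0, 0))

  alt <- time_domain_features(rri_series(rep(c(800, 851), 10)))
  expect_equal(unname(alt["nn50"]), 19)  # every successive diff is 51 ms
})

test_that("time-domain indices use unflagged beats only", {
  rr <- c(800, 810, 790, 860)
  w <- rri_series(c(rr[1:2], 2000, rr[3:4]),
                  flag = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(time_domain_features(w),
               time_domain_features(rri_series(rr)))
  expect_error(time_domain_features(rri_series(c(800, 810))), "3 unflagged")
})

test_that("the windowed ANF pipeline passes clean data and fails corrupted windows", {
  prof <- list(baseline_hr = 72)
  rri <- generate_rri(prof, rep(0.3, 610), 605, seed = 5)
  anf <- compute_anf_series(rri, age = 50)
  expect_equal(nrow(anf), 5)
  expect_true(all(anf$quality_pass))
  expect_true(all(anf$lf > 0 & anf$hf > 0))
  expect_equal(anf$lfhf_ratio, anf$lf / anf$hf)

  # corrupt only the third window (240-360 s): flag a third of its beats
  bad <- rri
  in3 <- bad$t_ms >= 240000 & bad$t_ms < 360000
  bad$flag[which(in3)[seq_len(ceiling(sum(in3) / 3))]] <- TRUE
  anf2 <- compute_anf_series(bad, age = 50)
  expect_equal(which(!anf2$quality_pass), 3)
  expect_true(is.na(anf2$lf[3]))
})
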