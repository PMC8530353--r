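#' Split a tachogram into analysis windows
#'
#' Shift-condition analysis uses tumbling 120-s windows; the pre/post-shift
#' resting measurements use a single 90-s span at the head of the recording.
#' Windows are half-open \code{[t, t + width)}; beats are assigned by their
#' timestamp.  Only complete windows are returned: a series shorter than one
#' window yields an empty list.
#'
#' @param rri an \code{\link{rri_series}}.
#' @param width_s window width in seconds (default 120).
#' @param mode \code{"tumbling"} for back-to-back windows anchored at
#'   \code{anchor_ms}, or \code{"resting"} for the single leading 90-s span.
#' @param anchor_ms grid origin in ms (default 0, i.e. shift start), so that
#'   windows align with the 2-min analysis grid.
#' @return list of \code{rri_series}, each with attributes \code{win_start_ms}
#'   and \code{win_end_ms}.
#' @export
window_rri <- function(rri, width_s = 120, mode = c("tumbling", "resting"),
                       anchor_ms = 0) {
  mode <- match.arg(mode)
  if (width_s <= 0) stop("width_s must be > 0")
  if (mode == "resting") width_s <- 90
  w_ms <- width_s * 1000
  if (nrow(rri) == 0) return(list())

  if (mode == "resting") {
    start <- rri$t_ms[1]
    span <- rri$t_ms[nrow(rri)] - start
    if (span < w_ms) return(list())
    keep <- rri$t_ms >= start & rri$t_ms < start + w_ms
    win <- as_rri_series(rri[keep, , drop = FALSE])
    attr(win, "win_start_ms") <- start
    attr(win, "win_end_ms") <- start + w_ms
    return(list(win))
  }

  last <- rri$t_ms[nrow(rri)]
  n_win <- floor((last - anchor_ms) / w_ms)
  if (n_win < 1) return(list())
  idx <- floor((rri$t_ms - anchor_ms) / w_ms)
  out <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    win <- as_rri_series(rri[idx == (k - 1), , drop = FALSE])
    attr(win, "win_start_ms") <- anchor_ms + (k - 1) * w_ms
    attr(win, "win_end_ms") <- anchor_ms + k * w_ms
    out[[k]] <- win
  }
  out
}

#' Default window quality rules
#'
#' A window is rejected when misdetected or abnormal beats exceed 10% of the
#' total beats (strictly more than 10%: exactly 10% still passes), or when its
#' average heart rate falls outside a physiological band.  A beat is abnormal
#' when its interval leaves \code{[300, 2000]} ms or jumps by more than 20%
#' relative to the preceding interval.
#'
#' @param max_bad_frac largest tolerated fraction of bad beats (default 0.10).
#' @param rri_range_ms plausible R-R interval range in ms.
#' @param max_rel_jump largest tolerated relative successive change.
#' @param avghr_range_bpm plausible window-average heart rate band, beats/min.
#' @export
quality_rules <- function(max_bad_frac = 0.10, rri_range_ms = c(300, 2000),
                          max_rel_jump = 0.20, avghr_range_bpm = c(30, 150)) {
  list(max_bad_frac = max_bad_frac, rri_range_ms = rri_range_ms,
       max_rel_jump = max_rel_jump, avghr_range_bpm = avghr_range_bpm)
}

#' Quality-gate a tachogram window
#'
#' @param window an \code{\link{rri_series}} window (non-empty).
#' @param rules a list from \code{\link{quality_rules}}.
#' @return list with \code{pass} (logical), \code{bad_frac}, \code{avghr_bpm}
#'   and \code{n_beats}.
#' @export
assess_window_quality <- function(window, rules = quality_rules()) {
  if (nrow(window) == 0) stop("empty window")
  rri <- window$rri_ms
  out_of_range <- rri < rules$rri_range_ms[1] | rri > rules$rri_range_ms[2]
  jump <- c(FALSE, abs(diff(rri)) / rri[-length(rri)] > rules$max_rel_jump)
  bad <- window$flag | out_of_range | jump
  bad_frac <- mean(bad)
  avghr <- 60000 / mean(rri)
  pass <- bad_frac <= rules$max_bad_frac &&
    avghr >= rules$avghr_range_bpm[1] && avghr <= rules$avghr_range_bpm[2]
  list(pass = pass, bad_frac = bad_frac, avghr_bpm = avghr,
       n_beats = nrow(window))
}

#' Maximum-entropy (Burg autoregressive) power spectral density
#'
#' Estimates the PSD of a short tachogram window, the standard route for
#' frequency-domain HRV on 2-min records.  The unevenly sampled tachogram is
#' interpolated onto an even 4 Hz grid with a cubic spline, linearly
#' detrended, and fit with a Burg autoregressive model (fixed order 16 by
#' default, or AIC-selected up to \code{order_max}).  The AR spectrum is
#' returned one-sided on \code{[0, fs/2]} Hz and rescaled so that its
#' trapezoidal integral equals the variance of the detrended series, which
#' keeps band powers calibrated in ms^2.
#'
#' Flagged beats are dropped before interpolation.
#'
#' @param window an \code{\link{rri_series}} window that passed quality.
#' @param order fixed AR order (default 16), used when \code{aic = FALSE}.
#' @param aic if TRUE, select the order by AIC up to \code{order_max}.
#' @param order_max cap for AIC order selection (default 30).
#' @param fs resampling rate, Hz (default 4).
#' @param n_freq number of frequency grid intervals (default 2048).
#' @return object of class \code{"mem_psd"}: list with \code{freq_hz} (grid
#'   spanning \code{[0, fs/2]}), \code{density} (ms^2/Hz, one-sided),
#'   \code{order}, \code{var_ms2}, \code{n_beats}.
#' @export
mem_psd <- function(window, order = 16, aic = FALSE, order_max = 30,
                    fs = 4, n_freq = 2048) {
  w <- window[!window$flag, , drop = FALSE]
  if (nrow(w) < 60) stop("need at least 60 unflagged beats for MEM PSD")
  t_s <- w$t_ms / 1000
  grid <- seq(t_s[1], t_s[length(t_s)], by = 1 / fs)
  x <- stats::spline(t_s, w$rri_ms, xout = grid)$y
  # linear detrend
  tt <- grid - grid[1]
  fit <- stats::lm.fit(cbind(1, tt), x)
  xd <- fit$residuals
  v <- stats::var(xd)

  freq <- seq(0, fs / 2, length.out = n_freq + 1)
  if (v < .Machine$double.eps) {
    out <- list(freq_hz = freq, density = rep(0, length(freq)),
                order = 0L, var_ms2 = 0, n_beats = nrow(w))
    class(out) <- "mem_psd"
    return(out)
  }

  ar_fit <- tryCatch(
    stats::ar.burg(xd, aic = aic,
                   order.max = if (aic) order_max else order,
                   demean = TRUE),
    error = function(e) stop("singular AR fit: ", conditionMessage(e)))
  a <- ar_fit$ar
  p <- length(a)
  # one-sided AR spectrum: 2 * sigma2 / fs / |1 - sum a_k e^{-i w k}|^2
  if (p > 0) {
    ek <- exp(-2i * pi * outer(freq / fs, seq_len(p)))
    denom <- Mod(1 - as.vector(ek %*% a))^2
  } else {
    denom <- rep(1, length(freq))
  }
  dens <- 2 * ar_fit$var.pred / fs / denom
  # rescale so the integral over [0, fs/2] matches the detrended variance
  tot <- trapz(freq, dens)
  if (tot > 0) dens <- dens * v / tot
  out <- list(freq_hz = freq, density = dens, order = p,
              var_ms2 = v, n_beats = nrow(w))
  class(out) <- "mem_psd"
  out
}

#' @export
print.mem_psd <- function(x, ...) {
  cat(sprintf("MEM PSD: AR order %d, %d beats, total power %.1f ms^2\n",
              x$order, x$n_beats, x$var_ms2))
  invisible(x)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Integrate a PSD over a frequency band
#'
#' Trapezoidal integral of the spectral density over \code{[f_lo, f_hi)};
#' the conventional HRV bands are LF 0.04-0.15 Hz and HF 0.15-0.40 Hz.
#'
#' @param psd a \code{\link{mem_psd}}.
#' @param f_lo,f_hi band edges in Hz, \code{0 <= f_lo < f_hi}, within the grid.
#' @return band power in ms^2 (non-negative).
#' @export
band_power <- function(psd, f_lo, f_hi) {
  if (!(f_lo >= 0 && f_lo < f_hi)) stop("need 0 <= f_lo < f_hi")
  fr <- psd$freq_hz
  if (f_lo < fr[1] || f_hi > fr[length(fr)]) stop("band outside PSD grid")
  d_lo <- stats::approx(fr, psd$density, xout = f_lo)$y
  d_hi <- stats::approx(fr, psd$density, xout = f_hi)$y
  inside <- fr > f_lo & fr < f_hi
  xs <- c(f_lo, fr[inside], f_hi)
  ys <- c(d_lo, psd$density[inside], d_hi)
  max(trapz(xs, ys), 0)
}

#' Age-referenced LF/HF deviation scores
#'
#' Standardizes the R-R-interval-normalized band powers against an
#' age-normative table to a mean-50, SD-10 scale:
#' \deqn{LF_{score} = 10 (\log(LF/RRI_{avg}) - \mu_{LF}(age)) / \sigma_{LF}(age) + 50}
#' \deqn{HF_{score} = 10 (HF/RRI_{avg} - \mu_{HF}(age)) / \sigma_{HF}(age) + 50}
#' Note the asymmetry: the LF input is log-transformed, the HF input is not.
#' That is how the scoring system defines them; set \code{log_hf = TRUE} for a
#' logged HF variant.
#'
#' @param lf,hf band powers in ms^2 (\code{lf > 0} since it is logged).
#' @param rri_average mean R-R interval of the window, ms.
#' @param age driver age in years (within table coverage).
#' @param table normative table (see \code{\link{synthetic_normative_table}}).
#' @param log_hf apply the log transform to the HF input as well (default
#'   FALSE, the as-defined behaviour).
#' @return named numeric vector \code{c(lf_score, hf_score)}.
#' @export
deviation_scores <- function(lf, hf, rri_average, age,
                             table = synthetic_normative_table(),
                             log_hf = FALSE) {
  validate_normative_table(table)
  if (rri_average <= 0) stop("rri_average must be > 0")
  if (hf < 0) stop("hf must be >= 0")
  if (lf <= 0) stop("lf must be > 0 (log transform)")
  row <- normative_row(table, age)
  lf_score <- 10 * (log(lf / rri_average) - row$mu_lf) / row$sigma_lf + 50
  hf_in <- if (log_hf) {
    if (hf <= 0) stop("hf must be > 0 when log_hf = TRUE")
    log(hf / rri_average)
  } else hf / rri_average
  hf_score <- 10 * (hf_in - row$mu_hf) / row$sigma_hf + 50
  c(lf_score = lf_score, hf_score = hf_score)
}

#' Time-domain HRV indices of a window
#'
#' Computed on unflagged beats only: AVGHR = 60000/mean(RRI) beats/min;
#' SDNN = sample SD of the intervals (n-1 denominator); NN50 = count of
#' successive absolute differences exceeding 50 ms; RMSSD = root mean square
#' of successive differences.
#'
#' @param window an \code{\link{rri_series}} with at least 3 unflagged beats.
#' @return named vector \code{c(avghr, sdnn, nn50, rmssd)}.
#' @export
time_domain_features <- function(window) {
  rri <- window$rri_ms[!window$flag]
  if (length(rri) < 3) stop("need at least 3 unflagged beats")
  d <- diff(rri)
  c(avghr = 60000 / mean(rri),
    sdnn = stats::sd(rri),
    nn50 = sum(abs(d) > 50),
    rmssd = sqrt(mean(d^2)))
}

#' Windowed autonomic-function series from a tachogram
#'
#' The full per-window pipeline: windowing, quality gating, MEM PSD, LF/HF
#' band powers, age-referenced deviation scores and time-domain indices.
#' Windows failing the quality gate (or too short for spectral estimation)
#' are kept in the output with \code{quality_pass = FALSE} and missing
#' indices.
#'
#' @param rri an \code{\link{rri_series}} covering the recording.
#' @param age driver age in years.
#' @param table normative table for the deviation scores.
#' @param mode \code{"shift"} (tumbling 120-s windows) or \code{"rest"}
#'   (single leading 90-s window).
#' @param rules quality rules, see \code{\link{quality_rules}}.
#' @param anchor_ms window-grid origin, ms (default 0 = shift start).
#' @param ... passed to \code{\link{mem_psd}} (AR order policy).
#' @return data.frame of class \code{"anf_windows"}, one row per window:
#'   \code{win_start_ms}, \code{win_end_ms}, \code{quality_pass},
#'   \code{avghr}, \code{rri_average}, \code{lf}, \code{hf},
#'   \code{lf_score}, \code{hf_score}, \code{lfhf_ratio}, \code{sdnn},
#'   \code{nn50}, \code{rmssd}.
#' @export
compute_anf_series <- function(rri, age, table = synthetic_normative_table(),
                               mode = c("shift", "rest"),
                               rules = quality_rules(), anchor_ms = 0, ...) {
  mode <- match.arg(mode)
  wins <- window_rri(rri, width_s = if (mode == "shift") 120 else 90,
                     mode = if (mode == "shift") "tumbling" else "resting",
                     anchor_ms = anchor_ms)
  cols <- c("avghr", "rri_average", "lf", "hf", "lf_score", "hf_score",
            "lfhf_ratio", "sdnn", "nn50", "rmssd")
  rows <- lapply(wins, function(w) {
    rec <- as.list(stats::setNames(rep(NA_real_, length(cols)), cols))
    rec$win_start_ms <- attr(w, "win_start_ms")
    rec$win_end_ms <- attr(w, "win_end_ms")
    rec$quality_pass <- FALSE
    if (nrow(w) == 0) return(as.data.frame(rec))
    q <- assess_window_quality(w, rules)
    n_clean <- sum(!w$flag)
    if (!q$pass || n_clean < 60) return(as.data.frame(rec))
    psd <- mem_psd(w, ...)
    lf <- band_power(psd, 0.04, 0.15)
    hf <- band_power(psd, 0.15, 0.40)
    td <- time_domain_features(w)
    rec$quality_pass <- TRUE
    rec$avghr <- unname(td["avghr"])
    rec$rri_average <- mean(w$rri_ms[!w$flag])
    rec$lf <- lf
    rec$hf <- hf
    if (lf > 0) {
      sc <- deviation_scores(lf, hf, rec$rri_average, age, table)
      rec$lf_score <- unname(sc["lf_score"])
      rec$hf_score <- unname(sc["hf_score"])
    }
    rec$lfhf_ratio <- if (hf > 0) lf / hf else NA_real_
    rec$sdnn <- unname(td["sdnn"])
    rec$nn50 <- unname(td["nn50"])
    rec$rmssd <- unname(td["rmssd"])
    as.data.frame(rec)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(cols) + 3),
      c("win_start_ms", "win_end_ms", "quality_pass", cols)))
  out <- out[, c("win_start_ms", "win_end_ms", "quality_pass", cols)]
  class(out) <- c("anf_windows", "data.frame")
  out
}
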