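#' Classify each telemetry second into a driving scene
#'
#' Speed-based driving-scene rules proxy the road type (expressway, ordinary
#' road, premises, creeping traffic) from 1 Hz speed alone:
#' \itemize{
#'   \item HIGH: minute blocks in which speed exceeds 70 km/h for more than
#'     30 s; a minute also inherits HIGH from the previous minute (carry-over
#'     hysteresis) unless it independently qualifies LOW, has a majority of
#'     stopped/extremely-low seconds, or never reaches 20 km/h.
#'   \item LOW: minute blocks with more than 45 s below 20 km/h, in runs of at
#'     least 5 consecutive such minutes.
#'   \item XLOW (extremely low): seconds with speed in (0, 3) km/h whose
#'     centered 5-s moving-average speed stays below 8 km/h at every second of
#'     the surrounding 10 s before and after.  Never applies at speed 0.
#'   \item STOPPED: speed exactly 0.
#'   \item MEDIUM: any remaining second with speed > 0.
#' }
#' Minute-level labels are broadcast to their seconds, then resolved with
#' per-second precedence STOPPED > XLOW > LOW > HIGH > MEDIUM.
#'
#' @param telemetry data.frame with columns \code{t_s} (contiguous 1 Hz
#'   timestamps) and \code{speed_kmh}.
#' @return data.frame of class \code{"scene_sequence"} with \code{t_s} and
#'   \code{scene} (factor with levels HIGH, MEDIUM, LOW, XLOW, STOPPED).
#' @export
classify_scenes <- function(telemetry) {
  stopifnot(all(c("t_s", "speed_kmh") %in% names(telemetry)))
  t_s <- telemetry$t_s
  sp <- telemetry$speed_kmh
  n <- length(sp)
  if (n == 0) stop("empty telemetry")
  if (n > 1 && any(diff(t_s) != 1)) {
    stop("telemetry must be a contiguous 1 Hz grid (fill or split gaps first)")
  }
  if (any(sp < 0)) stop("negative speeds")

  stopped <- sp == 0

  # XLOW: centered 5-s moving average < 8 km/h throughout [t-10, t+10]
  ma5 <- running_mean(sp, before = 2, after = 2)
  cond <- ma5 < 8
  ok21 <- running_all(cond, before = 10, after = 10)
  xlow <- sp > 0 & sp < 3 & ok21

  # minute aggregation (anchored at trace start; last minute may be partial)
  minute <- floor((t_s - t_s[1]) / 60)
  m_ids <- sort(unique(minute))
  n_min <- length(m_ids)
  cnt_over70 <- as.vector(tapply(sp > 70, minute, sum))
  cnt_under20 <- as.vector(tapply(sp < 20, minute, sum))
  max_speed <- as.vector(tapply(sp, minute, max))
  cnt_stop_xlow <- as.vector(tapply(stopped | xlow, minute, sum))
  min_len <- as.vector(tapply(sp, minute, length))

  low_cand <- cnt_under20 > 45
  low_minute <- runs_at_least(low_cand, 5)

  base_high <- cnt_over70 > 30
  terminates <- low_cand | (cnt_stop_xlow > min_len / 2) | (max_speed < 20)
  high_minute <- logical(n_min)
  for (k in seq_len(n_min)) {
    high_minute[k] <- base_high[k] ||
      (k > 1 && high_minute[k - 1] && !terminates[k])
  }

  sec_low <- low_minute[minute + 1 - m_ids[1]]
  sec_high <- high_minute[minute + 1 - m_ids[1]]

  scene <- rep("MEDIUM", n)
  scene[sec_high] <- "HIGH"
  scene[sec_low] <- "LOW"
  scene[xlow] <- "XLOW"
  scene[stopped] <- "STOPPED"
  out <- data.frame(
    t_s = t_s,
    scene = factor(scene, levels = c("HIGH", "MEDIUM", "LOW", "XLOW",
                                     "STOPPED")))
  class(out) <- c("scene_sequence", "data.frame")
  out
}

# mean over a clipped centered window [i - before, i + after]
running_mean <- function(x, before, after) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - before, 1)
  hi <- pmin(seq_len(n) + after, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# TRUE where a logical condition holds at every second of the clipped window
running_all <- function(cond, before, after) {
  n <- length(cond)
  cs <- c(0, cumsum(cond))
  lo <- pmax(seq_len(n) - before, 1)
  hi <- pmin(seq_len(n) + after, n)
  (cs[hi + 1] - cs[lo]) == (hi - lo + 1)
}

# TRUE for elements belonging to a run of >= k consecutive TRUEs
runs_at_least <- function(x, k) {
  if (!length(x)) return(logical(0))
  r <- rle(x)
  keep <- r$values & r$lengths >= k
  inverse.rle(list(lengths = r$lengths, values = keep))
}

#' Majority driving scene of each 20-s feature window
#'
#' Each tumbling 20-s window takes the majority label of its seconds; ties
#' resolve toward the faster scene (HIGH > MEDIUM > LOW > XLOW > STOPPED).
#'
#' @param scenes a \code{\link{classify_scenes}} result.
#' @param width_s window width in seconds (default 20).
#' @return data.frame with \code{win_start_s} and \code{scene}.
#' @export
window_scenes <- function(scenes, width_s = 20) {
  t0 <- scenes$t_s[1]
  win <- floor((scenes$t_s - t0) / width_s)
  full <- win < floor(nrow(scenes) / width_s)
  levs <- levels(scenes$scene)
  lab <- tapply(scenes$scene[full], win[full], function(s) {
    counts <- table(factor(s, levels = levs))
    levs[which.max(counts)]  # which.max takes the first (fastest) on ties
  })
  data.frame(win_start_s = t0 + as.numeric(names(lab)) * width_s,
             scene = factor(unname(as.character(lab)), levels = levs))
}
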