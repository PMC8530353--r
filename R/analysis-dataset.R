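#' Resample the 20-s risk index to 2-min resolution
#'
#' Each 2-min block (anchored at the shift-start grid) averages its six 20-s
#' risk values.  A block is dropped when any of the six is missing — the
#' conservative completeness policy, since a missing 20-s value means the
#' index was undefined (untrained scene) during part of the block.
#'
#' @param risk_20s data.frame with \code{win_start_s} and \code{risk}
#'   (a \code{\link{predict_risk}} result).
#' @param block_s block width in seconds (default 120).
#' @return data.frame with \code{block_start_s} and \code{risk}.
#' @export
resample_risk <- function(risk_20s, block_s = 120) {
  if (nrow(risk_20s) == 0) {
    return(data.frame(block_start_s = numeric(0), risk = numeric(0)))
  }
  per_block <- block_s / 20
  block <- floor(risk_20s$win_start_s / block_s) * block_s
  agg <- split(risk_20s$risk, block)
  keep <- vapply(agg, function(v) length(v) == per_block && !anyNA(v),
                 logical(1))
  data.frame(block_start_s = as.numeric(names(agg))[keep],
             risk = vapply(agg[keep], mean, numeric(1)),
             row.names = NULL)
}

#' Join risk and autonomic indices into the regression dataset
#'
#' Builds one record per 2-min block satisfying all of the record
#' filters: (a) the driver drove continuously (every second of the block has
#' speed > 0), (b) the block mean speed is at least 20 km/h (the risk index is
#' only validated in medium/high-speed driving), (c) the autonomic window
#' passed the quality gate, and (d) the resampled risk block exists.  The risk
#' is expressed in percent for the bounded-outcome regression.
#'
#' @param anf_windows an \code{\link{compute_anf_series}} result (120-s grid
#'   anchored at shift start, so the join with the 2-min risk grid is exact).
#' @param risk_2min a \code{\link{resample_risk}} result.
#' @param telemetry 1 Hz telemetry covering the driving period.
#' @param profile list with at least \code{driver_id} and \code{age}.
#' @param min_mean_speed mean-speed filter in km/h (default 20).
#' @param strict_all_seconds if TRUE, require every second (not just the
#'   mean) to be at or above \code{min_mean_speed}.
#' @return data.frame of class \code{"analysis_records"} with columns
#'   \code{driver_id}, \code{t_start_s}, \code{risk_pct}, \code{lf_score},
#'   \code{hf_score}, \code{lfhf_ratio}, \code{sdnn}, \code{nn50},
#'   \code{rmssd}, \code{avghr}, \code{mean_speed}, \code{age}; the filter
#'   funnel (record counts after each filter) is attached as
#'   \code{attr(, "funnel")}.
#' @export
build_analysis_dataset <- function(anf_windows, risk_2min, telemetry, profile,
                                   min_mean_speed = 20,
                                   strict_all_seconds = FALSE) {
  anf <- as.data.frame(anf_windows)
  anf$block_start_s <- anf$win_start_ms / 1000
  joined <- merge(anf, risk_2min, by = "block_start_s")
  if (anyDuplicated(joined$block_start_s)) stop("duplicated 2-min blocks")
  joined <- joined[joined$quality_pass, , drop = FALSE]
  n_concat <- nrow(joined)

  # per-block speed summaries from 1 Hz telemetry
  blk <- floor((telemetry$t_s) / 120) * 120
  all_moving <- tapply(telemetry$speed_kmh > 0, blk,
                       function(z) length(z) == 120 && all(z))
  mean_sp <- tapply(telemetry$speed_kmh, blk, mean)
  min_sp <- tapply(telemetry$speed_kmh, blk, min)
  key <- as.numeric(names(all_moving))

  i <- match(joined$block_start_s, key)
  cont <- !is.na(i) & as.logical(all_moving[i])
  joined <- joined[cont, , drop = FALSE]
  i <- i[cont]
  n_cont <- nrow(joined)

  joined$mean_speed <- as.numeric(mean_sp[i])
  speed_ok <- if (strict_all_seconds) {
    as.numeric(min_sp[i]) >= min_mean_speed
  } else {
    joined$mean_speed >= min_mean_speed
  }
  joined <- joined[speed_ok, , drop = FALSE]
  n_speed <- nrow(joined)

  out <- data.frame(
    driver_id = if (n_speed) profile$driver_id else character(0),
    t_start_s = joined$block_start_s,
    risk_pct = joined$risk * 100,
    lf_score = joined$lf_score, hf_score = joined$hf_score,
    lfhf_ratio = joined$lfhf_ratio, sdnn = joined$sdnn,
    nn50 = joined$nn50, rmssd = joined$rmssd, avghr = joined$avghr,
    mean_speed = joined$mean_speed,
    age = if (n_speed) profile$age else numeric(0),
    row.names = NULL)
  attr(out, "funnel") <- c(concatenated = n_concat,
                           continuous_2min = n_cont,
                           over_min_speed = n_speed)
  class(out) <- c("analysis_records", "data.frame")
  out
}
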