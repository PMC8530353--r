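#' Beat-to-beat R-R interval series (tachogram)
#'
#' Constructs a validated tachogram object: one row per detected heartbeat,
#' holding the beat timestamp (ms), the R-R interval that ends at that beat
#' (ms) and an artifact flag marking beats suspected to be misdetections
#' (merged beats, ectopic splits, sensor dropouts).
#'
#' Beat timestamps are the cumulative sums of the intervals plus the series
#' origin, so for a clean (unflagged) series \code{diff(t_ms)} equals
#' \code{rri_ms[-1]}.
#'
#' @param rri_ms numeric vector of R-R intervals in milliseconds, all > 0.
#' @param t0_ms timestamp of the start of the first interval (default 0).
#' @param flag logical vector marking artifact beats (default all FALSE).
#' @return A \code{data.frame} of class \code{"rri_series"} with columns
#'   \code{t_ms}, \code{rri_ms}, \code{flag}.
#' @examples
#' rri_series(c(800, 810, 790, 860))
#' @export
rri_series <- function(rri_ms, t0_ms = 0, flag = NULL) {
  rri_ms <- as.numeric(rri_ms)
  if (length(rri_ms) == 0L) {
    out <- data.frame(t_ms = numeric(0), rri_ms = numeric(0),
                      flag = logical(0))
    class(out) <- c("rri_series", "data.frame")
    return(out)
  }
  if (any(!is.finite(rri_ms)) || any(rri_ms <= 0)) {
    stop("all R-R intervals must be finite and > 0")
  }
  if (is.null(flag)) flag <- rep(FALSE, length(rri_ms))
  if (length(flag) != length(rri_ms)) {
    stop("'flag' must match the length of 'rri_ms'")
  }
  out <- data.frame(t_ms = t0_ms + cumsum(rri_ms), rri_ms = rri_ms,
                    flag = as.logical(flag))
  class(out) <- c("rri_series", "data.frame")
  out
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("R-R interval series: %d beats, %.1f s, %d flagged\n",
              nrow(x),
              if (nrow(x)) (x$t_ms[nrow(x)] - x$t_ms[1] + x$rri_ms[1]) / 1000
              else 0,
              sum(x$flag)))
  invisible(x)
}

as_rri_series <- function(df) {
  stopifnot(all(c("t_ms", "rri_ms", "flag") %in% names(df)))
  out <- as.data.frame(df)[, c("t_ms", "rri_ms", "flag")]
  class(out) <- c("rri_series", "data.frame")
  out
}
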