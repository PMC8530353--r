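#' Read and write the pipeline's CSV surfaces
#'
#' Thin, validated CSV readers/writers for the formats the pipeline consumes
#' and produces: tachograms (\code{t_ms, rri_ms, flag}), 1 Hz telemetry
#' (\code{t_s, speed_kmh, acc_x_ms2, acc_y_ms2}), warning-event logs
#' (\code{t_s, source, validated}), age-normative tables
#' (\code{age, mu_lf, sigma_lf, mu_hf, sigma_hf}) and per-window autonomic
#' indices.
#'
#' @param path file path.
#' @return the corresponding validated object.
#' @name ansrisk_io
NULL

#' @rdname ansrisk_io
#' @export
read_rri_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_ms", "rri_ms") %in% names(df))) {
    stop("tachogram CSV needs columns t_ms, rri_ms (optional flag)")
  }
  if (is.null(df$flag)) df$flag <- FALSE
  as_rri_series(df)
}

#' @rdname ansrisk_io
#' @param rri an \code{\link{rri_series}}.
#' @export
write_rri_csv <- function(rri, path) {
  utils::write.csv(as.data.frame(rri), path, row.names = FALSE)
  invisible(path)
}

#' @rdname ansrisk_io
#' @export
read_telemetry_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_s", "speed_kmh", "acc_x_ms2", "acc_y_ms2")
  if (!all(need %in% names(df))) {
    stop("telemetry CSV needs columns ", paste(need, collapse = ", "))
  }
  class(df) <- c("telemetry", "data.frame")
  df
}

#' @rdname ansrisk_io
#' @param telemetry a telemetry data.frame.
#' @export
write_telemetry_csv <- function(telemetry, path) {
  utils::write.csv(as.data.frame(telemetry), path, row.names = FALSE)
  invisible(path)
}

#' @rdname ansrisk_io
#' @export
read_warnings_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "source") %in% names(df))) {
    stop("warning CSV needs columns t_s, source (optional validated)")
  }
  if (is.null(df$validated)) df$validated <- TRUE
  class(df) <- c("warning_events", "data.frame")
  df
}

#' @rdname ansrisk_io
#' @export
read_normative_csv <- function(path) {
  df <- utils::read.csv(path)
  validate_normative_table(df)
  df
}

#' @rdname ansrisk_io
#' @param anf_windows an \code{\link{compute_anf_series}} result.
#' @export
write_anf_windows_csv <- function(anf_windows, path) {
  utils::write.csv(as.data.frame(anf_windows), path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' One tachogram, telemetry and warning CSV per driver
#' (\code{rri_<id>.csv}, \code{telemetry_<id>.csv},
#' \code{warnings_<id>.csv}), plus a JSON ground-truth/manifest file with
#' the planted parameters and profiles.
#'
#' @param cohort a \code{\link{generate_cohort}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- lapply(cohort, function(d) {
    id <- d$profile$driver_id
    write_rri_csv(d$rri, file.path(dir, paste0("rri_", id, ".csv")))
    write_telemetry_csv(d$telemetry,
                        file.path(dir, paste0("telemetry_", id, ".csv")))
    utils::write.csv(as.data.frame(d$warnings),
                     file.path(dir, paste0("warnings_", id, ".csv")),
                     row.names = FALSE)
    c(d$profile, list(phases = as.list(d$phases),
                      ground_truth = d$ground_truth[c("hazard",
                                                      "rri_params",
                                                      "seed")]))
  })
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
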