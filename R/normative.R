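#' Synthetic age-normative table for LF/HF deviation scores
#'
#' The deviation scores standardize the R-R-interval-normalized LF and HF band
#' powers against an age-referenced normal population (mean 50, SD 10 by
#' construction).  The normative means and SDs used in the original scoring
#' system come from proprietary reference cohorts and are not publicly
#' available, so this package ships a *synthetic* normative table: smooth,
#' physiologically plausible curves (spectral power declines with age) that
#' play the same structural role.  Scores computed against it are therefore
#' relative to this synthetic reference, not to any clinical population.
#'
#' Per age year the table carries the mean and SD of \code{log(LF/RRI_average)}
#' (columns \code{mu_lf}, \code{sigma_lf}) and of \code{HF/RRI_average}
#' (columns \code{mu_hf}, \code{sigma_hf}).
#'
#' @param ages integer vector of ages (years) to cover.
#' @return data.frame with columns \code{age}, \code{mu_lf}, \code{sigma_lf},
#'   \code{mu_hf}, \code{sigma_hf}.
#' @examples
#' head(synthetic_normative_table())
#' @export
synthetic_normative_table <- function(ages = 20:70) {
  ages <- as.integer(ages)
  if (any(ages < 1)) stop("ages must be positive")
  data.frame(
    age      = ages,
    mu_lf    = -0.90 - 0.020 * (ages - 50),
    sigma_lf = rep(0.85, length(ages)),
    mu_hf    = 0.28 - 0.004 * (ages - 50),
    sigma_hf = rep(0.12, length(ages))
  )
}

validate_normative_table <- function(table) {
  need <- c("age", "mu_lf", "sigma_lf", "mu_hf", "sigma_hf")
  if (!all(need %in% names(table))) {
    stop("normative table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(table$sigma_lf <= 0) || any(table$sigma_hf <= 0)) {
    stop("normative table SDs must be > 0")
  }
  ages <- sort(table$age)
  if (length(ages) > 1 && any(diff(ages) != 1)) {
    stop("normative table must cover a contiguous age range")
  }
  invisible(table)
}

normative_row <- function(table, age) {
  i <- match(as.integer(floor(age)), table$age)
  if (is.na(i)) stop("age ", age, " outside normative table coverage")
  table[i, ]
}
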