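#' Per-quantile AIC ranks and average rank of candidate models
#'
#' Given a models-by-quantiles AIC matrix, ranks the models within each
#' quantile (ascending, ties get average ranks) and averages each model's
#' rank across quantiles — the arbitration statistic of the hierarchical
#' model selection.
#'
#' @param aic numeric matrix, rows = models, columns = quantiles.
#' @return list with \code{ranks} (same shape as \code{aic}) and
#'   \code{avg_rank} (one value per model).
#' @export
aic_rank_table <- function(aic) {
  aic <- as.matrix(aic)
  ranks <- apply(aic, 2, rank)
  list(ranks = ranks, avg_rank = rowMeans(ranks))
}

sns_variables <- function() c("lf_score", "lfhf_ratio", "sdnn")
pns_variables <- function() c("hf_score", "nn50", "rmssd")
control_variables <- function() c("avghr", "age", "mean_speed")

#' Hierarchical AIC selection of the risk-analysis model
#'
#' Two-step selection of the logistic-quantile-regression model of the risk
#' index.  Step 1 fits the baseline model with the control variables (AVGHR,
#' age, mean speed; sex is dropped when invariant in the cohort).  Step 2 adds
#' one sympathetic-reflecting variable (LF_score, LF/HF or SDNN) and one
#' parasympathetic-reflecting variable (HF_score, NN50 or RMSSD) — all nine
#' pairs, no interactions — and fits every model at each quantile.  Models
#' are ranked by AIC within each quantile; among the candidates whose two
#' added coefficients are significant (normal test on bootstrap SEs,
#' \code{alpha = 0.05}) at every quantile, the one with the smallest average
#' rank is selected.  Every candidate design is also screened with the
#' VIF < 10 collinearity check.
#'
#' @param records an analysis dataset (\code{\link{build_analysis_dataset}}
#'   result or any data.frame with columns \code{risk_pct}, the three control
#'   variables and the six candidate autonomic indices).
#' @param quantiles quantile levels (default 0.25, 0.5, 0.75, 0.9, 0.95).
#' @param bounds,eps response bounds and clamp, see \code{\link{fit_lqr}}.
#' @param B bootstrap resamples for the significance test (default 2000).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed for the bootstrap.
#' @return object of class \code{"selection_table"}: model formulas, the
#'   (baseline + 9) x quantiles AIC matrix, per-quantile ranks and average
#'   ranks over the nine candidates, significance flags, VIF screen results
#'   and the chosen model id (NA with a diagnostic when no candidate passes
#'   the significance screen).
#' @export
hierarchical_select <- function(records,
                                quantiles = c(0.25, 0.5, 0.75, 0.9, 0.95),
                                bounds = c(0, 100), eps = 0.1,
                                B = 2000, alpha = 0.05, seed = 1) {
  ctrl <- control_variables()
  cands <- expand.grid(sns = sns_variables(), pns = pns_variables(),
                       stringsAsFactors = FALSE)
  # model order: sns varies slowest, matching the conventional numbering
  cands <- cands[order(match(cands$sns, sns_variables()),
                       match(cands$pns, pns_variables())), ]
  rownames(cands) <- NULL
  need <- c("risk_pct", ctrl, sns_variables(), pns_variables())
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  records <- records[stats::complete.cases(records[, need]), , drop = FALSE]
  y <- records$risk_pct

  model_vars <- c(list(baseline = ctrl),
                  stats::setNames(
                    lapply(seq_len(nrow(cands)),
                           function(i) c(cands$sns[i], cands$pns[i], ctrl)),
                    paste0("model_", seq_len(nrow(cands)))))

  n_m <- length(model_vars)
  aic <- matrix(NA_real_, n_m, length(quantiles),
                dimnames = list(names(model_vars), paste0("tau_", quantiles)))
  signif_all <- stats::setNames(rep(TRUE, n_m - 1), names(model_vars)[-1])
  vif_max <- stats::setNames(rep(NA_real_, n_m), names(model_vars))
  coef_tables <- list()

  for (m in seq_len(n_m)) {
    vars <- model_vars[[m]]
    X <- as.matrix(records[, vars, drop = FALSE])
    v <- vif(X)
    vif_max[m] <- max(v)
    for (q in seq_along(quantiles)) {
      tau <- quantiles[q]
      fit <- fit_lqr(X, y, tau, bounds, eps)
      aic[m, q] <- lqr_aic(fit)
      if (m > 1) {
        fit <- bootstrap_se(X, y, tau, bounds, eps, B = B,
                            seed = seed + 1000 * m + q, fit = fit)
        step2 <- c(cands$sns[m - 1], cands$pns[m - 1])
        if (any(fit$p_value[step2] >= alpha)) {
          signif_all[m - 1] <- FALSE
        }
      }
      coef_tables[[paste(names(model_vars)[m], tau, sep = "@")]] <- fit
    }
  }

  cand_aic <- aic[-1, , drop = FALSE]
  rk <- aic_rank_table(cand_aic)
  eligible <- names(signif_all)[signif_all]
  chosen <- if (length(eligible)) {
    eligible[which.min(rk$avg_rank[eligible])]
  } else NA_character_

  out <- list(models = model_vars,
              candidates = cands,
              quantiles = quantiles,
              aic = aic, ranks = rk$ranks, avg_rank = rk$avg_rank,
              significant = signif_all, vif_max = vif_max,
              chosen = chosen, fits = coef_tables,
              diagnostic = if (is.na(chosen))
                "no candidate had both added coefficients significant at all quantiles"
              else NULL)
  class(out) <- "selection_table"
  out
}

#' @export
print.selection_table <- function(x, ...) {
  cat("Hierarchical AIC selection (logistic quantile regression)\n")
  tab <- as.data.frame(round(x$aic, 1))
  tab$avg_rank <- c(NA, round(x$avg_rank, 1))
  tab$significant <- c(NA, x$significant)
  tab$formula <- vapply(x$models, paste, "", collapse = " + ")
  print(tab)
  if (is.na(x$chosen)) cat("No model selected:", x$diagnostic, "\n")
  else cat("Selected:", x$chosen, "(",
           paste(x$models[[x$chosen]], collapse = " + "), ")\n")
  invisible(x)
}
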