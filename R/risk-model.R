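#' Build 20-s vehicle-behaviour feature windows
#'
#' Aggregates 1 Hz speed and acceleration into tumbling 20-s windows with the
#' 15 standard explanatory variables: max/min/mean/SD of speed, longitudinal
#' acceleration and lateral acceleration; the fine speed-variation component
#' \code{std_diff_speed} (SD over the window of the per-second difference
#' between speed and its centered 10-s moving average); and the mean-speed
#' differences to the previous and following windows
#' (\code{diff_mspeed_bef = mean(current) - mean(previous)},
#' \code{diff_mspeed_aft = mean(next) - mean(current)}).
#'
#' First/last windows lack a neighbour: their difference features are set to 0
#' and flagged \code{complete = FALSE} (such windows are excluded from model
#' training by default).
#'
#' @param telemetry data.frame with \code{t_s}, \code{speed_kmh},
#'   \code{acc_x_ms2}, \code{acc_y_ms2} on a contiguous 1 Hz grid, at least
#'   60 s long.
#' @param width_s window width, s (default 20).
#' @return data.frame of class \code{"feature_windows"}: \code{win_start_s},
#'   the 15 features, \code{complete}.
#' @export
build_features <- function(telemetry, width_s = 20) {
  need <- c("t_s", "speed_kmh", "acc_x_ms2", "acc_y_ms2")
  stopifnot(all(need %in% names(telemetry)))
  n <- nrow(telemetry)
  if (n < 60) stop("need at least 60 s of telemetry")
  if (any(diff(telemetry$t_s) != 1)) stop("telemetry gaps: expect 1 Hz grid")
  sp <- telemetry$speed_kmh
  ax <- telemetry$acc_x_ms2
  ay <- telemetry$acc_y_ms2

  # centered 10-s moving average: window [t-5, t+4], clipped at the edges
  ma10 <- running_mean(sp, before = 5, after = 4)
  dev <- sp - ma10

  n_win <- floor(n / width_s)
  idx <- function(k) ((k - 1) * width_s + 1):(k * width_s)
  rows <- lapply(seq_len(n_win), function(k) {
    i <- idx(k)
    data.frame(
      win_start_s = telemetry$t_s[i[1]],
      max_speed = max(sp[i]), min_speed = min(sp[i]), mean_speed = mean(sp[i]),
      max_acc_x = max(ax[i]), min_acc_x = min(ax[i]), mean_acc_x = mean(ax[i]),
      max_acc_y = max(ay[i]), min_acc_y = min(ay[i]), mean_acc_y = mean(ay[i]),
      std_speed = stats::sd(sp[i]), std_acc_x = stats::sd(ax[i]),
      std_acc_y = stats::sd(ay[i]),
      std_diff_speed = stats::sd(dev[i]),
      diff_mspeed_bef = 0, diff_mspeed_aft = 0,
      complete = FALSE)
  })
  out <- do.call(rbind, rows)
  if (n_win >= 2) {
    ms <- out$mean_speed
    inner <- 2:(n_win - 1)
    if (n_win > 2) {
      out$diff_mspeed_bef[inner] <- ms[inner] - ms[inner - 1]
      out$diff_mspeed_aft[inner] <- ms[inner + 1] - ms[inner]
      out$complete[inner] <- TRUE
    }
  }
  class(out) <- c("feature_windows", "data.frame")
  out
}

risk_feature_names <- function() {
  c("max_speed", "min_speed", "mean_speed",
    "max_acc_x", "min_acc_x", "mean_acc_x",
    "max_acc_y", "min_acc_y", "mean_acc_y",
    "std_speed", "std_acc_x", "std_acc_y",
    "std_diff_speed", "diff_mspeed_bef", "diff_mspeed_aft")
}

#' Label feature windows with near-miss warnings
#'
#' A window \code{[t, t+20)} is labelled 1 when at least one validated
#' warning timestamp falls inside it (half-open, so a warning at exactly
#' \code{t+20} belongs to the next window), else 0.
#'
#' @param windows a \code{\link{build_features}} result.
#' @param warnings data.frame with \code{t_s} and optionally
#'   \code{validated} (non-validated warnings are ignored).
#' @param width_s window width, s (default 20).
#' @return \code{windows} with an added integer \code{near_miss} column.
#' @export
label_windows <- function(windows, warnings, width_s = 20) {
  wt <- warnings$t_s
  if (!is.null(warnings$validated)) wt <- wt[warnings$validated]
  windows$near_miss <- vapply(windows$win_start_s, function(s) {
    as.integer(any(wt >= s & wt < s + width_s))
  }, integer(1))
  windows
}

default_risk_grid <- function() {
  expand.grid(nrounds = c(100, 300), max_depth = c(3, 5),
              eta = c(0.05, 0.1))
}

#' Train per-scene gradient-boosted near-miss classifiers
#'
#' Fits one gradient-boosted decision-tree classifier per driving scene
#' (HIGH and MEDIUM only: low and extremely-low scenes carry no rear-end
#' near-misses and are excluded), selecting hyperparameters by grid search on
#' mean out-of-fold AUC under stratified shuffled 5-fold cross-validation.
#' Reports pooled out-of-fold ROC points, AUC and gain-based feature
#' importances normalized to sum to 1.
#'
#' @param windows labelled feature windows (\code{\link{label_windows}}).
#' @param scenes per-window scenes (\code{\link{window_scenes}}), aligned by
#'   \code{win_start_s}.
#' @param grid hyperparameter grid, a data.frame with columns
#'   \code{nrounds}, \code{max_depth}, \code{eta}.
#' @param n_folds number of CV folds (default 5).
#' @param seed RNG seed controlling fold assignment.
#' @param include_incomplete keep edge windows lacking a neighbour (default
#'   FALSE).
#' @param group_by_driver if TRUE, cross-validation folds keep each driver's
#'   windows together (requires a \code{driver_id} column), so performance is
#'   estimated across drivers rather than across interleaved windows.  Off by
#'   default: plain stratified folds are the reference behaviour.
#' @return object of class \code{"risk_model"}: per-scene fitted boosters,
#'   chosen hyperparameters, CV report (fold AUCs), pooled ROC points,
#'   out-of-fold AUC and normalized importances.
#' @export
train_risk_model <- function(windows, scenes, grid = default_risk_grid(),
                             n_folds = 5, seed = 1,
                             include_incomplete = FALSE,
                             group_by_driver = FALSE) {
  if (group_by_driver && is.null(windows$driver_id)) {
    stop("group_by_driver requires a driver_id column")
  }
  df <- merge(windows, scenes, by = window_keys(windows, scenes))
  if (!include_incomplete) df <- df[df$complete, , drop = FALSE]
  feats <- risk_feature_names()
  out <- list(models = list(), params = list(), cv_report = NULL,
              roc_points = NULL, auc = c(), importances = list(),
              feature_names = feats, seed = seed)
  for (sc in c("HIGH", "MEDIUM")) {
    d <- df[df$scene == sc, , drop = FALSE]
    if (nrow(d) == 0) next
    y <- d$near_miss
    if (length(unique(y)) < 2) {
      stop("scene ", sc, " has a single class; cannot train")
    }
    X <- as.matrix(d[, feats])
    folds <- if (group_by_driver) {
      grouped_folds(d$driver_id, n_folds,
                    seed = seed + match(sc, c("HIGH", "MEDIUM")))
    } else {
      stratified_folds(y, n_folds, seed = seed + match(sc, c("HIGH", "MEDIUM")))
    }
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      oof <- rep(NA_real_, length(y))
      fold_auc <- numeric(n_folds)
      for (f in seq_len(n_folds)) {
        tr <- folds != f
        set.seed(seed + 97 * f + g)
        bst <- fit_gbdt(X[tr, , drop = FALSE], y[tr], grid[g, ])
        oof[!tr] <- stats::predict(
          bst, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
        fold_auc[f] <- auc_fast(y[!tr], oof[!tr])
      }
      mean_auc <- mean(fold_auc, na.rm = TRUE)  # grouped folds may be 1-class
      if (is.null(best) || mean_auc > best$mean_auc) {
        best <- list(g = g, mean_auc = mean_auc, oof = oof,
                     fold_auc = fold_auc)
      }
    }
    set.seed(seed + 1009)
    final <- fit_gbdt(X, y, grid[best$g, ])
    imp <- xgboost::xgb.importance(model = final)
    gain <- stats::setNames(rep(0, length(feats)), feats)
    gain[imp$Feature] <- imp$Gain
    if (sum(gain) > 0) gain <- gain / sum(gain)

    roc <- pROC::roc(response = y, predictor = best$oof, quiet = TRUE,
                     direction = "<", levels = c(0, 1))
    out$models[[sc]] <- final
    out$params[[sc]] <- grid[best$g, , drop = FALSE]
    out$cv_report <- rbind(out$cv_report,
                           data.frame(scene = sc, fold = seq_len(n_folds),
                                      auc = best$fold_auc))
    out$roc_points <- rbind(out$roc_points,
                            data.frame(scene = sc,
                                       fpr = 1 - roc$specificities,
                                       tpr = roc$sensitivities))
    out$auc[sc] <- as.numeric(pROC::auc(roc))
    out$importances[[sc]] <- gain
  }
  class(out) <- "risk_model"
  out
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Near-miss risk model (gradient-boosted trees)\n")
  for (sc in names(x$models)) {
    p <- x$params[[sc]]
    cat(sprintf(
      "  %s: out-of-fold AUC %.3f (nrounds %d, depth %d, eta %.2f)\n",
      sc, x$auc[sc], p$nrounds, p$max_depth, p$eta))
  }
  invisible(x)
}

# join windows to scenes on (driver_id, win_start_s) when a driver key is
# present on both sides; multi-driver pools must carry one
window_keys <- function(windows, scenes) {
  keys <- intersect(c("driver_id", "win_start_s"),
                    intersect(names(windows), names(scenes)))
  if (!"win_start_s" %in% keys) stop("win_start_s key required")
  if (!"driver_id" %in% keys &&
      (anyDuplicated(windows$win_start_s) || anyDuplicated(scenes$win_start_s))) {
    stop("duplicated win_start_s: pooled multi-driver tables need a ",
         "driver_id column on both windows and scenes")
  }
  keys
}

fit_gbdt <- function(X, y, par) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = par$max_depth,
                  eta = par$eta, nthread = 1, eval_metric = "logloss"),
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = par$nrounds, verbose = 0)
}

# stratified shuffled fold assignment: balanced class proportions per fold
stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    folds[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  folds
}

# whole-driver fold assignment (each driver's windows stay together)
grouped_folds <- function(driver_id, n_folds, seed) {
  set.seed(seed)
  ids <- unique(driver_id)
  fold_of <- stats::setNames(sample(rep_len(seq_len(n_folds), length(ids))),
                             ids)
  unname(fold_of[as.character(driver_id)])
}

# rank-based AUC (Mann-Whitney); fast enough for CV inner loops
auc_fast <- function(y, p) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Predict the continuous 20-s collision-risk index
#'
#' The risk index of a window is the predicted near-miss probability from the
#' model of its driving scene.  Windows in scenes with no trained model
#' (LOW, XLOW, STOPPED) get \code{NA}: the index is undefined at low speed.
#'
#' @param model a \code{\link{train_risk_model}} fit.
#' @param windows feature windows.
#' @param scenes per-window scenes aligned by \code{win_start_s}.
#' @return data.frame \code{win_start_s}, \code{scene}, \code{risk}
#'   (probability in [0,1] or NA).
#' @export
predict_risk <- function(model, windows, scenes) {
  keys <- window_keys(windows, scenes)
  df <- merge(windows, scenes, by = keys)
  df <- df[do.call(order, df[keys]), ]
  feats <- model$feature_names
  if (!all(feats %in% names(df))) stop("feature schema mismatch")
  risk <- rep(NA_real_, nrow(df))
  for (sc in names(model$models)) {
    i <- df$scene == sc
    if (any(i)) {
      risk[i] <- stats::predict(
        model$models[[sc]],
        xgboost::xgb.DMatrix(as.matrix(df[i, feats, drop = FALSE])))
    }
  }
  out <- df[, c(keys, "scene")]
  out$risk <- risk
  rownames(out) <- NULL
  out
}
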