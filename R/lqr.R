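#' Logit transform for a bounded response
#'
#' Maps a response bounded in \code{(y_min, y_max)} onto the real line,
#' \code{z = log((y - y_min) / (y_max - y))}.  Observations on or near the
#' bounds are first clamped into \code{[y_min + eps, y_max - eps]} so the
#' transform stays finite; quantile regression on the transformed scale then
#' yields fitted conditional quantiles that respect the bounds after
#' back-transformation.
#'
#' @param y numeric response within \code{[y_min, y_max]}.
#' @param y_min,y_max response bounds (default 0 and 100, a percentage).
#' @param eps boundary clamp (default 0.1).
#' @return transformed values \code{z}.
#' @seealso \code{\link{inverse_logistic_transform}}
#' @export
logistic_transform <- function(y, y_min = 0, y_max = 100, eps = 0.1) {
  if (any(y < y_min | y > y_max, na.rm = TRUE)) {
    stop("response outside [y_min, y_max]")
  }
  y <- pmin(pmax(y, y_min + eps), y_max - eps)
  log((y - y_min) / (y_max - y))
}

#' @rdname logistic_transform
#' @param z values on the transformed (logit) scale.
#' @export
inverse_logistic_transform <- function(z, y_min = 0, y_max = 100) {
  y_min + (y_max - y_min) * stats::plogis(z)
}

# check loss rho_tau(u) = u * (tau - 1{u < 0})
check_loss <- function(u, tau) sum(u * (tau - (u < 0)))

# Solver front end: Frisch-Newton interior point (compiled), with the IRLS
# smoothing solver as a fallback when the interior point fails to close the
# duality gap.  Returns whichever solution has the smaller check loss.
rq_solve <- function(Xd, z, tau, beta_init = NULL) {
  qr0 <- qr(Xd)
  if (qr0$rank < ncol(Xd)) stop("design matrix is rank deficient")
  fn <- tryCatch(.rq_fn_cpp(Xd, z, tau), error = function(e) NULL)
  if (!is.null(fn)) {
    fn$beta <- as.vector(fn$beta)
    fn$loss <- check_loss(z - Xd %*% fn$beta, tau)
  }
  if (!is.null(fn) && fn$converged) {
    return(fn)
  }
  ir <- rq_irls(Xd, z, tau, beta_init = beta_init)
  if (!is.null(fn) && fn$loss < ir$loss) fn else ir
}

# Quantile regression by iteratively reweighted least squares on the
# smoothed check loss (weights psi_i / max(|r_i|, delta)); converges to the
# check-loss minimum as delta -> 0.
rq_irls <- function(Xd, z, tau, tol = 1e-8, maxit = 200, delta = 1e-6,
                    beta_init = NULL) {
  if (is.null(beta_init)) {
    qr0 <- qr(Xd)
    if (qr0$rank < ncol(Xd)) stop("design matrix is rank deficient")
    beta <- qr.coef(qr0, z)
  } else {
    beta <- beta_init
  }
  loss <- check_loss(z - Xd %*% beta, tau)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    r <- as.vector(z - Xd %*% beta)
    psi <- ifelse(r > 0, tau, 1 - tau)
    w <- psi / pmax(abs(r), delta)
    Xw <- Xd * w
    beta_new <- tryCatch(
      solve(crossprod(Xw, Xd), crossprod(Xw, z)),
      error = function(e) stats::lm.wfit(Xd, z, w)$coefficients)
    if (anyNA(beta_new)) stop("rank deficiency during reweighting")
    loss_new <- check_loss(z - Xd %*% beta_new, tau)
    step <- max(abs(beta_new - beta))
    if (loss_new <= loss) beta <- beta_new
    if (abs(loss - loss_new) < tol * (1 + abs(loss)) || step < 1e-10) {
      loss <- min(loss, loss_new)
      converged <- TRUE
      break
    }
    loss <- min(loss, loss_new)
  }
  list(beta = beta, loss = check_loss(z - Xd %*% beta, tau),
       converged = converged, iterations = it)
}

#' Logistic quantile regression
#'
#' Fits the conditional \eqn{\tau}-quantile of a bounded response by quantile
#' regression on the logit-transformed scale:
#' \deqn{Q_y(\tau \mid X) = \frac{y_{max} \exp(X\beta_\tau) + y_{min}}
#'       {1 + \exp(X\beta_\tau)}}
#' The coefficients minimize the check loss
#' \eqn{\sum_i \rho_\tau(z_i - x_i\beta)} with
#' \eqn{\rho_\tau(u) = u(\tau - 1\{u<0\})} on the transformed scale, solved by
#' iteratively reweighted least squares (tolerance 1e-8).
#'
#' @param x numeric matrix or data.frame of predictors (no intercept column;
#'   one is added).
#' @param y bounded response.
#' @param tau quantile level in (0, 1).
#' @param bounds response bounds \code{c(y_min, y_max)} (default 0, 100).
#' @param eps boundary clamp passed to \code{\link{logistic_transform}}.
#' @return object of class \code{"lqr_fit"}: coefficients (named, intercept
#'   first), \code{tau}, \code{n}, \code{bounds}, check \code{loss}, fitted
#'   quantiles on the original scale (\code{fitted_q}), convergence status.
#'   Standard errors/p-values are filled in by \code{\link{bootstrap_se}}.
#' @examples
#' set.seed(1)
#' x <- cbind(a = rnorm(200))
#' y <- inverse_logistic_transform(-1 + 0.5 * x[, 1] + rlogis(200) / 2)
#' fit_lqr(x, y, tau = 0.5)
#' @export
fit_lqr <- function(x, y, tau, bounds = c(0, 100), eps = 0.1,
                    beta_init = NULL) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  x <- as.matrix(x)
  if (ncol(x) > 0 && is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  n <- length(y)
  if (nrow(x) != n) stop("x and y dimensions disagree")
  z <- logistic_transform(y, bounds[1], bounds[2], eps)
  Xd <- cbind(`(Intercept)` = 1, x)
  sol <- rq_solve(Xd, z, tau, beta_init = beta_init)
  fitted_z <- as.vector(Xd %*% sol$beta)
  out <- list(coefficients = stats::setNames(as.vector(sol$beta),
                                             colnames(Xd)),
              tau = tau, n = n, bounds = bounds, eps = eps,
              loss = sol$loss,
              fitted_q = inverse_logistic_transform(fitted_z,
                                                    bounds[1], bounds[2]),
              converged = sol$converged, se = NULL, p_value = NULL)
  class(out) <- "lqr_fit"
  out
}

#' @export
print.lqr_fit <- function(x, ...) {
  cat(sprintf("Logistic quantile regression, tau = %.2f, n = %d%s\n",
              x$tau, x$n, if (x$converged) "" else " (not converged)"))
  tab <- data.frame(estimate = x$coefficients)
  if (!is.null(x$se)) {
    tab$se <- x$se
    tab$p <- x$p_value
  }
  print(round(tab, 4))
  invisible(x)
}

#' AIC of a quantile-regression fit
#'
#' Under the asymmetric-Laplace working likelihood with scale set to the mean
#' check loss \eqn{\hat\sigma = n^{-1}\sum_i \rho_\tau(r_i)}, the maximized
#' log-likelihood is \eqn{\hat\ell = n(\log(\tau(1-\tau)) - \log\hat\sigma - 1)}
#' and \eqn{AIC = 2k - 2\hat\ell} with \eqn{k} the number of regression
#' coefficients.  The same form is used for every model, so AIC differences
#' at a fixed \eqn{\tau} are meaningful for model comparison.
#'
#' @param fit an \code{\link{lqr_fit}}.
#' @return the AIC (finite; zero residual loss is an error).
#' @export
lqr_aic <- function(fit) {
  if (!fit$converged) warning("AIC from a non-converged fit")
  sigma <- fit$loss / fit$n
  if (sigma <= 0) stop("degenerate fit: zero check loss")
  k <- length(fit$coefficients)
  ll <- fit$n * (log(fit$tau * (1 - fit$tau)) - log(sigma) - 1)
  2 * k - 2 * ll
}

#' Bootstrap standard errors for logistic quantile regression
#'
#' Resamples records with replacement \code{B} times (2000 by default), refits at the same quantile, and reports the SD of the
#' bootstrap coefficient vectors as the standard error, plus two-sided
#' normal-approximation p-values.  Seeded and reproducible.
#'
#' @inheritParams fit_lqr
#' @param B number of bootstrap resamples (default 2000).
#' @param seed RNG seed.
#' @param fit optionally, the fit on the original data (refit if omitted).
#' @return the \code{\link{lqr_fit}} with \code{se} and \code{p_value} filled
#'   in, and the bootstrap coefficient matrix attached as
#'   \code{attr(, "boot_coef")}.
#' @export
bootstrap_se <- function(x, y, tau, bounds = c(0, 100), eps = 0.1,
                         B = 2000, seed = 1, fit = NULL) {
  if (B < 2) stop("need B >= 2")
  x <- as.matrix(x)
  if (ncol(x) > 0 && is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  if (is.null(fit)) fit <- fit_lqr(x, y, tau, bounds, eps)
  n <- length(y)
  set.seed(seed)
  bc <- matrix(NA_real_, B, length(fit$coefficients))
  failures <- 0
  for (b in seq_len(B)) {
    i <- sample.int(n, n, replace = TRUE)
    # warm start at the full-data solution: large bootstrap speedup
    fb <- tryCatch(fit_lqr(x[i, , drop = FALSE], y[i], tau, bounds, eps,
                           beta_init = fit$coefficients),
                   error = function(e) NULL)
    if (is.null(fb)) failures <- failures + 1 else bc[b, ] <- fb$coefficients
  }
  if (failures > B / 2) stop("rank deficiency in most bootstrap resamples")
  se <- apply(bc, 2, stats::sd, na.rm = TRUE)
  fit$se <- stats::setNames(se, names(fit$coefficients))
  fit$p_value <- 2 * stats::pnorm(-abs(fit$coefficients / se))
  attr(fit, "boot_coef") <- bc
  fit
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1/(1 - R^2_j)} from regressing predictor \eqn{j} on the
#' others (with intercept).  Values above 10 indicate multicollinearity;
#' exact collinearity yields \code{Inf}.
#'
#' @param x numeric matrix or data.frame with at least 2 columns (predictors
#'   only, no intercept).
#' @return named vector of VIFs with a logical attribute \code{"flagged"}
#'   marking entries above \code{threshold}.
#' @param threshold flag level (default 10).
#' @export
vif <- function(x, threshold = 10) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 predictor columns")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  out <- vapply(seq_len(ncol(x)), function(j) {
    yj <- x[, j]
    Xj <- cbind(1, x[, -j, drop = FALSE])
    fit <- stats::lm.fit(Xj, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(x)
  attr(out, "flagged") <- out > threshold
  out
}

#' Mean-effect model for the bounded response
#'
#' The "mean" column companion of the quantile fits.  Two routes give a
#' conditional-mean effect on the same logit scale as the quantile
#' coefficients: ordinary least squares of the logit-transformed response
#' (default), or a quasi-likelihood fractional-logit GLM of \code{y} scaled
#' to \code{[0, 1]} (quasibinomial with logit link).  Both report
#' coefficients, SEs and p-values.
#'
#' @inheritParams fit_lqr
#' @param method \code{"ols"} (default) or \code{"fractional"}.
#' @return object of class \code{"lqr_mean_fit"} with coefficients, SEs and
#'   p-values.
#' @export
fit_mean_model <- function(x, y, bounds = c(0, 100), eps = 0.1,
                           method = c("ols", "fractional")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (ncol(x) > 0 && is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  if (method == "ols") {
    z <- logistic_transform(y, bounds[1], bounds[2], eps)
    df <- data.frame(z = z, x, check.names = FALSE)
    fit <- stats::lm(z ~ ., data = df)
  } else {
    frac <- (y - bounds[1]) / (bounds[2] - bounds[1])
    df <- data.frame(frac = frac, x, check.names = FALSE)
    fit <- stats::glm(frac ~ ., data = df, family = stats::quasibinomial())
  }
  sm <- summary(fit)$coefficients
  out <- list(coefficients = stats::setNames(sm[, 1], rownames(sm)),
              se = stats::setNames(sm[, 2], rownames(sm)),
              p_value = stats::setNames(sm[, 4], rownames(sm)),
              n = length(y), bounds = bounds, method = method, fit = fit)
  class(out) <- "lqr_mean_fit"
  out
}

#' @export
print.lqr_mean_fit <- function(x, ...) {
  cat(sprintf("Mean-effect model (%s, logit scale), n = %d\n",
              if (identical(x$method, "fractional")) "fractional logit"
              else "OLS", x$n))
  print(round(data.frame(estimate = x$coefficients, se = x$se,
                         p = x$p_value), 4))
  invisible(x)
}
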