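# PLS1 calibration core: NIPALS fitting, leave-one-out latent-factor
# selection, prediction and calibration/validation metrics.

# NIPALS PLS1 on centered data. Deterministic; stops early when the
# X'y covariance is numerically exhausted (effective rank reached).
.pls1_core <- function(X, y, n_latent) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  X1 <- sweep(X, 2L, x_mean)
  y1 <- y - y_mean
  A <- min(n_latent, n - 1L, p)
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  nw0 <- NA_real_
  a <- 0L
  while (a < A) {
    w <- crossprod(X1, y1)
    nw <- sqrt(sum(w^2))
    if (a == 0L) nw0 <- nw
    if (!is.finite(nw) || nw == 0 || nw < 1e-10 * max(nw0, 1e-300)) break
    w <- w / nw
    t <- X1 %*% w
    tt <- sum(t^2)
    if (tt < 1e-300) break
    pv <- crossprod(X1, t) / tt
    qa <- sum(y1 * t) / tt
    X1 <- X1 - t %*% t(pv)
    y1 <- y1 - qa * t
    a <- a + 1L
    W[, a] <- w; P[, a] <- pv; q[a] <- qa
  }
  list(x_mean = x_mean, y_mean = y_mean,
       weights = W[, seq_len(a), drop = FALSE],
       x_loadings = P[, seq_len(a), drop = FALSE],
       y_loadings = q[seq_len(a)], n_latent = a)
}

.pls1_regression_vector <- function(fit, ncomp = fit$n_latent) {
  idx <- seq_len(ncomp)
  W <- fit$weights[, idx, drop = FALSE]
  P <- fit$x_loadings[, idx, drop = FALSE]
  # R = P'W is unit lower-bidiagonal-free upper triangular; solve directly
  as.vector(W %*% solve(crossprod(P, W), fit$y_loadings[idx]))
}

# Predictions for every factor count 1..fit$n_latent via score deflation,
# the path the NIPALS model defines; returns an n x n_latent matrix.
.pls1_predict_all <- function(fit, X_new) {
  X_new <- as.matrix(X_new)
  Xc <- sweep(X_new, 2L, fit$x_mean)
  A <- fit$n_latent
  out <- matrix(fit$y_mean, nrow(X_new), max(A, 1L))
  acc <- rep(fit$y_mean, nrow(X_new))
  for (a in seq_len(A)) {
    t <- Xc %*% fit$weights[, a]
    acc <- acc + as.vector(t) * fit$y_loadings[a]
    Xc <- Xc - t %*% t(fit$x_loadings[, a])
    out[, a] <- acc
  }
  out
}

#' Fit a PLS1 calibration model
#'
#' Univariate-response partial least squares by the NIPALS algorithm:
#' predictors are mean-centered (never variance-scaled -- spectral variable
#' scale is physically meaningful), and for each latent factor the weight
#' vector is the normalized X'y covariance, followed by deflation of X and
#' y. Fitting is deterministic. If the requested number of latent factors
#' exceeds the effective rank of the centered predictor matrix, the model
#' is truncated to the achievable number with a warning.
#'
#' @param X Numeric matrix, samples x variables.
#' @param y Numeric response vector (concentration, mg/g).
#' @param n_latent Number of latent factors (>= 1).
#' @return An object of class `pls1` with components `x_mean`, `y_mean`,
#'   `weights`, `x_loadings`, `y_loadings`, `n_latent`,
#'   `regression_vector`, `fitted_values`, `residuals`, `y`.
#' @seealso [loo_select_lv()] to choose `n_latent`, [predict.pls1()].
#' @examples
#' X <- matrix(rnorm(60), 10, 6)
#' y <- X[, 1] - 2 * X[, 3] + rnorm(10, sd = 0.1)
#' m <- pls1(X, y, n_latent = 3)
#' summary(m)
#' @export
pls1 <- function(X, y, n_latent) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("pls1 needs at least 2 samples", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n_latent < 1L) stop("n_latent must be >= 1", call. = FALSE)
  fit <- .pls1_core(X, y, n_latent)
  if (fit$n_latent < n_latent) {
    warning(sprintf(
      "requested %d latent factors but the effective rank allows only %d; truncated",
      n_latent, fit$n_latent))
  }
  fit$regression_vector <- .pls1_regression_vector(fit)
  fitted <- as.vector(sweep(X, 2L, fit$x_mean) %*% fit$regression_vector) +
    fit$y_mean
  fit$fitted_values <- fitted
  fit$residuals <- y - fitted
  fit$y <- y
  class(fit) <- "pls1"
  attr(fit, "X") <- X  # kept for the per-factor RMSEC path in summary()
  fit
}

#' Predict concentrations from a fitted PLS1 model
#'
#' \eqn{\hat y = (X_{new} - \bar x) b + \bar y} with the model's regression
#' vector (equivalently, the sequential score-deflation prediction).
#'
#' @param object A `pls1` model.
#' @param newdata Numeric matrix with the training number of columns.
#' @param ncomp Number of latent factors to use (default: all fitted).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls1 <- function(object, newdata, ncomp = object$n_latent, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    stop("newdata has the wrong number of variables", call. = FALSE)
  }
  if (ncomp == object$n_latent) {
    b <- object$regression_vector
  } else {
    if (ncomp < 1L || ncomp > object$n_latent) {
      stop("ncomp outside the fitted range", call. = FALSE)
    }
    b <- .pls1_regression_vector(object, ncomp)
  }
  as.vector(sweep(newdata, 2L, object$x_mean) %*% b) + object$y_mean
}

#' @export
coef.pls1 <- function(object, ...) {
  c(`(Intercept)` = object$y_mean -
      sum(object$x_mean * object$regression_vector),
    stats::setNames(object$regression_vector,
                    paste0("V", seq_along(object$regression_vector))))
}

#' @export
residuals.pls1 <- function(object, ...) object$residuals

#' @export
fitted.pls1 <- function(object, ...) object$fitted_values

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("<pls1> %d latent factors, %d variables, %d samples\n",
              x$n_latent, length(x$x_mean), length(x$y)))
  cat(sprintf("  RMSEC %.4g, R calibration %.4f\n",
              sqrt(mean(x$residuals^2)),
              suppressWarnings(stats::cor(x$y, x$fitted_values))))
  invisible(x)
}

#' @export
summary.pls1 <- function(object, ...) {
  preds <- .pls1_predict_all(object, .reconstruct_X(object))
  rmsec <- sqrt(colMeans((preds - object$y)^2))
  out <- list(n_latent = object$n_latent,
              rmsec_by_factor = rmsec,
              rmsec = sqrt(mean(object$residuals^2)),
              r_cal = suppressWarnings(stats::cor(object$y,
                                                  object$fitted_values)))
  class(out) <- "summary.pls1"
  out
}

# The per-factor RMSEC curve needs the training matrix, which pls1()
# stores as an attribute; models rebuilt from JSON do not carry it.
.reconstruct_X <- function(object) {
  attr(object, "X") %||% stop("training matrix not stored", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.summary.pls1 <- function(x, ...) {
  cat(sprintf("PLS1 calibration: %d latent factors\n", x$n_latent))
  cat(sprintf("  RMSEC by factor: %s\n",
              paste(sprintf("%.4g", x$rmsec_by_factor), collapse = " ")))
  cat(sprintf("  final RMSEC %.4g, R %.4f\n", x$rmsec, x$r_cal))
  invisible(x)
}

#' @export
plot.pls1 <- function(x, ...,
                      xlab = "Reference concentration (mg/g)",
                      ylab = "Predicted concentration (mg/g)") {
  graphics::plot(x$y, x$fitted_values, xlab = xlab, ylab = ylab, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Choose the number of latent factors by leave-one-out cross-validation
#'
#' For each candidate factor count k = 1..min(`max_lv`, n-2, p), each
#' calibration sample is predicted by a model fitted to the remaining
#' samples, and the k minimizing the root-mean-square cross-validation
#' error is returned; ties break toward fewer factors (parsimony).
#'
#' @param X_cal,y_cal Calibration predictors and response.
#' @param max_lv Largest factor count to consider (default 20).
#' @return Integer: the selected factor count, with the RMSECV curve in
#'   attribute `"rmsecv"`.
#' @export
loo_select_lv <- function(X_cal, y_cal, max_lv = 20L) {
  X_cal <- as.matrix(X_cal)
  n <- nrow(X_cal)
  if (n < 3L) stop("leave-one-out selection needs at least 3 samples",
                   call. = FALSE)
  K <- min(max_lv, n - 2L, ncol(X_cal))
  preds <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    fit <- .pls1_core(X_cal[-i, , drop = FALSE], y_cal[-i], K)
    pi <- .pls1_predict_all(fit, X_cal[i, , drop = FALSE])
    a <- fit$n_latent
    if (a == 0L) {
      preds[i, ] <- fit$y_mean
    } else {
      preds[i, seq_len(a)] <- pi[1L, seq_len(a)]
      if (a < K) preds[i, (a + 1L):K] <- pi[1L, a]
    }
  }
  rmsecv <- sqrt(colMeans((preds - y_cal)^2))
  k <- which.min(rmsecv)  # first minimum: ties resolve to fewer factors
  structure(as.integer(k), rmsecv = rmsecv)
}

#' Correlation and root-mean-square error of a prediction
#'
#' R is the Pearson correlation between reference and predicted values;
#' RMSE is in response units (mg/g). A zero-variance reference or
#' prediction vector leaves R undefined (`NA` with a warning).
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 2.
#' @return Named numeric vector `c(R = ..., RMSE = ...)`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2L) {
    stop("y_true and y_pred must have equal length >= 2", call. = FALSE)
  }
  rmse <- sqrt(mean((y_pred - y_true)^2))
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    warning("zero variance: correlation is undefined")
    r <- NA_real_
  } else {
    r <- stats::cor(y_true, y_pred)
  }
  c(R = r, RMSE = rmse)
}

#' Serialize a fitted PLS1 model to JSON
#'
#' Stores the centering vectors, per-factor weights and loadings and the
#' factor count, so a model can be saved and reloaded for prediction
#' without refitting.
#'
#' @param model A `pls1` model.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pls1_json <- function(model, path) {
  stopifnot(inherits(model, "pls1"))
  obj <- list(x_mean = model$x_mean, y_mean = model$y_mean,
              weights = model$weights, x_loadings = model$x_loadings,
              y_loadings = model$y_loadings, n_latent = model$n_latent)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a PLS1 model serialized with [write_pls1_json()]
#'
#' @param path Path to the JSON file.
#' @return A `pls1` model usable with [predict.pls1()] (training fitted
#'   values and residuals are not stored).
#' @export
read_pls1_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- list(x_mean = as.numeric(obj$x_mean), y_mean = obj$y_mean,
              weights = as.matrix(obj$weights),
              x_loadings = as.matrix(obj$x_loadings),
              y_loadings = as.numeric(obj$y_loadings),
              n_latent = as.integer(obj$n_latent))
  fit$regression_vector <- .pls1_regression_vector(fit)
  class(fit) <- "pls1"
  fit
}
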