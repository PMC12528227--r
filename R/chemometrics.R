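#' Principal component analysis
#'
#' SVD-based PCA with optional mean centering, the qualitative monitoring
#' model: PC scores plotted against reaction time trace the reaction
#' progress without requiring reference concentrations.
#'
#' @param X numeric matrix (samples x channels).
#' @param n_pc number of components to keep, at most `min(dim(X))`.
#' @param center mean-center columns first (default `TRUE`).
#' @return An object of class `pca_model`: `means`, `loadings`
#'   (channels x n_pc, orthonormal columns), `scores` (samples x n_pc),
#'   `explained_variance_pct` (per kept PC, relative to total variance).
#' @export
pca_fit <- function(X, n_pc, center = TRUE) {
  X <- as.matrix(X)
  if (n_pc > min(dim(X)))
    stop("n_pc must be <= min(dim(X)) = ", min(dim(X)))
  means <- if (center) colMeans(X) else numeric(ncol(X))
  Xc <- sweep(X, 2L, means)
  sv <- svd(Xc)
  loadings <- sv$v[, seq_len(n_pc), drop = FALSE]
  scores <- Xc %*% loadings
  tot <- sum(sv$d^2)
  evar <- if (tot > 0) 100 * sv$d[seq_len(n_pc)]^2 / tot else rep(0, n_pc)
  structure(list(means = means, loadings = loadings, scores = scores,
                 explained_variance_pct = evar, center = center),
            class = "pca_model")
}

#' Project new data onto a fitted PCA model
#'
#' @param model a [pca_fit()] result.
#' @param X_new matrix with the same channel count as the training data.
#' @return Score matrix (`nrow(X_new) x n_pc`).
#' @export
pca_project <- function(model, X_new) {
  stopifnot(inherits(model, "pca_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$means))
    stop("X_new must have ", length(model$means), " channels")
  sweep(X_new, 2L, model$means) %*% model$loadings
}

#' Partial least squares regression (PLS1)
#'
#' Single-response PLS by NIPALS with optional mean centering. At the full
#' latent-variable count on full-rank data the fit coincides with ordinary
#' least squares.
#'
#' @param X numeric matrix (samples x channels).
#' @param y numeric response vector.
#' @param n_lv number of latent variables, >= 1.
#' @param center mean-center `X` and `y` (default `TRUE`).
#' @return An object of class `pls_model` with regression vector `coef`,
#'   centering vectors, weights/loadings, and `n_lv` (possibly reduced if
#'   the residual collapses early).
#' @export
pls_fit <- function(X, y, n_lv, center = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (stats::var(y) == 0) stop("y is constant; no variance to model")
  if (n_lv < 1 || n_lv > min(dim(X)))
    stop("n_lv must be in 1..min(dim(X))")
  x_mean <- if (center) colMeans(X) else numeric(ncol(X))
  y_mean <- if (center) mean(y) else 0
  E <- sweep(X, 2L, x_mean)
  f <- y - y_mean
  p <- ncol(X)
  W <- P <- matrix(0, p, n_lv)
  q <- numeric(n_lv)
  a_eff <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(E, f)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14 * max(1, sqrt(sum(f^2)))) break
    w <- w / nw
    t_sc <- E %*% w
    tt <- sum(t_sc^2)
    if (tt < .Machine$double.eps) break
    pvec <- crossprod(E, t_sc)[, 1L] / tt
    qa <- sum(f * t_sc) / tt
    E <- E - t_sc %*% t(pvec)
    f <- f - qa * t_sc[, 1L]
    W[, a] <- w; P[, a] <- pvec; q[a] <- qa
    a_eff <- a
  }
  if (a_eff == 0L) stop("no usable latent variable (X'y is zero)")
  W <- W[, seq_len(a_eff), drop = FALSE]
  P <- P[, seq_len(a_eff), drop = FALSE]
  q <- q[seq_len(a_eff)]
  coef <- W %*% solve(crossprod(P, W), q)
  structure(list(kind = "pls", coef = coef[, 1L], x_mean = x_mean,
                 y_mean = y_mean, weights = W, x_loadings = P,
                 y_loadings = q, n_lv = a_eff, center = center),
            class = "pls_model")
}

#' @rdname pls_fit
#' @param model a fitted `pls_model`.
#' @param X_new matrix of new samples.
#' @return `pls_predict` returns the predicted response vector.
#' @export
pls_predict <- function(model, X_new) {
  stopifnot(inherits(model, "pls_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$x_mean))
    stop("X_new must have ", length(model$x_mean), " channels")
  as.numeric(sweep(X_new, 2L, model$x_mean) %*% model$coef) + model$y_mean
}

#' Choose the PLS latent-variable count by venetian-blinds CV
#'
#' Interleaved ("venetian blinds") cross-validation on the calibration set:
#' split `s` holds out every `n_splits`-th sample starting at `s`. Returns
#' the LV count (capped at `max_lv`) minimizing RMSECV.
#'
#' @param X,y calibration data.
#' @param max_lv cap on the latent-variable count (default 10).
#' @param n_splits number of blinds (default 7).
#' @return Integer LV count.
#' @export
choose_n_lv <- function(X, y, max_lv = 10, n_splits = 7) {
  X <- as.matrix(X)
  n <- nrow(X)
  n_splits <- min(n_splits, n - 1L)
  lv_cap <- min(max_lv, min(n - ceiling(n / n_splits), ncol(X)))
  press <- rep(0, lv_cap)
  for (s in seq_len(n_splits)) {
    val <- seq(s, n, by = n_splits)
    cal <- setdiff(seq_len(n), val)
    for (a in seq_len(lv_cap)) {
      fit <- pls_fit(X[cal, , drop = FALSE], y[cal], n_lv = a)
      press[a] <- press[a] + sum((pls_predict(fit, X[val, , drop = FALSE]) -
                                    y[val])^2)
    }
  }
  which.min(press)
}

#' Support vector regression
#'
#' \eqn{\varepsilon}-insensitive SVR with a linear or radial basis function
#' (Gaussian) kernel, via the LIBSVM solver. Inputs are not rescaled;
#' spectra are assumed preprocessed. Defaults follow common spectral
#' calibration practice: `cost = 1`, `epsilon = 0.01 * range(y)`,
#' `gamma = 1 / (n_channels * var(X))`.
#'
#' @param X numeric matrix (samples x channels).
#' @param y numeric response.
#' @param kernel `"lin"` or `"rbf"`.
#' @param cost regularization parameter C, > 0.
#' @param epsilon insensitivity tube half-width, >= 0.
#' @param gamma RBF kernel width, > 0 (ignored for `"lin"`).
#' @return An object of class `svr_model` wrapping the fitted
#'   [e1071::svm()] state.
#' @export
svr_fit <- function(X, y, kernel = c("lin", "rbf"), cost = 1,
                    epsilon = NULL, gamma = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  kernel <- match.arg(kernel)
  epsilon <- epsilon %||% (0.01 * diff(range(y)))
  gamma <- gamma %||% (1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-12)))
  check_scalar(cost, "cost", 0)
  check_scalar(epsilon, "epsilon", 0, strict = FALSE)
  check_scalar(gamma, "gamma", 0)
  fit <- e1071::svm(x = X, y = y, type = "eps-regression",
                    kernel = if (kernel == "lin") "linear" else "radial",
                    cost = cost, epsilon = epsilon, gamma = gamma,
                    scale = FALSE)
  structure(list(kind = paste0("svr_", kernel), fit = fit,
                 hyperparams = list(cost = cost, epsilon = epsilon,
                                    gamma = gamma)),
            class = "svr_model")
}

#' @rdname svr_fit
#' @param model a fitted `svr_model`.
#' @param X_new matrix of new samples.
#' @export
svr_predict <- function(model, X_new) {
  stopifnot(inherits(model, "svr_model"))
  as.numeric(stats::predict(model$fit, as.matrix(X_new)))
}

#' Small grid search for SVR hyperparameters
#'
#' Optional 3 x 3 x 3 grid (cost, epsilon, gamma multipliers around the
#' defaults) scored by venetian-blinds cross-validation on the calibration
#' set. Off by default in the study pipeline.
#'
#' @inheritParams svr_fit
#' @param n_splits CV blinds.
#' @return List with the winning `cost`, `epsilon`, `gamma` and the CV RMSE.
#' @export
svr_tune <- function(X, y, kernel = c("lin", "rbf"), n_splits = 7) {
  X <- as.matrix(X)
  kernel <- match.arg(kernel)
  n <- nrow(X)
  eps0 <- 0.01 * diff(range(y))
  gam0 <- 1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-12))
  grid <- expand.grid(cost = c(0.1, 1, 10),
                      epsilon = eps0 * c(0.5, 1, 2),
                      gamma = gam0 * c(0.1, 1, 10))
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    sse <- 0
    for (s in seq_len(min(n_splits, n - 1L))) {
      val <- seq(s, n, by = min(n_splits, n - 1L))
      cal <- setdiff(seq_len(n), val)
      fit <- svr_fit(X[cal, , drop = FALSE], y[cal], kernel,
                     cost = grid$cost[g], epsilon = grid$epsilon[g],
                     gamma = grid$gamma[g])
      sse <- sse + sum((svr_predict(fit, X[val, , drop = FALSE]) - y[val])^2)
    }
    rmse_cv <- sqrt(sse / n)
    if (is.null(best) || rmse_cv < best$rmse_cv)
      best <- list(cost = grid$cost[g], epsilon = grid$epsilon[g],
                   gamma = grid$gamma[g], rmse_cv = rmse_cv)
  }
  best
}

#' Root mean square error
#'
#' \eqn{\sqrt{\sum (\hat y - y)^2 / n}}, the RMSEC/RMSEP measure of
#' calibration and prediction accuracy.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  sqrt(mean((y_pred - y_true)^2))
}

#' F-test on the ratio of two RMSE values
#'
#' Two-sided F-test on the ratio of mean squared errors,
#' \eqn{F = \max(\mathrm{rmse}_1, \mathrm{rmse}_2)^2 /
#'          \min(\mathrm{rmse}_1, \mathrm{rmse}_2)^2},
#' with degrees of freedom equal to the corresponding sample counts — the
#' comparison used to judge whether low-level and mid-level fusion errors
#' differ at a stated significance level.
#'
#' @param rmse1,rmse2 positive RMSE values.
#' @param n1,n2 sample counts behind each RMSE (>= 2).
#' @param level significance level of the test (default 0.95).
#' @return List of class `f_test_result`: `F`, `df1`, `df2`, `p`,
#'   `significant` (`p < 1 - level`), `level`.
#' @export
f_test_rmse <- function(rmse1, rmse2, n1, n2, level = 0.95) {
  check_scalar(rmse1, "rmse1", 0)
  check_scalar(rmse2, "rmse2", 0)
  if (n1 < 2 || n2 < 2) stop("n1 and n2 must be >= 2")
  if (rmse1 >= rmse2) {
    F <- (rmse1 / rmse2)^2; df1 <- n1; df2 <- n2
  } else {
    F <- (rmse2 / rmse1)^2; df1 <- n2; df2 <- n1
  }
  p <- min(1, 2 * stats::pf(F, df1, df2, lower.tail = FALSE))
  structure(list(F = F, df1 = df1, df2 = df2, p = p,
                 significant = p < 1 - level, level = level),
            class = "f_test_result")
}

#' @export
print.f_test_result <- function(x, ...) {
  cat("F(", x$df1, ", ", x$df2, ") = ", format(x$F, digits = 4),
      ", p = ", format(x$p, digits = 4),
      if (x$significant) " (significant" else " (not significant",
      " at ", 100 * x$level, "%)\n", sep = "")
  invisible(x)
}
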