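# shared fixture builders and independent oracles

study_times <- seq(0, 310, length.out = 51)

# minimal series wrapper for hand-made matrices
mk_series <- function(X, technique = "raman", axis = NULL, times = NULL) {
  X <- as.matrix(X)
  spectral_series(technique,
                  axis %||% seq_len(ncol(X)),
                  times %||% seq_len(nrow(X)) - 1,
                  X)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# noiseless/noisy study-like single-technique series
study_series <- function(technique, k = 0.004, seed = 1, noise_frac = 0,
                         baseline_frac = 0, shift_sd = 0) {
  kin <- simulate_kinetics(k, 1, study_times)
  simulate_technique(technique, kin, seed = seed, noise_frac = noise_frac,
                     baseline_frac = baseline_frac, shift_sd = shift_sd)
}

# brute-force synchronous covariance (double loop over channel pairs)
brute_force_sync <- function(X1, X2) {
  m <- nrow(X1)
  phi <- matrix(0, ncol(X1), ncol(X2))
  for (i in seq_len(ncol(X1))) {
    xi <- X1[, i] - mean(X1[, i])
    for (j in seq_len(ncol(X2))) {
      xj <- X2[, j] - mean(X2[, j])
      phi[i, j] <- sum(xi * xj) / (m - 1)
    }
  }
  phi
}

# exhaustive active-set NNLS oracle: enumerate all sign supports, keep
# feasible candidates, return the quadratic-objective minimizer
brute_force_nnls <- function(AtA, Atb) {
  p <- length(Atb)
  best_x <- numeric(p)
  best_q <- 0  # empty support: x = 0, q = 0
  for (mask in seq_len(2^p - 1)) {
    P <- as.logical(bitwAnd(mask, 2^(seq_len(p) - 1)))
    xP <- tryCatch(solve(AtA[P, P, drop = FALSE], Atb[P]),
                   error = function(e) NULL)
    if (is.null(xP) || any(xP < 0)) next
    x <- numeric(p)
    x[P] <- xP
    q <- 0.5 * sum(x * (AtA %*% x)) - sum(Atb * x)
    if (q < best_q - 1e-15) {
      best_q <- q
      best_x <- x
    }
  }
  best_x
}

# channel index closest to a position
nearest_channel <- function(axis, pos) which.min(abs(axis - pos))
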