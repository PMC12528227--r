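#' Evolving factor analysis
#'
#' Singular values of growing forward windows (first \eqn{i} spectra,
#' \eqn{i = 2..m}) and backward windows (last \eqn{i} spectra) of the
#' series, used to detect when chemical components emerge and vanish and to
#' seed MCR-ALS.
#'
#' @param series a [spectral_series()] or numeric matrix
#'   (times x channels).
#' @param max_factors number of singular values recorded per window;
#'   must not exceed `min(n_times, n_channels)`.
#' @param times time vector when `series` is a bare matrix.
#' @return An object of class `efa_result` with `forward_sv` and
#'   `backward_sv` (`(m - 1) x max_factors`; forward row `i` covers spectra
#'   `1..(i + 1)`, backward row `i` covers the last `i + 1` spectra) and
#'   `times`.
#' @export
efa <- function(series, max_factors = 3, times = NULL) {
  if (is_spectral_series(series)) {
    X <- series$X
    times <- series$times
  } else {
    X <- as.matrix(series)
    times <- times %||% seq_len(nrow(X))
  }
  m <- nrow(X)
  if (max_factors > min(dim(X)))
    stop("max_factors must be <= min(n_times, n_channels) = ", min(dim(X)))
  if (m < 2L) stop("at least 2 spectra are required")
  window_sv <- function(idx) {
    sv <- La.svd(X[idx, , drop = FALSE], nu = 0, nv = 0)$d
    out <- numeric(max_factors)
    k <- min(max_factors, length(sv))
    out[seq_len(k)] <- sv[seq_len(k)]
    out
  }
  fwd <- t(vapply(2:m, function(i) window_sv(1:i), numeric(max_factors)))
  bwd <- t(vapply(2:m, function(i) window_sv((m - i + 1L):m),
                  numeric(max_factors)))
  structure(list(forward_sv = fwd, backward_sv = bwd, times = times),
            class = "efa_result")
}

#' Initial concentration profiles from EFA
#'
#' Standard EFA construction for a sequential system: component \eqn{i}'s
#' initial profile at time \eqn{t} is
#' \eqn{\min(\mathrm{fwd}_i(t), \mathrm{bwd}_{n-i+1}(t))}, where
#' \eqn{\mathrm{fwd}_i(t)} is the \eqn{i}-th forward singular value of the
#' window ending at \eqn{t} and \eqn{\mathrm{bwd}_j(t)} the \eqn{j}-th
#' backward singular value of the window starting at \eqn{t}. Values below a
#' noise floor (10th percentile of the smallest recorded singular values)
#' are clipped to zero and each profile is rescaled to [0, 1].
#'
#' @param efa_res an [efa()] result.
#' @param n_components number of components, at most the recorded factor
#'   count.
#' @return Matrix `m x n_components` of non-negative initial profiles.
#' @export
efa_initial_profiles <- function(efa_res, n_components = 2) {
  stopifnot(inherits(efa_res, "efa_result"))
  nf <- ncol(efa_res$forward_sv)
  if (n_components > nf)
    stop("n_components exceeds the ", nf, " recorded factors")
  m <- nrow(efa_res$forward_sv) + 1L
  floor_sv <- stats::quantile(c(efa_res$forward_sv[, nf],
                                efa_res$backward_sv[, nf]), 0.1,
                              names = FALSE)
  C0 <- matrix(0, m, n_components)
  for (ci in seq_len(n_components)) {
    fwd <- c(0, efa_res$forward_sv[, ci])              # value at time j
    bwd <- c(rev(efa_res$backward_sv[, n_components - ci + 1L]), 0)
    prof <- pmin(fwd, bwd)
    prof[prof < floor_sv] <- 0
    if (max(prof) > 0) prof <- prof / max(prof)
    C0[, ci] <- prof
  }
  C0
}
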