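#' Savitzky-Golay smoothing
#'
#' Smooths each spectrum (row) independently along the channel axis with a
#' Savitzky-Golay filter; the study default is an 11-point window with a
#' grade-3 polynomial. Axis and times are unchanged. A degree-3 filter
#' reproduces cubic signals exactly.
#'
#' @param series a [spectral_series()].
#' @param window odd filter length, > `polyorder`.
#' @param polyorder polynomial degree.
#' @return The smoothed [spectral_series()].
#' @export
savgol_smooth <- function(series, window = 11, polyorder = 3) {
  stopifnot(is_spectral_series(series))
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= polyorder) stop("window must be greater than polyorder")
  if (length(series$axis) < window)
    stop("series must have at least `window` channels")
  series$X <- t(apply(series$X, 1L, signal::sgolayfilt,
                      p = polyorder, n = window))
  series
}

#' Baseline correction
#'
#' Subtracts a per-spectrum smooth baseline estimate. Two standard
#' estimators are provided:
#' \describe{
#'   \item{`iterative_poly`}{iterative polynomial fitting with peak
#'     down-weighting (the fitted polynomial is re-fit to
#'     `pmin(signal, fit)` until it settles below the peaks).}
#'   \item{`asls`}{asymmetric least squares: Whittaker smoothing with
#'     asymmetric weights (`p` on points above the baseline, `1 - p`
#'     below), second-difference penalty `lambda`.}
#' }
#'
#' @param series a [spectral_series()].
#' @param method `"iterative_poly"` or `"asls"`.
#' @param degree polynomial degree for `iterative_poly`.
#' @param lambda smoothness penalty for `asls` (default 1e5).
#' @param p asymmetry parameter for `asls` (default 0.01).
#' @param max_iter iteration cap.
#' @return The corrected [spectral_series()].
#' @export
baseline_correct <- function(series, method = c("iterative_poly", "asls"),
                             degree = 4, lambda = 1e5, p = 0.01,
                             max_iter = 50) {
  stopifnot(is_spectral_series(series))
  if (!is.character(method) || !all(method %in% c("iterative_poly", "asls")))
    stop("unknown baseline method; allowed: iterative_poly, asls")
  method <- match.arg(method)
  est <- switch(method,
    iterative_poly = {
      u <- seq(-1, 1, length.out = length(series$axis))
      V <- stats::poly(u, degree = degree, raw = FALSE)
      V <- cbind(1, V)
      qrV <- qr(V)
      function(y) {
        yw <- y
        fit <- y
        for (i in seq_len(max_iter)) {
          fit <- qr.fitted(qrV, yw)
          yn <- pmin(yw, fit)
          if (max(abs(yn - yw)) < 1e-9 * max(1e-12, diff(range(y))))
            break
          yw <- yn
        }
        fit
      }
    },
    asls = {
      n <- length(series$axis)
      D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                              diagonals = list(rep(1, n - 2L),
                                               rep(-2, n - 2L),
                                               rep(1, n - 2L)))
      DtD <- lambda * Matrix::crossprod(D)
      function(y) {
        w <- rep(1, n)
        z <- y
        for (i in seq_len(max_iter)) {
          W <- Matrix::Diagonal(n, w)
          z <- as.numeric(Matrix::solve(W + DtD, w * y))
          w_new <- ifelse(y > z, p, 1 - p)
          if (identical(w_new, w)) break
          w <- w_new
        }
        z
      }
    })
  series$X <- t(apply(series$X, 1L, function(y) y - est(y)))
  series$meta$baseline_method <- method
  series
}

#' Normalize spectra to the highest peak
#'
#' Divides each spectrum (row) by its maximum absolute intensity so the
#' highest peak of every spectrum equals 1. All-zero rows are left unchanged
#' with a warning.
#'
#' @param series a [spectral_series()].
#' @return The normalized [spectral_series()].
#' @export
normalize_to_max <- function(series) {
  stopifnot(is_spectral_series(series))
  mx <- apply(abs(series$X), 1L, max)
  zero <- mx == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero spectra left unchanged")
    mx[zero] <- 1
  }
  series$X <- series$X / mx
  series
}

#' Reference NMR spectra to a target chemical shift
#'
#' Shifts each spectrum so that its global maximum (the solvent resonance in
#' the study system, acetonitrile at 1.96 ppm) sits at `target`, compensating
#' the shift drift of compact low-field magnets. The shift is applied by
#' axis translation followed by linear re-interpolation onto the common
#' grid; edge channels take the nearest value.
#'
#' @param series an NMR [spectral_series()].
#' @param target chemical shift (ppm) the highest peak is referenced to.
#' @return The referenced [spectral_series()].
#' @export
reference_to_peak <- function(series, target = 1.96) {
  stopifnot(is_spectral_series(series))
  if (series$technique != "nmr")
    stop("reference_to_peak applies to NMR series only")
  series$X <- t(apply(series$X, 1L, function(y) {
    shift <- target - series$axis[which.max(y)]
    if (shift == 0) return(y)
    stats::approx(series$axis + shift, y, xout = series$axis, rule = 2)$y
  }))
  series
}

#' Restrict a series to selected spectral regions
#'
#' Keeps only the channels falling inside the selection's windows (bounds
#' inclusive), preserving channel order; times are unchanged. Applying the
#' same selection twice is idempotent.
#'
#' @param series a [spectral_series()].
#' @param selection a [region_selection()] for the same technique.
#' @return The region-reduced [spectral_series()].
#' @export
select_regions <- function(series, selection) {
  stopifnot(is_spectral_series(series), inherits(selection, "region_selection"))
  if (selection$technique != series$technique)
    stop("selection is for technique '", selection$technique,
         "' but series is '", series$technique, "'")
  tol <- 1e-6 * mean(abs(diff(series$axis)))
  keep <- rep(FALSE, length(series$axis))
  for (i in seq_len(nrow(selection$windows))) {
    w <- selection$windows[i, ]
    inside <- series$axis >= w["lo"] - tol & series$axis <= w["hi"] + tol
    if (!any(inside))
      stop("window (", w["lo"], ", ", w["hi"],
           ") does not overlap the series axis")
    keep <- keep | inside
  }
  series$axis <- series$axis[keep]
  series$X <- series$X[, keep, drop = FALSE]
  series$meta$regions <- selection$windows
  series
}
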