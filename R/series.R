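#' @keywords internal
"_PACKAGE"

TECHNIQUES <- c("raman", "nir", "nmr")

#' Time-resolved spectral series
#'
#' Container for one technique's reaction-monitoring series: a spectral axis
#' (cm\eqn{^{-1}} for Raman/NIR, ppm for NMR), acquisition times in minutes,
#' and an intensity matrix with one row per acquisition.
#'
#' @param technique one of `"raman"`, `"nir"`, `"nmr"`.
#' @param axis numeric vector of channel positions, strictly monotone.
#' @param times numeric vector of acquisition times (minutes), strictly
#'   increasing.
#' @param X numeric intensity matrix, `length(times)` rows and
#'   `length(axis)` columns; all values finite.
#' @param meta list of free-form provenance (seed, noise level, generator
#'   parameters).
#' @return An object of class `spectral_series` with fields `technique`,
#'   `axis`, `times`, `X`, `meta`.
#' @export
spectral_series <- function(technique, axis, times, X, meta = list()) {
  technique <- match_technique(technique)
  axis <- as.numeric(axis)
  times <- as.numeric(times)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (length(axis) < 1L || anyNA(axis)) stop("axis must be non-empty numeric")
  d <- diff(axis)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("axis must be strictly monotone")
  if (length(times) < 1L || anyNA(times) || (length(times) > 1L && any(diff(times) <= 0)))
    stop("times must be strictly increasing")
  if (nrow(X) != length(times))
    stop("X must have one row per time point (", length(times), " expected)")
  if (ncol(X) != length(axis))
    stop("X must have one column per channel (", length(axis), " expected)")
  if (!all(is.finite(X))) stop("X must contain only finite values")
  structure(
    list(technique = technique, axis = axis, times = times, X = X, meta = meta),
    class = "spectral_series"
  )
}

match_technique <- function(technique) {
  if (length(technique) != 1L || !is.character(technique) ||
      !technique %in% TECHNIQUES)
    stop("unknown technique '", paste(technique, collapse = ","),
         "'; must be one of: ", paste(TECHNIQUES, collapse = ", "))
  technique
}

is_spectral_series <- function(x) inherits(x, "spectral_series")

#' @export
print.spectral_series <- function(x, ...) {
  cat("Spectral series [", x$technique, "]: ",
      length(x$times), " spectra x ", length(x$axis), " channels\n", sep = "")
  cat("  axis: ", format(min(x$axis)), " .. ", format(max(x$axis)),
      if (x$technique == "nmr") " ppm" else " cm-1", "\n", sep = "")
  cat("  times: ", format(min(x$times)), " .. ", format(max(x$times)),
      " min\n", sep = "")
  invisible(x)
}

#' @export
dim.spectral_series <- function(x) dim(x$X)

#' Write / read a spectral series as CSV
#'
#' The on-disk dialect is: first row the spectral axis, first column the
#' acquisition time in minutes, cell (i, j) the intensity; UTF-8, `.` decimal
#' separator, comma delimiter.
#'
#' @param series a [spectral_series()].
#' @param path file path.
#' @return `write_series` returns `path` invisibly; `read_series` returns a
#'   [spectral_series()].
#' @export
write_series <- function(series, path) {
  stopifnot(is_spectral_series(series))
  df <- data.frame(time = series$times, series$X, check.names = FALSE)
  colnames(df) <- c("time", format(series$axis, trim = TRUE, digits = 12))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_series
#' @param technique technique label to attach on read.
#' @export
read_series <- function(path, technique) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  axis <- as.numeric(colnames(df)[-1L])
  if (anyNA(axis)) stop("header row of ", path, " is not a numeric axis")
  spectral_series(technique, axis, df[[1L]],
                  as.matrix(df[, -1L, drop = FALSE]),
                  meta = list(source = path))
}

#' Spectral region selection
#'
#' A set of non-overlapping, ascending `(lo, hi)` windows on one technique's
#' axis, as used for region-reduced multivariate analysis.
#'
#' @param technique one of `"raman"`, `"nir"`, `"nmr"`.
#' @param windows two-column matrix or data frame of window bounds
#'   (`lo < hi`), in axis units; rows must be sorted ascending and must not
#'   overlap.
#' @return An object of class `region_selection`.
#' @export
region_selection <- function(technique, windows) {
  technique <- match_technique(technique)
  windows <- as.matrix(windows)
  if (ncol(windows) != 2L) stop("windows must have two columns (lo, hi)")
  storage.mode(windows) <- "double"
  colnames(windows) <- c("lo", "hi")
  if (any(windows[, "lo"] >= windows[, "hi"]))
    stop("each window must satisfy lo < hi")
  if (nrow(windows) > 1L) {
    o <- order(windows[, "lo"])
    windows <- windows[o, , drop = FALSE]
    if (any(windows[-1L, "lo"] <= windows[-nrow(windows), "hi"]))
      stop("windows must be non-overlapping")
  }
  structure(list(technique = technique, windows = windows),
            class = "region_selection")
}

#' @export
print.region_selection <- function(x, ...) {
  cat("Region selection [", x$technique, "]:\n", sep = "")
  apply(x$windows, 1L, function(w)
    cat("  ", format(w[1L]), " .. ", format(w[2L]), "\n", sep = ""))
  invisible(x)
}

#' Default selected regions
#'
#' The packaged per-technique window sets used for PCA and data fusion
#' (Raman 977-1049, 1231-1325, 1562-1709, 2785-2899 cm\eqn{^{-1}};
#' NIR 4004-4100, 5222-5307 cm\eqn{^{-1}}; NMR 3.43-5.00 ppm), stored in
#' `inst/extdata/selected_regions.csv` and overridable from the study config.
#'
#' @param technique one of `"raman"`, `"nir"`, `"nmr"`.
#' @return A [region_selection()].
#' @export
default_regions <- function(technique) {
  technique <- match_technique(technique)
  path <- system.file("extdata", "selected_regions.csv", package = "specfuse",
                      mustWork = TRUE)
  tab <- utils::read.csv(path)
  tab <- tab[tab$technique == technique, , drop = FALSE]
  region_selection(technique, tab[, c("lo", "hi")])
}
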