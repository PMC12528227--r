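#' Synchronous 2D heterocovariance map
#'
#' Covariance-transforms two spectral series along the shared perturbation
#' dimension (reaction time). Each series is mean-centered per channel over
#' time and the map is the sample covariance
#' \deqn{\Phi_{ij} = \frac{1}{m-1} \sum_t \tilde{x}_1(t, i)\,\tilde{x}_2(t, j),}
#' Noda's synchronous convention. Positive entries indicate simultaneous
#' signal change (product-product or reactant-reactant), negative entries a
#' reciprocal change (product-reactant).
#'
#' @param series1,series2 [spectral_series()] objects sharing the same time
#'   vector (acquisitions synchronized across techniques); at least two
#'   spectra each.
#' @return An object of class `correlation_map` with fields `axis1`,
#'   `axis2`, `phi` (`n1 x n2`), `m`, `techniques`.
#' @export
sync_map <- function(series1, series2) {
  stopifnot(is_spectral_series(series1), is_spectral_series(series2))
  if (length(series1$times) != length(series2$times) ||
      any(series1$times != series2$times))
    stop("series must share the same time vector; resample/align the ",
         "acquisitions before computing the map")
  m <- length(series1$times)
  if (m < 2L) stop("at least 2 spectra are required (m >= 2)")
  X1 <- scale(series1$X, center = TRUE, scale = FALSE)
  X2 <- scale(series2$X, center = TRUE, scale = FALSE)
  phi <- crossprod(X1, X2) / (m - 1)
  structure(list(axis1 = series1$axis, axis2 = series2$axis,
                 phi = unname(phi), m = m,
                 techniques = c(series1$technique, series2$technique)),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat("Synchronous heterocovariance map ", x$techniques[1L], " x ",
      x$techniques[2L], ": ", nrow(x$phi), " x ", ncol(x$phi),
      " (m = ", x$m, ")\n", sep = "")
  invisible(x)
}

#' Ranked signed correlation peaks
#'
#' Extracts local extrema of the absolute covariance intensity (strictly
#' largest within their 3x3 neighborhood), labels each in-phase (positive)
#' or anti-phase (negative), and returns up to `n` of them sorted by
#' decreasing magnitude. Ties are broken by lower (axis1, axis2) position.
#'
#' @param map a [sync_map()] result.
#' @param n maximum number of peaks, >= 1.
#' @param threshold minimum absolute intensity, >= 0.
#' @return Data frame with columns `pos1`, `pos2`, `intensity`, `phase`
#'   (`"in_phase"`/`"anti_phase"`); zero rows when nothing qualifies.
#' @export
top_correlations <- function(map, n = 10, threshold = 0) {
  stopifnot(inherits(map, "correlation_map"))
  if (n < 1) stop("n must be >= 1")
  if (threshold < 0) stop("threshold must be >= 0")
  A <- abs(map$phi)
  n1 <- nrow(A); n2 <- ncol(A)
  pad <- matrix(-Inf, n1 + 2L, n2 + 2L)
  pad[2:(n1 + 1L), 2:(n2 + 1L)] <- A
  is_max <- matrix(TRUE, n1, n2)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max &
      (A > pad[(2:(n1 + 1L)) + di, (2:(n2 + 1L)) + dj])
  }
  cand <- which(is_max & A > threshold & A > 0, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(pos1 = numeric(0), pos2 = numeric(0),
                      intensity = numeric(0), phase = character(0)))
  val <- A[cand]
  o <- order(-val, cand[, 1L], cand[, 2L])
  cand <- cand[o[seq_len(min(n, length(o)))], , drop = FALSE]
  intensity <- map$phi[cand]
  data.frame(pos1 = map$axis1[cand[, 1L]], pos2 = map$axis2[cand[, 2L]],
             intensity = intensity,
             phase = ifelse(intensity > 0, "in_phase", "anti_phase"))
}

#' Suggest spectral regions from a heterocovariance map
#'
#' Projects the maximum absolute covariance onto one axis, thresholds it at
#' a fraction of its maximum, and merges contiguous above-threshold channels
#' into windows — the data-driven region reduction used ahead of PCA and
#' data fusion.
#'
#' @param map a [sync_map()] result.
#' @param axis which axis to project onto (1 or 2).
#' @param threshold_fraction fraction of the projected maximum, in (0, 1).
#' @return A [region_selection()] for the chosen axis's technique.
#' @export
suggest_regions <- function(map, axis = 1, threshold_fraction = 0.1) {
  stopifnot(inherits(map, "correlation_map"))
  if (!axis %in% c(1, 2)) stop("axis must be 1 or 2")
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  A <- abs(map$phi)
  proj <- if (axis == 1) apply(A, 1L, max) else apply(A, 2L, max)
  ax <- if (axis == 1) map$axis1 else map$axis2
  sel <- proj >= threshold_fraction * max(proj)
  r <- rle(sel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  windows <- cbind(lo = ax[starts[keep]], hi = ax[ends[keep]])
  # single-channel runs: widen to a degenerate-but-valid window of one step
  step <- mean(abs(diff(ax)))
  one <- windows[, "hi"] <= windows[, "lo"]
  windows[one, "hi"] <- windows[one, "lo"] + step / 2
  region_selection(map$techniques[axis], windows)
}

#' Export a heterocovariance map as CSV and contour figure
#'
#' Writes `<path>.csv` (the covariance matrix with axis1 as row labels and
#' axis2 as column labels) and `<path>.png`, a contour rendering with
#' positive levels in blue and negative levels in red.
#'
#' @param map a [sync_map()] result.
#' @param path output path base name (without extension).
#' @param thresholds optional positive contour magnitudes; defaults to six
#'   levels spread over the data range. Levels outside the data range simply
#'   draw no contours.
#' @return Invisibly, a list with the two file paths.
#' @export
export_contour <- function(map, path, thresholds = NULL) {
  stopifnot(inherits(map, "correlation_map"))
  csv_path <- paste0(path, ".csv")
  fig_path <- paste0(path, ".png")
  df <- data.frame(axis1 = map$axis1, map$phi, check.names = FALSE)
  colnames(df) <- c("axis1", format(map$axis2, trim = TRUE, digits = 12))
  ok <- tryCatch({
    utils::write.csv(df, csv_path, row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("cannot write to ", csv_path, ": ",
                              conditionMessage(e)))
  amax <- max(abs(map$phi))
  lv <- thresholds %||% (if (amax > 0) seq(0.1, 0.9, length.out = 6) * amax
                         else numeric(0))
  lv <- abs(lv)
  grDevices::png(fig_path, width = 700, height = 600)
  on.exit(grDevices::dev.off())
  graphics::plot(range(map$axis1), range(map$axis2), type = "n",
                 xlab = map$techniques[1L], ylab = map$techniques[2L],
                 main = "Synchronous heterocovariance map")
  pos <- lv[lv > 0 & lv < max(map$phi)]
  neg <- -lv[-lv > min(map$phi) & lv > 0]
  if (length(pos))
    graphics::contour(map$axis1, map$axis2, map$phi, levels = pos,
                      col = "blue", add = TRUE, drawlabels = FALSE)
  if (length(neg))
    graphics::contour(map$axis1, map$axis2, map$phi, levels = neg,
                      col = "red", add = TRUE, drawlabels = FALSE)
  invisible(list(csv = csv_path, figure = fig_path))
}
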