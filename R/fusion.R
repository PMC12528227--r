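#' Low-level data fusion
#'
#' Horizontally concatenates region-selected series from several techniques
#' into pseudo-spectra (one fused row per acquisition time), recording the
#' feature ranges contributed by each block.
#'
#' @param series_list list of [spectral_series()] sharing the same time
#'   vector.
#' @param y target concentration vector, one value per time point.
#' @return An object of class `fused_dataset` with `level = "low"`, the
#'   fused matrix `X`, `block_boundaries` (data frame with `technique`,
#'   `start`, `end`, 1-based inclusive), `y`, and empty `cal_idx`/`val_idx`
#'   (see [split_calibration()]).
#' @export
low_level_fuse <- function(series_list, y) {
  if (!length(series_list) || !all(vapply(series_list, is_spectral_series,
                                          logical(1))))
    stop("series_list must be a non-empty list of spectral series")
  times <- series_list[[1L]]$times
  for (s in series_list)
    if (length(s$times) != length(times) || any(s$times != times))
      stop("all series must share the same time vector")
  y <- as.numeric(y)
  if (length(y) != length(times)) stop("y must have one value per time point")
  widths <- vapply(series_list, function(s) length(s$axis), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  bb <- data.frame(
    technique = vapply(series_list, function(s) s$technique, character(1)),
    start = starts, end = ends)
  X <- do.call(cbind, lapply(series_list, function(s) s$X))
  structure(list(level = "low", X = X, block_boundaries = bb, y = y,
                 cal_idx = NULL, val_idx = NULL),
            class = "fused_dataset")
}

#' @export
print.fused_dataset <- function(x, ...) {
  cat(x$level, "-level fused dataset: ", nrow(x$X), " pseudo-spectra x ",
      ncol(x$X), " features (", nrow(x$block_boundaries), " blocks)\n",
      sep = "")
  if (!is.null(x$cal_idx))
    cat("  split: ", length(x$cal_idx), " calibration / ",
        length(x$val_idx), " validation\n", sep = "")
  invisible(x)
}

# deterministic calibration/validation index split
calibration_split <- function(n, cal_fraction = 2 / 3,
                              scheme = c("interleaved", "chronological")) {
  if (cal_fraction <= 0 || cal_fraction >= 1)
    stop("cal_fraction must be in (0, 1)")
  scheme <- match.arg(scheme)
  if (scheme == "interleaved") {
    period <- round(1 / (1 - cal_fraction))
    val <- seq.int(period, n, by = period)
  } else {
    n_cal <- round(cal_fraction * n)
    val <- if (n_cal < n) seq.int(n_cal + 1L, n) else integer(0)
  }
  if (length(val) == 0L || length(val) == n)
    stop("cal_fraction yields an empty calibration or validation set")
  list(cal_idx = setdiff(seq_len(n), val), val_idx = val)
}

#' Split a fused dataset into calibration and validation sets
#'
#' Deterministic split, no randomness. The default interleaved scheme sends
#' every third acquisition (ranks 3, 6, ...) to validation so both sets span
#' the whole kinetic range; for the study's 51 pseudo-spectra at
#' `cal_fraction = 2/3` this gives 34 calibration and 17 validation
#' spectra. A chronological scheme (first fraction calibrates) is available
#' for comparison.
#'
#' @param dataset a `fused_dataset`.
#' @param cal_fraction calibration fraction in (0, 1), default 2/3.
#' @param scheme `"interleaved"` (default) or `"chronological"`.
#' @return The dataset with `cal_idx` and `val_idx` filled (disjoint, union
#'   covering all rows).
#' @export
split_calibration <- function(dataset, cal_fraction = 2 / 3,
                              scheme = c("interleaved", "chronological")) {
  stopifnot(inherits(dataset, "fused_dataset"))
  sp <- calibration_split(nrow(dataset$X), cal_fraction, scheme)
  dataset$cal_idx <- sp$cal_idx
  dataset$val_idx <- sp$val_idx
  dataset
}

#' Mid-level data fusion
#'
#' Per-technique feature extraction followed by score concatenation: for
#' each block a mean-centered PCA with `n_lv` latent variables is fitted on
#' the calibration rows only; calibration scores are concatenated into the
#' calibration design and validation rows are projected through the
#' calibration-fitted block models (no leakage of validation data into
#' centering or loadings). For the study configuration (three techniques,
#' `n_lv = 5`) the fused design has 15 features.
#'
#' @param series_list list of region-selected [spectral_series()] sharing
#'   the same time vector.
#' @param y target concentration vector.
#' @param n_lv latent variables per block (default 5).
#' @param split list with `cal_idx` and `val_idx` (e.g. a split
#'   `fused_dataset` or [split_calibration()] output).
#' @return A `fused_dataset` with `level = "mid"`; block PCA models are kept
#'   in the `block_models` field.
#' @export
mid_level_fuse <- function(series_list, y, n_lv = 5, split) {
  low <- low_level_fuse(series_list, y)  # validates shapes and times
  if (is.null(split$cal_idx) || is.null(split$val_idx))
    stop("split must provide cal_idx and val_idx")
  cal <- split$cal_idx
  val <- split$val_idx
  n <- nrow(low$X)
  if (n_lv < 1) stop("n_lv must be >= 1")
  scores <- vector("list", length(series_list))
  models <- vector("list", length(series_list))
  for (b in seq_along(series_list)) {
    Xb <- series_list[[b]]$X
    if (n_lv > min(length(cal) - 1L, ncol(Xb)))
      stop("n_lv = ", n_lv, " exceeds the rank bound of block '",
           series_list[[b]]$technique, "'")
    mod <- pca_fit(Xb[cal, , drop = FALSE], n_pc = n_lv, center = TRUE)
    sc <- matrix(NA_real_, n, n_lv)
    sc[cal, ] <- mod$scores
    sc[val, ] <- pca_project(mod, Xb[val, , drop = FALSE])
    scores[[b]] <- sc
    models[[b]] <- mod
  }
  widths <- rep(n_lv, length(series_list))
  ends <- cumsum(widths)
  bb <- data.frame(
    technique = vapply(series_list, function(s) s$technique, character(1)),
    start = ends - widths + 1L, end = ends)
  structure(list(level = "mid", X = do.call(cbind, scores),
                 block_boundaries = bb, y = as.numeric(y),
                 cal_idx = cal, val_idx = val, block_models = models),
            class = "fused_dataset")
}

#' Calibrate PLS and SVR models on a fused dataset
#'
#' Fits PLS (latent-variable count picked by venetian-blinds CV on the
#' calibration set, capped at `pls_max_lv`), SVR-lin and SVR-rbf on the
#' calibration rows and evaluates RMSEC (calibration) and RMSEP
#' (validation).
#'
#' @param dataset a split `fused_dataset`.
#' @param pls_max_lv cap for the PLS LV search (default 10).
#' @param svr_cost,svr_epsilon,svr_gamma optional SVR hyperparameters
#'   (defaults as in [svr_fit()]).
#' @return List with `metrics` (data frame: `model`, `rmsec`, `rmsep`),
#'   `pls_n_lv`, and the fitted models.
#' @export
fit_fusion_models <- function(dataset, pls_max_lv = 10, svr_cost = 1,
                              svr_epsilon = NULL, svr_gamma = NULL) {
  stopifnot(inherits(dataset, "fused_dataset"))
  if (is.null(dataset$cal_idx)) stop("dataset must be split first")
  cal <- dataset$cal_idx
  val <- dataset$val_idx
  Xc <- dataset$X[cal, , drop = FALSE]
  Xv <- dataset$X[val, , drop = FALSE]
  yc <- dataset$y[cal]
  yv <- dataset$y[val]
  n_lv <- choose_n_lv(Xc, yc, max_lv = pls_max_lv)
  pls <- pls_fit(Xc, yc, n_lv = n_lv)
  svr_l <- svr_fit(Xc, yc, "lin", cost = svr_cost, epsilon = svr_epsilon,
                   gamma = svr_gamma)
  svr_r <- svr_fit(Xc, yc, "rbf", cost = svr_cost, epsilon = svr_epsilon,
                   gamma = svr_gamma)
  metrics <- data.frame(
    model = c("PLS", "SVR rbf", "SVR lin"),
    rmsec = c(rmse(yc, pls_predict(pls, Xc)),
              rmse(yc, svr_predict(svr_r, Xc)),
              rmse(yc, svr_predict(svr_l, Xc))),
    rmsep = c(rmse(yv, pls_predict(pls, Xv)),
              rmse(yv, svr_predict(svr_r, Xv)),
              rmse(yv, svr_predict(svr_l, Xv))))
  list(metrics = metrics, pls_n_lv = n_lv,
       models = list(pls = pls, svr_rbf = svr_r, svr_lin = svr_l))
}
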