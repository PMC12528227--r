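#' Spectral peak descriptor
#'
#' @param center band/resonance position in axis units (cm\eqn{^{-1}} or ppm).
#' @param width full width at half maximum in axis units, > 0.
#' @param amplitude peak intensity, >= 0.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @param owner `"reactant"`, `"product"`, `"solvent"` or `"water"`; water
#'   bands scale with product concentration (condensation byproduct),
#'   solvent bands are constant in time.
#' @return One-row data frame describing the peak.
#' @export
peak <- function(center, width, amplitude, shape = "gaussian",
                 owner = "product") {
  check_scalar(center, "center", strict = FALSE)
  check_scalar(width, "width", 0)
  check_scalar(amplitude, "amplitude", 0, strict = FALSE)
  shape <- match.arg(shape, c("gaussian", "lorentzian"))
  owner <- match.arg(owner, c("reactant", "product", "solvent", "water"))
  data.frame(center = center, width = width, amplitude = amplitude,
             shape = shape, owner = owner, stringsAsFactors = FALSE)
}

#' Per-technique component peak library
#'
#' Encodes the assigned bands/resonances of the monitored Schiff base
#' formation (acetophenone + benzylamine -> N-benzylimine + water in
#' acetonitrile) for each technique:
#' \itemize{
#'   \item Raman (Lorentzian lines, 200-3000 cm\eqn{^{-1}} at 1 cm\eqn{^{-1}}):
#'     product C=N 1630, C=C 1595, 1290, 995 and N-CH\eqn{_2} stretch
#'     2850 cm\eqn{^{-1}} (anti-phase with the benzylamine resonances in the
#'     heterocovariance maps); reactant C=O 1685 and 1250 cm\eqn{^{-1}};
#'     dominant solvent nitrile stretch 2248 cm\eqn{^{-1}}.
#'   \item NIR (Gaussian bands, 4000-10000 cm\eqn{^{-1}} at 2 cm\eqn{^{-1}}):
#'     product band near 4050 cm\eqn{^{-1}}, water combination band
#'     5260 cm\eqn{^{-1}} (grows with product), reactant band near
#'     4400 cm\eqn{^{-1}}.
#'   \item \eqn{^1}H NMR (Gaussian lines, 0-10 ppm at 0.005 ppm): product
#'     methyl 2.32 and imine methylene 4.76 ppm; reactant methyl 2.59 and
#'     benzylamine methylene 3.85 ppm; dominant solvent methyl 1.96 ppm;
#'     overlapping aromatic envelope at 7-8 ppm carried by both reactant and
#'     product (unresolved at low field).
#' }
#'
#' @param technique one of `"raman"`, `"nir"`, `"nmr"`.
#' @param axis_step optional grid spacing override (axis units).
#' @return An object of class `component_library` with fields `technique`,
#'   `peaks` (data frame), `axis_lo`, `axis_hi`, `axis_step`.
#' @examples
#' lib <- make_component_library("raman")
#' subset(lib$peaks, owner == "product")
#' @export
make_component_library <- function(technique, axis_step = NULL) {
  technique <- match_technique(technique)
  spec <- switch(technique,
    raman = list(lo = 200, hi = 3000, step = 1, peaks = rbind(
      peak(1630, 14, 1.00, "lorentzian", "product"),
      peak(1595, 12, 0.55, "lorentzian", "product"),
      peak(1290, 12, 0.45, "lorentzian", "product"),
      peak(995, 10, 0.35, "lorentzian", "product"),
      peak(2850, 18, 0.50, "lorentzian", "product"),
      peak(1685, 14, 0.90, "lorentzian", "reactant"),
      peak(1250, 12, 0.40, "lorentzian", "reactant"),
      peak(2248, 12, 2.50, "lorentzian", "solvent"))),
    nir = list(lo = 4000, hi = 10000, step = 2, peaks = rbind(
      peak(4050, 80, 0.80, "gaussian", "product"),
      peak(5260, 100, 1.00, "gaussian", "water"),
      peak(4400, 90, 0.90, "gaussian", "reactant"))),
    nmr = list(lo = 0, hi = 10, step = 0.005, peaks = rbind(
      peak(2.32, 0.05, 0.80, "gaussian", "product"),
      peak(4.76, 0.05, 0.70, "gaussian", "product"),
      peak(7.40, 0.25, 0.90, "gaussian", "product"),
      peak(2.59, 0.05, 0.80, "gaussian", "reactant"),
      peak(3.85, 0.05, 0.70, "gaussian", "reactant"),
      peak(7.30, 0.25, 1.20, "gaussian", "reactant"),
      peak(1.96, 0.05, 3.00, "gaussian", "solvent")))
  )
  step <- axis_step %||% spec$step
  check_scalar(step, "axis_step", 0)
  stopifnot(all(spec$peaks$center >= spec$lo & spec$peaks$center <= spec$hi))
  structure(list(technique = technique, peaks = spec$peaks,
                 axis_lo = spec$lo, axis_hi = spec$hi, axis_step = step),
            class = "component_library")
}

library_axis <- function(library) {
  seq(library$axis_lo, library$axis_hi, by = library$axis_step)
}

eval_peak <- function(center, width, amplitude, shape, axis) {
  if (shape == "gaussian") {
    amplitude * exp(-4 * log(2) * (axis - center)^2 / width^2)
  } else {
    hw2 <- (width / 2)^2
    amplitude * hw2 / ((axis - center)^2 + hw2)
  }
}

#' Pure-component spectra of a library
#'
#' Evaluates the library's peaks on its axis and sums them per kinetic
#' component. Water bands are folded into the product component (they grow
#' proportionally to product concentration); solvent bands form a separate
#' constant component when present.
#'
#' @param library a [make_component_library()] result.
#' @param axis optional axis override.
#' @return Matrix `n_components x n_channels` with rownames among
#'   `"reactant"`, `"product"`, `"solvent"`.
#' @export
component_spectra <- function(library, axis = NULL) {
  stopifnot(inherits(library, "component_library"))
  axis <- axis %||% library_axis(library)
  comp_of <- c(reactant = "reactant", product = "product",
               water = "product", solvent = "solvent")
  comps <- c("reactant", "product")
  if (any(library$peaks$owner == "solvent")) comps <- c(comps, "solvent")
  S <- matrix(0, length(comps), length(axis),
              dimnames = list(comps, NULL))
  for (i in seq_len(nrow(library$peaks))) {
    p <- library$peaks[i, ]
    S[comp_of[[p$owner]], ] <- S[comp_of[[p$owner]], ] +
      eval_peak(p$center, p$width, p$amplitude, p$shape, axis)
  }
  S
}

#' Synthesize a time-resolved spectral series
#'
#' Bilinear Beer-Lambert-like generative model
#' \eqn{X = C S^\top + B + E}: `C` holds the kinetic concentration
#' trajectories (reactant, product, plus a constant solvent channel when the
#' library has solvent peaks), `S` the pure-component spectra from the
#' library, `B` a smooth per-spectrum quadratic baseline whose coefficients
#' follow a slow random walk across acquisitions, and `E` i.i.d. Gaussian
#' noise. Identical seed and arguments give bit-identical output.
#'
#' @param library a [make_component_library()] result.
#' @param kinetics a [simulate_kinetics()] result.
#' @param baseline_amplitude typical baseline magnitude (intensity units),
#'   >= 0.
#' @param noise_sd additive noise standard deviation (intensity units), >= 0.
#' @param seed integer RNG seed.
#' @param shift_sd standard deviation of a per-spectrum axis shift (axis
#'   units), emulating chemical-shift drift of a compact NMR magnet;
#'   default 0.
#' @return A [spectral_series()]; `meta` records all generator parameters.
#' @export
synthesize_series <- function(library, kinetics, baseline_amplitude = 0,
                              noise_sd = 0, seed = 1, shift_sd = 0) {
  stopifnot(inherits(library, "component_library"),
            inherits(kinetics, "kinetic_profile"))
  check_scalar(baseline_amplitude, "baseline_amplitude", 0, strict = FALSE)
  check_scalar(noise_sd, "noise_sd", 0, strict = FALSE)
  check_scalar(shift_sd, "shift_sd", 0, strict = FALSE)
  axis <- library_axis(library)
  m <- length(kinetics$times)
  n <- length(axis)
  S <- component_spectra(library, axis)
  C <- cbind(reactant = kinetics$c_reactant, product = kinetics$c_product)
  if ("solvent" %in% rownames(S))
    C <- cbind(C, solvent = rep(kinetics$c0, m))

  with_seed(seed, {
    # slow random-walk quadratic baseline coefficients (one walk per degree)
    coefs <- vapply(1:3, function(j)
      stats::rnorm(1) / 2 + cumsum(stats::rnorm(m, 0, 0.1)), numeric(m))
    shifts <- if (shift_sd > 0) stats::rnorm(m, 0, shift_sd) else numeric(m)
    E <- if (noise_sd > 0)
      matrix(stats::rnorm(m * n, 0, noise_sd), m, n) else 0

    X <- if (shift_sd > 0) {
      Xs <- matrix(0, m, n)
      for (i in seq_len(m)) {
        Si <- component_spectra(library, axis - shifts[i])
        Xs[i, ] <- C[i, rownames(Si)] %*% Si
      }
      Xs
    } else {
      C[, rownames(S), drop = FALSE] %*% S
    }
    if (baseline_amplitude > 0) {
      u <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
      B <- baseline_amplitude *
        (coefs[, 1L] %o% rep(1, n) + coefs[, 2L] %o% u + coefs[, 3L] %o% u^2)
      X <- X + B
    }
    X <- X + E
  })

  spectral_series(library$technique, axis, kinetics$times, X,
                  meta = list(seed = seed, noise_sd = noise_sd,
                              baseline_amplitude = baseline_amplitude,
                              shift_sd = shift_sd, k = kinetics$k,
                              stoich = kinetics$stoich, c0 = kinetics$c0))
}

#' Simulate one technique at study-like conditions
#'
#' Convenience wrapper: builds the technique's component library, scales the
#' noise and baseline magnitudes relative to the maximum noiseless signal,
#' and synthesizes the series.
#'
#' @param technique one of `"raman"`, `"nir"`, `"nmr"`.
#' @param kinetics a [simulate_kinetics()] result.
#' @param seed integer RNG seed.
#' @param noise_frac noise standard deviation as a fraction of the maximum
#'   noiseless signal (default 0.01, i.e. 1 percent).
#' @param baseline_frac baseline magnitude as a fraction of the maximum
#'   noiseless signal.
#' @param shift_sd per-spectrum axis shift SD (axis units).
#' @return A [spectral_series()].
#' @export
simulate_technique <- function(technique, kinetics, seed, noise_frac = 0.01,
                               baseline_frac = 0, shift_sd = 0) {
  lib <- make_component_library(technique)
  S <- component_spectra(lib)
  C <- cbind(kinetics$c_reactant, kinetics$c_product)
  if ("solvent" %in% rownames(S)) C <- cbind(C, kinetics$c0)
  peak_max <- max(C %*% S)
  synthesize_series(lib, kinetics,
                    baseline_amplitude = baseline_frac * peak_max,
                    noise_sd = noise_frac * peak_max,
                    seed = seed, shift_sd = shift_sd)
}

#' Generate the full synthetic study dataset
#'
#' Emulates the monitoring campaign: 51 spectra per technique over a 310-min
#' window (a `strict_5min` flag restores exact 5-min spacing, 63 spectra),
#' one shared kinetic profile across the three techniques, 1 percent additive
#' noise and 5 percent slowly drifting baseline by default.
#'
#' @param k ground-truth rate constant in min\eqn{^{-1}} (default 0.004).
#' @param seed integer RNG seed (per-technique sub-seeds are derived from
#'   it).
#' @param n_times number of acquisitions (default 51).
#' @param t_max monitoring window length in minutes (default 310).
#' @param strict_5min if `TRUE`, use a strict 5-min schedule
#'   (`seq(0, t_max, by = 5)`) instead of `n_times` equispaced points.
#' @param noise_frac,baseline_frac,shift_sd forwarded to
#'   [simulate_technique()].
#' @param stoich reactant:product coefficient (default 1.5).
#' @return Named list with `raman`, `nir`, `nmr` ([spectral_series()]) and
#'   `kinetics` (the shared [simulate_kinetics()] profile).
#' @examples
#' ds <- make_study_dataset(seed = 1)
#' nrow(ds$raman$X)  # 51
#' @export
make_study_dataset <- function(k = 0.004, seed, n_times = 51, t_max = 310,
                               strict_5min = FALSE, noise_frac = 0.01,
                               baseline_frac = 0.05, shift_sd = 0,
                               stoich = 1.5) {
  if (missing(seed)) stop("seed must be given")
  times <- if (strict_5min) seq(0, t_max, by = 5)
           else seq(0, t_max, length.out = n_times)
  kin <- simulate_kinetics(k, 1, times, stoich = stoich)
  out <- lapply(seq_along(TECHNIQUES), function(i)
    simulate_technique(TECHNIQUES[i], kin, seed = seed * 3 + (i - 1L),
                       noise_frac = noise_frac,
                       baseline_frac = baseline_frac,
                       shift_sd = if (TECHNIQUES[i] == "nmr") shift_sd else 0))
  names(out) <- TECHNIQUES
  out$kinetics <- kin
  out
}
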