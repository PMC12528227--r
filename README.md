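# specfuse

Chemometric workflow for multi-technique spectroscopic reaction monitoring,
built around a model condensation: a Schiff base (N-benzylimine) forming
from acetophenone and benzylamine in acetonitrile, followed inline/online
by NIR, Raman and low-field ¹H NMR over a 310-min window (51 acquisitions
per technique).

The package is aimed at process-analytical chemists who want to go from
raw time-resolved spectra to (i) assignments and region selection, (ii)
reaction kinetics, and (iii) quantitative calibration models, without a
reference assay. Because no public spectra accompany the study system, the
package ships a synthetic generator that reproduces the campaign's
structure, so every stage is testable end to end.

## What it computes

**Synthetic generator.** Bilinear Beer–Lambert-like series
`X = C Sᵀ + B + E`: concentrations `C` follow first-order
`1.5 A → B` kinetics (`c_A(t) = c₀ e^{−kt}`,
`c_B(t) = (c₀ − c_A(t))/1.5`, closure exact), `S` holds per-technique
component spectra at the assigned band positions (e.g. Raman C=N
1630 cm⁻¹ / C=O 1685 cm⁻¹; NMR methylene 4.76 / 3.85 ppm; NIR water
5260 cm⁻¹), `B` a slowly drifting quadratic baseline, `E` i.i.d. noise.

**Preprocessing.** Savitzky–Golay smoothing (11-point, grade 3), baseline
correction (iterative polynomial or asymmetric least squares),
normalization to the highest peak, NMR referencing to the solvent
resonance at 1.96 ppm, and inclusive-bounds region selection.

**Synchronous 2D heterocovariance spectroscopy.** For two series sharing
the perturbation (reaction-time) axis,

```
Φ(i, j) = 1/(m−1) · Σₜ x̃₁(t, i) · x̃₂(t, j)
```

with per-channel mean centering; positive entries mark co-varying
(same-species) channel pairs, negative entries reactant–product pairs.
Ranked signed peak extraction and data-driven region suggestion follow.

**Kinetic MCR-ALS.** Evolving factor analysis seeds a two-component
multivariate curve resolution `X ≈ C S` by alternating least squares with
non-negativity on both profiles (FNNLS, Bro–De Jong active set) and a hard
kinetic constraint: each iteration the rate constant is re-fitted
(start k₀ = 0.005 min⁻¹) and `C` is replaced by the integrated rate law.
Alternative rate laws (A→B→C, A+B→C, A+B→C→D) can be screened by fit
diagnostics.

**Data fusion + calibration.** Low-level fusion concatenates
region-selected spectra into pseudo-spectra; mid-level fusion concatenates
per-block PCA scores (5 mean-centered latent variables per technique,
fitted on calibration rows only). A deterministic 2/3 interleaved split
(51 → 34 calibration / 17 validation) feeds PLS and ε-SVR (linear and RBF)
models; RMSEC/RMSEP are compared by a two-sided F-test on the MSE ratio.

## Worked example

```r
library(specfuse)
cfg <- default_config()
cfg$generator$k <- 0.0041          # ground-truth rate constant, min^-1
rep <- run_study(cfg, seed = 7)
print(rep)
```

```
Study report (seed 7, config fc6d245f)

MCR-ALS rate constants (min^-1):
 technique       k_fit       lof
     raman 0.004063585  8.546597
       nir 0.004129190 11.282674
       nmr 0.004102505 12.129797

Calibration metrics (34 cal / 17 val):
   model   low_rmsec   low_rmsep   mid_rmsec   mid_rmsep
     PLS 0.001056022 0.007213533 0.002959389 0.004127845
 SVR rbf 0.010418631 0.015669241 0.005031375 0.008055535
 SVR lin 0.004590505 0.009963925 0.003643184 0.005119402

F-tests:
                 comparison        F df1 df2           p significant
      PLS: low vs mid RMSEP 3.053861  17  17 0.026849999        TRUE
  SVR rbf: low vs mid RMSEP 3.783616  17  17 0.008955753        TRUE
  SVR lin: low vs mid RMSEP 3.788109  17  17 0.008898653        TRUE
 PLS vs SVR rbf RMSEP (low) 4.718456  17  17 0.002576548        TRUE
 PLS vs SVR rbf RMSEP (mid) 3.808395  17  17 0.008645751        TRUE
```

All three techniques recover the simulated rate constant within ~1%
(0.00406–0.00413 vs 0.0041 min⁻¹). The lack of fit (8–12%) reflects the
noise-to-signal energy ratio of sparse-band spectra, not unexplained
structure. PLS beats both SVR variants on this run, and within each model
the low- and mid-level RMSEP differ by a factor the F-test flags at 95%.
`run_study(..., outdir = "...")` additionally writes the metrics tables,
heterocovariance maps (CSV + contour PNG), the generated series and a JSON
run summary, byte-identically reproducible for a fixed config and seed.

Single stages are available directly:

```r
ds  <- make_study_dataset(k = 0.0041, seed = 42)   # 3 x 51 spectra
map <- sync_map(ds$raman, ds$nmr)                  # heterocovariance map
top_correlations(map, n = 10)                      # signed peak pairs
res <- mcr_kinetic_fit(baseline_correct(ds$nmr))   # EFA + kinetic MCR-ALS
res$k_fit
```

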