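test_that("component libraries carry the assigned bands per technique", {
  raman <- make_component_library("raman")
  expect_true(any(raman$peaks$center == 1630 & raman$peaks$owner == "product"))
  expect_true(any(raman$peaks$center == 1685 & raman$peaks$owner == "reactant"))
  expect_true(any(raman$peaks$center == 2248 & raman$peaks$owner == "solvent"))

  nmr <- make_component_library("nmr")
  expect_true(any(nmr$peaks$center == 3.85 & nmr$peaks$owner == "reactant"))
  expect_true(any(nmr$peaks$center == 4.76 & nmr$peaks$owner == "product"))
  expect_true(any(nmr$peaks$center == 1.96 & nmr$peaks$owner == "solvent"))
  # overlapping aromatic envelope carried by both species
  arom <- nmr$peaks[nmr$peaks$center >= 7 & nmr$peaks$center <= 8, ]
  expect_setequal(arom$owner, c("reactant", "product"))

  nir <- make_component_library("nir")
  expect_true(any(nir$peaks$center == 5260 & nir$peaks$owner == "water"))
  expect_true(any(abs(nir$peaks$center - 4400) < 50 &
                    nir$peaks$owner == "reactant"))
  expect_true(all(sapply(list(raman, nir, nmr), function(l)
    all(l$peaks$center >= l$axis_lo & l$peaks$center <= l$axis_hi))))

  expect_error(make_component_library("ftir"), "raman.*nir.*nmr")
})

test_that("kinetics follow the closed form with exact closure", {
  kp0 <- simulate_kinetics(0.0041, 1, times = 0)
  expect_equal(kp0$c_reactant, 1)
  expect_equal(kp0$c_product, 0)

  # closed form cross-checked against numerical integration of dA/dt = -kA
  kp <- simulate_kinetics(0.01, 1, times = c(0, 100), stoich = 1.5)
  ode <- deSolve::ode(c(A = 1), c(0, 100),
                      function(t, y, p) list(-0.01 * y), NULL,
                      rtol = 1e-12, atol = 1e-14)
  expect_equal(kp$c_reactant[2], exp(-1), tolerance = 1e-10)
  expect_equal(kp$c_reactant[2], unname(ode[2, "A"]), tolerance = 1e-8)
  expect_equal(kp$c_product[2], (1 - exp(-1)) / 1.5, tolerance = 1e-10)

  kp <- simulate_kinetics(0.0041, 1, seq(0, 310, by = 5))
  expect_true(all(diff(kp$c_reactant) < 0))
  expect_true(all(diff(kp$c_product) > 0))
  expect_lt(max(abs(kp$c_reactant + 1.5 * kp$c_product - 1)), 1e-12)

  expect_error(simulate_kinetics(-0.1, 1, 0:10), "k")
  expect_error(simulate_kinetics(0.01, 0, 0:10), "c0")
  expect_error(simulate_kinetics(0.01, 1, c(0, 5, 5)), "increasing")
})

test_that("closure holds for arbitrary positive k, c0, stoich", {
  set.seed(11)
  for (i in 1:20) {
    k <- runif(1, 1e-4, 0.5)
    c0 <- runif(1, 0.1, 5)
    st <- runif(1, 0.5, 3)
    kp <- simulate_kinetics(k, c0, sort(runif(20, 0, 400)), stoich = st)
    expect_lt(max(abs(kp$c_reactant + st * kp$c_product - c0)), 1e-12)
  }
})

test_that("synthesized series are bilinear, deterministic and noise-calibrated", {
  kin <- simulate_kinetics(0.004, 1, study_times)
  lib <- make_component_library("nmr")

  clean <- synthesize_series(lib, kin, 0, 0, seed = 3)
  sv <- svd(clean$X)$d
  expect_lt(sv[4] / sv[1], 1e-10)  # rank <= 3 with solvent

  nir_clean <- synthesize_series(make_component_library("nir"), kin, 0, 0,
                                 seed = 3)
  expect_lt(svd(nir_clean$X)$d[3] / svd(nir_clean$X)$d[1], 1e-10)  # no solvent

  # sign structure on noiseless output
  expect_true(all(diff(clean$X[, nearest_channel(clean$axis, 4.76)]) >= 0))
  expect_true(all(diff(clean$X[, nearest_channel(clean$axis, 3.85)]) <= 0))

  a <- synthesize_series(lib, kin, 0.05, 0.01, seed = 9)
  b <- synthesize_series(lib, kin, 0.05, 0.01, seed = 9)
  expect_identical(a$X, b$X)
  c2 <- synthesize_series(lib, kin, 0.05, 0.01, seed = 10)
  expect_false(identical(a$X, c2$X))

  # residual standard deviation matches the requested noise level
  target_sd <- 0.01 * max(clean$X)
  noisy <- synthesize_series(lib, kin, 0, target_sd, seed = 5)
  expect_equal(sd(noisy$X - clean$X), target_sd, tolerance = 0.1)

  expect_error(synthesize_series(lib, kin, -1, 0), "baseline_amplitude")
  expect_error(synthesize_series(lib, kin, 0, -1), "noise_sd")
})

test_that("study dataset matches the monitoring campaign layout", {
  ds <- make_study_dataset(seed = 1)
  expect_equal(nrow(ds$raman$X), 51)
  expect_equal(nrow(ds$nir$X), 51)
  expect_equal(nrow(ds$nmr$X), 51)
  expect_identical(ds$raman$times, ds$nir$times)
  expect_identical(ds$raman$times, ds$nmr$times)
  expect_equal(range(ds$raman$times), c(0, 310))

  ds5 <- make_study_dataset(seed = 1, strict_5min = TRUE)
  expect_equal(nrow(ds5$raman$X), 63)
  expect_equal(diff(ds5$raman$times)[1], 5)

  # noiseless product trace at the NIR water band reaches the closed-form
  # conversion fraction at t = 310
  ds_clean <- make_study_dataset(k = 0.0077, seed = 2, noise_frac = 0,
                                 baseline_frac = 0)
  lib <- make_component_library("nir")
  S <- component_spectra(lib)
  ch <- nearest_channel(ds_clean$nir$axis, 5260)
  frac <- unname(ds_clean$nir$X[51, ch] / S["product", ch])
  expect_equal(frac, (1 - exp(-0.0077 * 310)) / 1.5, tolerance = 1e-8)

  expect_error(make_study_dataset(), "seed")
})

test_that("series CSV dialect round-trips", {
  ser <- study_series("raman", seed = 4, noise_frac = 0.01)
  path <- tempfile(fileext = ".csv")
  write_series(ser, path)
  back <- read_series(path, "raman")
  expect_equal(back$axis, ser$axis)
  expect_equal(back$times, ser$times)
  expect_equal(back$X, ser$X, ignore_attr = TRUE, tolerance = 1e-10)
})
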