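test_that("fnnls solves the textbook cases", {
  expect_equal(fnnls(diag(2), c(1, -1)), c(1, 0))

  set.seed(41)
  # unconstrained optimum already non-negative -> equals ordinary LS
  A <- matrix(rnorm(40), 10)
  x_true <- c(2, 1, 0.5, 3)
  b <- A %*% x_true
  expect_lt(max(abs(fnnls(crossprod(A), crossprod(A, b)[, 1]) - x_true)),
            1e-10)

  expect_error(fnnls(diag(3), c(1, 2)), "match")
})

test_that("fnnls agrees with exhaustive active-set enumeration", {
  set.seed(42)
  for (i in 1:40) {
    A <- matrix(rnorm(24), 6, 4)
    b <- rnorm(6)
    AtA <- crossprod(A)
    Atb <- crossprod(A, b)[, 1]
    expect_lt(max(abs(fnnls(AtA, Atb) - brute_force_nnls(AtA, Atb))), 1e-8)
  }
})

test_that("EFA tracks rank across growing windows", {
  kin <- simulate_kinetics(0.004, 1, study_times)
  rank1 <- spectral_series("raman", 1:30, study_times,
                           kin$c_product %o% runif(30))
  e1 <- efa(rank1, max_factors = 2)
  expect_true(all(e1$forward_sv[, 2] < 1e-10 * e1$forward_sv[, 1]))
  expect_true(all(e1$backward_sv[, 2] < 1e-10 * e1$backward_sv[, 1]))

  two <- select_regions(study_series("raman", seed = 1),
                        default_regions("raman"))
  e2 <- efa(two, max_factors = 3)
  full <- e2$forward_sv[nrow(e2$forward_sv), ]
  expect_equal(sum(full > 1e-8 * full[1]), 2)

  # interlacing: adding a spectrum cannot shrink any singular value
  set.seed(43)
  er <- efa(mk_series(matrix(rnorm(8 * 6), 8)), max_factors = 3)
  expect_true(all(diff(er$forward_sv) > -1e-10))
  expect_true(all(diff(er$backward_sv) > -1e-10))

  expect_error(efa(two, max_factors = 100), "max_factors")
})

test_that("EFA initial profiles have the sequential-system shapes", {
  ser <- study_series("nmr", seed = 2, noise_frac = 0.01)
  C0 <- efa_initial_profiles(efa(ser, 3), 2)
  expect_true(all(C0 >= 0) && all(C0 <= 1))
  # first profile tracks the vanishing species, second the emerging one
  t_idx <- seq_along(study_times)
  expect_lt(cor(C0[, 1], t_idx), -0.5)
  expect_gt(cor(C0[, 2], t_idx), 0.5)

  # rank-1 data, one component: min(forward, backward) gives a non-negative
  # unimodal envelope of the component's presence
  kin <- simulate_kinetics(0.004, 1, study_times)
  rank1 <- spectral_series("raman", 1:30, study_times,
                           kin$c_product %o% runif(30))
  p1 <- efa_initial_profiles(efa(rank1, 2), 1)[, 1]
  expect_true(all(p1 >= 0) && max(p1) == 1)
  peak_at <- which.max(p1)
  expect_true(all(diff(p1[seq_len(peak_at)]) >= -1e-10))
  expect_true(all(diff(p1[peak_at:length(p1)]) <= 1e-10))

  expect_error(efa_initial_profiles(efa(ser, 2), 5), "factors")
})

test_that("rate-constant fitting recovers exact and perturbed profiles", {
  mod <- kinetic_model("first_order_1p5AtoB")
  Cx <- kinetic_profiles(mod, study_times, params = 0.0041)
  f <- fit_rate_constant(Cx, study_times, mod, k0 = 0.005)
  expect_equal(unname(f$k_fit), 0.0041, tolerance = 1e-6 / 0.0041)
  expect_true(f$converged)

  # insensitive to a 10x-off start within the basin
  f10 <- fit_rate_constant(Cx, study_times, mod, k0 = 0.05)
  expect_equal(unname(f10$k_fit), unname(f$k_fit), tolerance = 1e-8)

  set.seed(44)
  errs <- replicate(10, {
    Cn <- Cx + matrix(rnorm(length(Cx), 0, 0.01), nrow(Cx))
    abs(unname(fit_rate_constant(Cn, study_times, mod)$k_fit) - 0.0041) /
      0.0041
  })
  expect_lt(median(errs), 0.05)

  expect_error(fit_rate_constant(Cx[, 1, drop = FALSE], study_times, mod),
               "components")
})

test_that("kinetic model profiles satisfy their balances", {
  expect_error(kinetic_model("AtoD"), "first_order_1p5AtoB")
  mabc <- kinetic_model("AtoBtoC", params = c(0.01, 0.003))
  P <- kinetic_profiles(mabc, study_times)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  # closed form cross-checked against numerical integration
  ode <- deSolve::ode(c(A = 1, B = 0, C = 0), study_times,
                      function(t, y, p)
                        list(c(-0.01 * y[1], 0.01 * y[1] - 0.003 * y[2],
                               0.003 * y[2])), NULL,
                      rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(P - ode[, -1])), 1e-7)

  Pab <- kinetic_profiles(kinetic_model("ApBtoC", params = 0.02),
                          study_times)
  expect_lt(max(abs((Pab[, "A"] - Pab[, "B"]) - 0.5)), 1e-6)  # excess amine
  expect_lt(max(abs(Pab[, "B"] + Pab[, "C"] - 1)), 1e-6)
})

test_that("MCR-ALS is a fixed point on exact bilinear data", {
  ser <- select_regions(study_series("raman", seed = 1),
                        default_regions("raman"))
  lib <- make_component_library("raman")
  S_true <- component_spectra(lib, ser$axis)[c("reactant", "product"), ]
  kin <- simulate_kinetics(0.004, 1, study_times)
  C_true <- cbind(kin$c_reactant, kin$c_product)

  res <- mcr_als(ser, C_true)
  expect_lte(res$n_iter, 2)
  expect_lt(res$lof, 1e-6)

  # profile recovery up to positive per-component scale
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  hard <- mcr_als(ser, efa_initial_profiles(efa(ser, 3), 2),
                  model = kinetic_model("first_order_1p5AtoB"))
  for (j in 1:2) {
    expect_gt(cosine(hard$C[, j], C_true[, j]), 0.99)
    expect_gt(cosine(hard$S[j, ], S_true[j, ]), 0.99)
  }
  expect_equal(unname(hard$k_fit), 0.004, tolerance = 1e-4)

  expect_error(mcr_als(matrix(0, 5, 4), matrix(1, 5, 2)), "zero")
})

test_that("lack of fit decreases monotonically in soft mode", {
  set.seed(45)
  for (i in 1:5) {
    C <- cbind(exp(-0.01 * (0:19)), 1 - exp(-0.01 * (0:19)))
    S <- matrix(runif(2 * 15), 2)
    X <- C %*% S + matrix(rnorm(20 * 15, 0, 0.02), 20)
    res <- mcr_als(abs(X), matrix(runif(40), 20, 2), max_iter = 50)
    expect_true(all(diff(res$lof_trace) <= 1e-12))
  }
})

test_that("noisy study-like series resolve into the assigned bands", {
  res <- mcr_kinetic_fit(study_series("raman", seed = 7, noise_frac = 0.01))
  ser <- select_regions(study_series("raman", seed = 7, noise_frac = 0.01),
                        default_regions("raman"))
  # irreducible noise lack of fit from the known noise realization
  clean <- select_regions(study_series("raman", seed = 7),
                          default_regions("raman"))
  lof_noise <- 100 * sqrt(sum((ser$X - clean$X)^2) / sum(ser$X^2))
  expect_lt(res$lof, 2 * lof_noise)
  # component 1 = reactant (largest initial concentration), 2 = product
  expect_lt(abs(ser$axis[which.max(res$S[1, ])] - 1685), 3)
  expect_lt(abs(ser$axis[which.max(res$S[2, ])] - 1630), 3)
  expect_equal(unname(res$k_fit), 0.004, tolerance = 0.05)
})

test_that("model comparison exposes superfluous components", {
  ser <- study_series("nir", seed = 9, noise_frac = 0.01)
  tab <- compare_models(ser, list(kinetic_model("first_order_1p5AtoB"),
                                  kinetic_model("AtoBtoC")))
  expect_equal(nrow(tab), 2)
  expect_true(all(diff(tab$lof) >= 0))  # sorted by lack of fit
  row2 <- tab[tab$model == "first_order_1p5AtoB", ]
  rowABC <- tab[tab$model == "AtoBtoC", ]
  expect_equal(row2$n_effective_components, 2)
  # the working model fits at least as well (within the noise floor)
  expect_lte(row2$lof, rowABC$lof * 1.05)

  one <- compare_models(ser, list(kinetic_model("AtoB")))
  expect_equal(nrow(one), 1)

  twice <- compare_models(ser, list(kinetic_model("AtoB"),
                                    kinetic_model("AtoB")))
  expect_equal(twice[1, ], twice[2, ], ignore_attr = TRUE)

  expect_error(compare_models(ser, list()), "non-empty")
})
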