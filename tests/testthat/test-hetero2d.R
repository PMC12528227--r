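test_that("synchronous map matches hand computations and the brute-force oracle", {
  s1 <- mk_series(matrix(c(0, 1, 2), 3))
  s2 <- mk_series(matrix(c(0, 2, 4), 3))
  expect_equal(sync_map(s1, s2)$phi, matrix(2), ignore_attr = TRUE)
  s3 <- mk_series(matrix(c(4, 2, 0), 3))
  expect_equal(sync_map(s1, s3)$phi, matrix(-2), ignore_attr = TRUE)

  # constant channel annihilated by mean centering
  s4 <- mk_series(cbind(c(0, 1, 2), c(7, 7, 7)))
  expect_equal(sync_map(s4, s4)$phi[2, ], c(0, 0))

  set.seed(21)
  for (i in 1:20) {
    m <- sample(2:10, 1)
    X1 <- matrix(rnorm(m * sample(1:8, 1)), m)
    X2 <- matrix(rnorm(m * sample(1:8, 1)), m)
    map <- sync_map(mk_series(X1, times = seq_len(m)),
                    mk_series(X2, "nmr", times = seq_len(m)))
    expect_lt(max(abs(map$phi - brute_force_sync(X1, X2))), 1e-12)
    # argument order transposes the map
    expect_equal(t(map$phi),
                 sync_map(mk_series(X2, "nmr", times = seq_len(m)),
                          mk_series(X1, times = seq_len(m)))$phi)
  }
})

test_that("map is bilinear and self-maps are positive semidefinite", {
  set.seed(22)
  X1 <- matrix(rnorm(40), 5)
  X2 <- matrix(rnorm(30), 5)
  m1 <- sync_map(mk_series(X1), mk_series(X2, "nmr"))
  m3 <- sync_map(mk_series(3.7 * X1), mk_series(X2, "nmr"))
  expect_equal(m3$phi, 3.7 * m1$phi)

  self <- sync_map(mk_series(X1), mk_series(X1))
  expect_equal(self$phi, t(self$phi))
  ev <- eigen(self$phi, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * sum(diag(self$phi)))

  expect_error(sync_map(mk_series(X1), mk_series(X2[1:4, ], "nmr")),
               "align")
  expect_error(sync_map(mk_series(X1[1, , drop = FALSE]),
                        mk_series(X2[1, , drop = FALSE], "nmr")), "m >= 2")
})

test_that("correlation peaks reproduce the reactant/product sign structure", {
  raman <- study_series("raman", k = 0.004, seed = 1)
  nmr <- study_series("nmr", k = 0.004, seed = 2)
  map <- sync_map(raman, nmr)

  # product-product pair in phase, product-reactant pair anti phase
  i1630 <- nearest_channel(map$axis1, 1630)
  expect_gt(map$phi[i1630, nearest_channel(map$axis2, 4.76)], 0)
  expect_gt(map$phi[i1630, nearest_channel(map$axis2, 2.32)], 0)
  expect_lt(map$phi[i1630, nearest_channel(map$axis2, 2.59)], 0)
  expect_lt(map$phi[nearest_channel(map$axis1, 2850),
                    nearest_channel(map$axis2, 3.85)], 0)

  peaks <- top_correlations(map, n = 50)
  near <- function(p1, p2) peaks[abs(peaks$pos1 - p1) <= 2 &
                                   abs(peaks$pos2 - p2) <= 0.02, ]
  expect_equal(near(1630, 4.76)$phase, "in_phase")
  expect_equal(near(1630, 2.59)$phase, "anti_phase")
  expect_true(all(peaks$phase == ifelse(peaks$intensity > 0,
                                        "in_phase", "anti_phase")))
  expect_true(all(diff(abs(peaks$intensity)) <= 1e-15))  # sorted
})

test_that("peak extraction handles degenerate maps", {
  zero <- structure(list(axis1 = 1:4, axis2 = 1:5,
                         phi = matrix(0, 4, 5), m = 3,
                         techniques = c("raman", "nmr")),
                    class = "correlation_map")
  expect_equal(nrow(top_correlations(zero, 5)), 0)

  spike <- zero
  spike$phi[2, 3] <- 1.5
  tc <- top_correlations(spike, 5)
  expect_equal(nrow(tc), 1)
  expect_equal(tc$pos1, 2)
  expect_equal(tc$pos2, 3)
  expect_equal(tc$phase, "in_phase")
})

test_that("region suggestion finds the covarying bands", {
  raman <- study_series("raman", seed = 1)
  nmr <- study_series("nmr", seed = 2)
  map <- sync_map(raman, nmr)
  sel <- suggest_regions(map, axis = 1, threshold_fraction = 0.1)
  covers <- function(sel, x)
    any(sel$windows[, "lo"] <= x & sel$windows[, "hi"] >= x)
  expect_true(covers(sel, 1630))
  expect_true(covers(sel, 1685))
  expect_equal(sel$technique, "raman")

  # threshold -> 1 keeps at most the global-maximum channel
  sel1 <- suggest_regions(map, axis = 1, threshold_fraction = 1 - 1e-9)
  expect_lte(nrow(sel1$windows), 1)
  argmax <- map$axis1[which.max(apply(abs(map$phi), 1, max))]
  expect_true(covers(sel1, argmax))

  # coherent kinetic structure concentrates the windows; incoherent random
  # traces spread them out
  sel5 <- suggest_regions(map, axis = 1, threshold_fraction = 0.5)
  coverage <- function(sel, n_axis, step = 1)
    sum(sel$windows[, "hi"] - sel$windows[, "lo"] + step) / (n_axis * step)
  frac_struct <- coverage(sel5, length(map$axis1))
  expect_lt(frac_struct, 0.2)
  set.seed(33)
  r1 <- mk_series(matrix(rnorm(20 * 50), 20), times = 1:20)
  r2 <- mk_series(matrix(rnorm(20 * 50), 20), "nmr", times = 1:20)
  selr <- suggest_regions(sync_map(r1, r2), axis = 1,
                          threshold_fraction = 0.5)
  frac_noise <- coverage(selr, 50)
  expect_gt(frac_noise, frac_struct)

  expect_error(suggest_regions(map, axis = 1, threshold_fraction = 1.2),
               "threshold_fraction")
})

test_that("contour export round-trips the covariance matrix", {
  set.seed(5)
  map <- sync_map(mk_series(matrix(rnorm(24), 4), axis = c(10, 20, 30, 35, 40, 50)),
                  mk_series(matrix(rnorm(12), 4), "nmr", axis = c(1, 2, 3)))
  base <- file.path(tempdir(), "map_test")
  paths <- export_contour(map, base)
  expect_true(file.exists(paths$csv))
  expect_true(file.exists(paths$figure))
  back <- utils::read.csv(paths$csv, check.names = FALSE)
  expect_equal(as.numeric(back[[1]]), map$axis1)
  expect_equal(as.numeric(colnames(back)[-1]), map$axis2)
  expect_lt(max(abs(as.matrix(back[, -1]) - map$phi)), 1e-12)

  # thresholds excluding every value still render without error
  expect_no_error(export_contour(map, file.path(tempdir(), "map_empty"),
                                 thresholds = max(abs(map$phi)) * 10))
})
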