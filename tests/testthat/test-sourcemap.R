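# Covariance pooling, LCMV weights, coefficient mapping, amplitude sums and
# baseline Z-scoring.

test_that("white-noise covariance approaches the identity", {
  fs <- 1000
  nch <- 4
  set.seed(5)
  data <- array(rnorm(nch * 1e6), c(1, nch, 1e6))
  ts <- trial_set(data, fs, time_s = (seq_len(1e6) - 1) / fs)
  C <- broadband_covariance(ts)
  expect_equal(diag(C), rep(1, nch), tolerance = 0.01)
  off <- C[upper.tri(C)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("covariance removes means and ignores trial order", {
  fs <- 100
  data <- array(7, c(2, 3, 500))
  ts <- trial_set(data, fs, time_s = (seq_len(500) - 1) / fs)
  expect_equal(broadband_covariance(ts), matrix(0, 3, 3))
  set.seed(8)
  d2 <- array(rnorm(4 * 3 * 500), c(4, 3, 500))
  ts2 <- trial_set(d2, fs, time_s = (seq_len(500) - 1) / fs)
  expect_equal(broadband_covariance(ts2), broadband_covariance(ts2[4:1]))
})

test_that("LCMV reduces to normalized leadfield columns for white noise", {
  fwd <- small_forward(30, 12)
  G <- fwd$leadfield$gain
  Tr <- lcmv_transfer(fwd$leadfield, diag(12), reg_lambda = 0)
  expected <- t(sweep(G, 2, colSums(G^2), "/"))
  expect_equal(Tr$T, expected, tolerance = 1e-10)
  # unit gain holds with an arbitrary PSD covariance too
  set.seed(2)
  A <- matrix(rnorm(144), 12)
  Tr2 <- lcmv_transfer(fwd$leadfield, crossprod(A) / 12, reg_lambda = 0.05)
  expect_equal(unname(diag(Tr2$T %*% G)), rep(1, ncol(G)), tolerance = 1e-6)
  expect_error(lcmv_transfer(fwd$leadfield, diag(5)), "channel count")
  expect_error(lcmv_transfer(fwd$leadfield, diag(12), reg_lambda = -1),
               "reg_lambda")
})

test_that("a noiseless single source maximizes output variance at its vertex", {
  fwd <- small_forward(100, 16, seed = 12)
  v <- 37L
  g <- fwd$leadfield$gain[, v]
  fs <- 400
  ns <- 2000
  set.seed(3)
  s <- rnorm(ns)
  data <- array(0, c(1, 16, ns))
  data[1, , ] <- g %o% s
  ts <- trial_set(data, fs, time_s = (seq_len(ns) - 1) / fs)
  C <- suppressWarnings(broadband_covariance(ts))
  Tr <- lcmv_transfer(fwd$leadfield, C, reg_lambda = 0.05)
  Y <- Tr$T %*% matrix(data[1, , ], nrow = 16)
  expect_equal(which.max(apply(Y, 1, var)), v)
})

test_that("beamforming commutes with the wavelet transform", {
  fwd <- small_forward(30, 10, seed = 6)
  s <- quick_session(n_per_hand = 2, n_channels = 10, n_vertices = 30,
                     seed = 15, fwd = fwd)
  ts <- s$trials
  C <- broadband_covariance(ts)
  Tr <- lcmv_transfer(fwd$leadfield, C)
  d <- morlet_transform(ts, 70:74)
  j1 <- map_coefficients(Tr, d)
  # transform the beamformed time series instead
  nV <- nrow(Tr$T)
  ysrc <- array(0, c(dim(ts$data)[1], nV, dim(ts$data)[3]))
  for (i in seq_len(dim(ts$data)[1]))
    ysrc[i, , ] <- Tr$T %*% matrix(ts$data[i, , ], nrow = 10)
  ts2 <- trial_set(ysrc, ts$fs, time_s = ts$time_s, labels = ts$labels)
  j2 <- morlet_transform(ts2, 70:74)
  rel <- max(Mod(j1$coef - j2$coef)) / max(Mod(j1$coef))
  expect_lt(rel, 1e-8)
  expect_equal(j1$domain, "source")
  expect_error(map_coefficients(matrix(1, 3, 4), d), "channel count")
})

test_that("identity mapping and zero coefficients pass through", {
  fs <- 400
  ts <- as_trials(array(rnorm(2 * 3 * 800), c(2, 3, 800)), fs)
  d <- morlet_transform(ts, 70:72)
  j <- map_coefficients(diag(3), d)
  expect_equal(j$coef, d$coef)
  d0 <- morlet_transform(as_trials(array(0, c(1, 3, 800)), fs), 70:72)
  expect_true(all(map_coefficients(diag(3), d0)$coef == 0))
})

test_that("amplitude and power sums follow the printed formulas", {
  coef <- array(2 + 0i, c(2, 1, 4, 3))   # |j| = 2 everywhere, N = 3
  j <- tf_coefficients(coef, 80, c(-0.5, 0, 0.5, 1), "source",
                       matrix(TRUE, 1, 4), 2)
  m <- average_amplitude(j, baseline_s = c(-0.5, 0.5), signal_s = c(0.5, 1.5))
  expect_true(all(m$a == 6))
  expect_true(all(m$p == 12))
  expect_equal(m$n_trials, 3)
  m1 <- average_amplitude(j, retain = 2)
  expect_true(all(m1$a == 2))            # N = 1: a = |j|
  # duplicating trials doubles both sums (no 1/N anywhere)
  coef6 <- array(2 + 0i, c(2, 1, 4, 6))
  j6 <- tf_coefficients(coef6, 80, c(-0.5, 0, 0.5, 1), "source",
                        matrix(TRUE, 1, 4), 2)
  m6 <- average_amplitude(j6)
  expect_equal(m6$a, 2 * m$a)
  expect_equal(m6$p, 2 * m$p)
  expect_error(average_amplitude(j, retain = integer(0)), "retained")
})

test_that("baseline Z-scores follow the (n-1) arithmetic", {
  # baseline samples {1, 2, 3}, signal sample 4 -> Z = 2
  a <- array(c(1, 2, 3, 4), c(1, 1, 4))
  m <- map_from_a(a, time_s = c(-1, -2 / 3, -1 / 3, 0))
  m <- zscore_baseline(m)
  expect_equal(m$z[1, 1, 4], 2)
  expect_equal(m$z[1, 1, 1], -1)

  # flat post-cue amplitude at the baseline mean gives Z = 0
  a2 <- array(c(1, 3, 2, 2), c(1, 1, 4))
  m2 <- zscore_baseline(map_from_a(a2, time_s = c(-1, -0.5, 0, 0.5),
                                   baseline_s = c(-1, 0)))
  expect_true(all(m2$z[1, 1, 3:4] == 0))

  # constant amplitude: zero baseline SD -> invalid, reported
  a3 <- array(5, c(2, 1, 4))
  expect_message(m3 <- zscore_baseline(map_from_a(a3, c(-1, -0.5, 0, 0.5))),
                 "zero baseline SD")
  expect_true(all(m3$invalid_loc))
  expect_true(all(is.na(m3$z)))
})

test_that("Z maps are invariant to global amplitude rescaling", {
  s <- quick_session(n_per_hand = 3, n_channels = 10, n_vertices = 30,
                     seed = 19)
  ts <- s$trials
  fit1 <- hg_fit(ts, s$fwd$leadfield, decim = 16)
  ts2 <- trial_set(ts$data * 3.7, ts$fs, ts$time_s, ts$labels)
  fit2 <- hg_fit(ts2, s$fwd$leadfield, decim = 16)
  expect_equal(fit1$map$z, fit2$map$z, tolerance = 1e-8)
})
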