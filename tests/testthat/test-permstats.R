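# Maximum statistic, segment swapping, the permutation null and its
# statistical properties.

# Magnitude-space null generator: i.i.d. positive magnitudes, no effect.
null_magnitudes <- function(n_v = 6, n_f = 4, n_trials = 12, L = 10, fs = 10) {
  time_s <- seq(-1, 1 - 1 / fs, by = 1 / fs)
  mag <- array(abs(rnorm(n_v * n_f * length(time_s) * n_trials)) + 0.1,
               c(n_v, n_f, length(time_s), n_trials))
  list(mag = mag, time_s = time_s)
}

test_that("max_statistic respects window, ties and validity", {
  a <- array(0, c(20, 3, 8))
  time_s <- seq(-1, 0.75, by = 0.25)
  m <- map_from_a(a + 1, time_s, freqs_hz = c(80, 81, 82))
  m$z <- array(0, dim(a))
  m$z[12, 2, 7] <- 7                       # t = 0.5 s, f = 81, v = 12
  m$invalid_loc <- matrix(FALSE, 20, 3)
  pk <- max_statistic(m)
  expect_equal(pk$statistic, 7)
  expect_equal(pk$vertex, 12)
  expect_equal(pk$freq_hz, 81)
  expect_equal(pk$time_s, 0.5)

  # a larger value outside the signal window is ignored
  m$z[3, 1, 1] <- 50                       # t = -1 s
  expect_equal(max_statistic(m)$statistic, 7)

  # all-equal map: lowest (vertex, freq, time) wins
  m$z <- array(1, dim(a))
  pk2 <- max_statistic(m)
  expect_equal(pk2$vertex, 1)
  expect_equal(pk2$freq_hz, 80)
  expect_equal(pk2$time_s, 0)
})

test_that("segment swapping is an involution that conserves values", {
  set.seed(4)
  nm <- null_magnitudes()
  b_idx <- which(nm$time_s < 0)
  s_idx <- which(nm$time_s >= 0)
  swapped <- swap_segments(nm$mag, c(2, 5, 9), b_idx, s_idx)
  expect_false(identical(swapped, nm$mag))
  expect_identical(swap_segments(swapped, c(2, 5, 9), b_idx, s_idx), nm$mag)
  # the multiset of values within each trial is conserved
  for (i in c(2, 5, 9))
    expect_equal(sort(as.vector(swapped[, , , i])),
                 sort(as.vector(nm$mag[, , , i])))
})

test_that("p-values follow the add-one rule", {
  expect_equal(perm_pvalue(10, rep(1, 999)), 1 / 1000)
  expect_equal(perm_pvalue(0, rep(1, 999)), 1)
  null <- seq_len(99)
  expect_lt(abs(perm_pvalue(50, null) - 0.5), 1 / 100 + 1e-12)
  expect_error(perm_pvalue(1, numeric(0)), "null")
})

test_that("the null is exactly reproducible from the seed", {
  set.seed(11)
  nm <- null_magnitudes()
  spec <- perm_spec(freqs_hz = 1:4, n_perm = 50, seed = 42)
  n1 <- permutation_null(nm$mag, spec, time_s = nm$time_s)
  n2 <- permutation_null(nm$mag, spec, time_s = nm$time_s)
  expect_identical(n1, n2)
  spec2 <- perm_spec(freqs_hz = 1:4, n_perm = 50, seed = 43)
  expect_false(identical(n1, permutation_null(nm$mag, spec2,
                                              time_s = nm$time_s)))
  expect_length(n1, 50)
  expect_true(all(is.finite(n1)))
})

test_that("perm_spec enforces window and count contracts", {
  expect_error(perm_spec(baseline_s = c(-1, 0), signal_s = c(0, 0.5)),
               "equal length")
  expect_error(perm_spec(baseline_s = c(-0.5, 0.5), signal_s = c(0, 1)),
               "disjoint")
  expect_error(perm_spec(n_perm = 10), "19")
})

test_that("under exchangeable segments the test is level-alpha (super-uniform)", {
  set.seed(99)
  n_sim <- 200
  p <- vapply(seq_len(n_sim), function(s) {
    nm <- null_magnitudes()
    spec <- perm_spec(freqs_hz = 1:4, n_perm = 99, seed = 1000 + s)
    null <- permutation_null(nm$mag, spec, time_s = nm$time_s)
    # observed statistic from the unswapped data, same machinery
    m <- map_from_a(rowSums(nm$mag, dims = 3), nm$time_s, freqs_hz = 1:4)
    m <- zscore_baseline(m)
    perm_pvalue(max_statistic(m)$statistic, null)
  }, 0)
  for (alpha in c(0.01, 0.05, 0.1)) {
    se <- sqrt(alpha * (1 - alpha) / n_sim)
    expect_lte(mean(p <= alpha), alpha + 3 * se)
  }
  # and not wildly conservative either
  expect_gt(mean(p <= 0.1), 0.02)
})

test_that("a single huge-amplitude trial cannot fake significance", {
  # An outlier whose signal segment carries 100x amplitude dominates the
  # observed maximum, but the ~50% of permutations that keep it in the
  # signal window raise the null maxima in the same way, and the observed
  # statistic is exchangeable with them. p is therefore ~uniform on
  # (0, 1/2]: P(p > 0.05) = E[(B1 - 4)/(B1 + 1)] with B1 ~ Bin(99, 1/2),
  # about 0.90 per simulation. Assert three binomial SDs below that, plus
  # the location of the bulk of the p distribution.
  set.seed(77)
  p <- vapply(seq_len(50), function(s) {
    nm <- null_magnitudes(n_trials = 16)
    s_idx <- which(nm$time_s >= 0)
    nm$mag[, , s_idx, 16] <- nm$mag[, , s_idx, 16] * 100  # outlier signal
    spec <- perm_spec(freqs_hz = 1:4, n_perm = 99, seed = 2000 + s)
    null <- permutation_null(nm$mag, spec, time_s = nm$time_s)
    m <- zscore_baseline(map_from_a(rowSums(nm$mag, dims = 3), nm$time_s,
                                    freqs_hz = 1:4))
    perm_pvalue(max_statistic(m)$statistic, null)
  }, 0)
  expect_gte(mean(p > 0.05), 0.9 - 3 * sqrt(0.9 * 0.1 / 50))
  expect_gt(median(p), 0.05)
  expect_lt(median(p), 0.6)
})
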