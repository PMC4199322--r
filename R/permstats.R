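# Maximum-statistic permutation test. Under the null, the pre-cue baseline
# second and the post-cue signal second are exchangeable: each permutation
# swaps the two segments in a random half of the trials, rebuilds the
# trial-summed amplitude and its baseline Z map, and records the maximum Z
# over the signal window, the frequency grid and all sources. Taking the
# maximum jointly over time x frequency x space controls the family-wise
# error with no further multiplicity correction, and makes the test robust
# to single outlier trials (an outlier inflates the null maxima together
# with the observed maximum). Swapping operates on source-domain
# coefficient magnitudes per frequency, which is equivalent to swapping the
# raw segments before averaging (the average is over |j|) and avoids
# re-running the wavelet transform and beamformer per permutation.

#' Permutation test specification
#'
#' @param baseline_s,signal_s half-open analysis windows in seconds
#'   (defaults `[-1, 0)` and `[0, 1)`); must be disjoint and of equal
#'   length.
#' @param freqs_hz frequency grid (default 70-100 Hz in 1 Hz steps).
#' @param n_perm permutation count (default 1000, >= 19).
#' @param seed integer seed; the null is exactly reproducible from it.
#' @param swap_fraction fraction of trials swapped per permutation
#'   (default 0.5, i.e. `floor(N/2)` trials without replacement).
#' @return an object of class `perm_spec`.
#' @export
perm_spec <- function(baseline_s = c(-1, 0), signal_s = c(0, 1),
                      freqs_hz = 70:100, n_perm = 1000, seed = 1,
                      swap_fraction = 0.5) {
  stop_if_not(abs(diff(baseline_s) - diff(signal_s)) < 1e-9,
              "baseline and signal windows must have equal length")
  stop_if_not(baseline_s[2] <= signal_s[1] || signal_s[2] <= baseline_s[1],
              "baseline and signal windows must be disjoint")
  stop_if_not(n_perm >= 19, "n_perm must be >= 19")
  stop_if_not(swap_fraction > 0 && swap_fraction <= 1,
              "swap_fraction must be in (0, 1]")
  structure(list(baseline_s = baseline_s, signal_s = signal_s,
                 freqs_hz = freqs_hz, n_perm = as.integer(n_perm),
                 seed = seed, swap_fraction = swap_fraction),
            class = "perm_spec")
}

#' Maximum Z statistic over the signal window
#'
#' Maximum of the Z map over signal-window times, all frequencies and all
#' sources, with ties broken by the lowest (vertex, frequency, time) index.
#'
#' @param m a Z-scored [source_tf_map()].
#' @param signal_s signal window (default the map's own).
#' @return list: `statistic`, `vertex`, `freq_hz`, `time_s`.
#' @export
max_statistic <- function(m, signal_s = NULL) {
  stop_if_not(inherits(m, "source_tf_map") && !is.null(m$z),
              "m must be a Z-scored source_tf_map (run zscore_baseline)")
  signal_s <- signal_s %||% m$signal_s
  sidx <- window_indices(m$time_s, signal_s)
  stop_if_not(length(sidx) >= 1, "signal window contains no samples")
  ok <- m$valid[, sidx, drop = FALSE]
  zs <- m$z[, , sidx, drop = FALSE]
  zs[is.na(zs)] <- -Inf
  for (k in seq_along(sidx)) zs[, !ok[, k], k] <- -Inf
  stop_if_not(any(is.finite(zs)), "no valid (source, freq, time) in the signal window")
  mx <- max(zs)
  w <- which(zs == mx, arr.ind = TRUE)
  w <- w[order(w[, 1], w[, 2], w[, 3]), , drop = FALSE][1, ]
  list(statistic = mx, vertex = unname(w[1]),
       freq_hz = m$freqs_hz[w[2]], time_s = m$time_s[sidx[w[3]]])
}

#' Swap baseline and signal segments in selected trials
#'
#' Exchanges the two time blocks of a source-magnitude array for the given
#' trials. An involution: applying the same swap twice restores the input,
#' and the multiset of per-trial segment values is conserved.
#'
#' @param mag numeric array sources x freqs x times x trials.
#' @param trials integer indices of trials to swap.
#' @param b_idx,s_idx time indices of the two segments (equal length).
#' @return the array with segments exchanged.
#' @export
swap_segments <- function(mag, trials, b_idx, s_idx) {
  stop_if_not(length(b_idx) == length(s_idx),
              "segments must have equal length")
  tmp <- mag[, , b_idx, trials, drop = FALSE]
  mag[, , b_idx, trials] <- mag[, , s_idx, trials, drop = FALSE]
  mag[, , s_idx, trials] <- tmp
  mag
}

# Shared kernel: columns of a_b/a_s are cases (permutations); rows are
# (source, freq) x window-time in (source, freq)-fastest order. Returns the
# max Z per case, where Z uses the baseline mean and (n-1) SD over window
# times. Column-major layout keeps every step allocation-light.
max_z_cols <- function(a_b, a_s, n_vf, n_t) {
  n_case <- ncol(a_b)
  blk <- function(l) (l - 1L) * n_vf + seq_len(n_vf)
  mu <- a_b[blk(1), , drop = FALSE]
  ss <- mu^2
  if (n_t > 1) for (l in 2:n_t) {
    x <- a_b[blk(l), , drop = FALSE]
    mu <- mu + x
    ss <- ss + x^2
  }
  mu <- mu / n_t
  sg <- sqrt(pmax(0, (ss - n_t * mu^2) / (n_t - 1)))
  smax <- a_s[blk(1), , drop = FALSE]
  if (n_t > 1) for (l in 2:n_t) smax <- pmax(smax, a_s[blk(l), , drop = FALSE])
  z <- (smax - mu) / sg
  z[sg <= 0] <- -Inf
  vapply(seq_len(n_case), function(k) max(z[, k]), 0)
}

# Fast path on window magnitudes: mb, ms are (V*F*L) x trials matrices,
# rows ordered (source, freq) fastest, window time slowest. Permutations
# are processed in chunks so peak memory stays near 2e7 doubles regardless
# of n_perm.
perm_null_windows <- function(mb, ms, n_vf, n_t, n_perm, seed,
                              swap_fraction = 0.5) {
  n <- ncol(mb)
  stop_if_not(n >= 4, "need at least 4 retained trials")
  n_swap <- max(1L, floor(n * swap_fraction))
  W <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      w <- numeric(n); w[sample.int(n, n_swap)] <- 1; w
    }, numeric(n))
  })                                    # trials x n_perm
  totb <- rowSums(mb)
  tots <- rowSums(ms)
  chunk <- max(1L, min(n_perm, as.integer(2e7 %/% nrow(mb))))
  out <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    idx <- (done + 1L):min(n_perm, done + chunk)
    Sb <- mb %*% W[, idx, drop = FALSE]
    Ss <- ms %*% W[, idx, drop = FALSE]
    a_b <- (Ss - Sb) + totb             # swapped-half baseline sums
    a_s <- (Sb - Ss) + tots
    out[idx] <- max_z_cols(a_b, a_s, n_vf, n_t)
    done <- idx[length(idx)]
  }
  out
}

# Extract (V*F*L) x trials window-magnitude matrices from a source-domain
# coefficient array.
window_magnitudes <- function(mag, time_s, valid, baseline_s, signal_s) {
  bidx <- window_indices(time_s, baseline_s)
  sidx <- window_indices(time_s, signal_s)
  stop_if_not(length(bidx) >= 2 && length(sidx) >= 1,
              "windows exceed the trial extent")
  stop_if_not(length(bidx) == length(sidx),
              "baseline and signal windows must contain equally many samples")
  if (!is.null(valid))
    stop_if_not(all(valid[, c(bidx, sidx)]),
                "analysis windows overlap the wavelet edge region")
  dd <- dim(mag)
  shape <- function(idx) {
    x <- mag[, , idx, , drop = FALSE]             # V x F x L x trials
    dim(x) <- c(dd[1] * dd[2] * length(idx), dd[4])
    x
  }
  list(mb = shape(bidx), ms = shape(sidx),
       n_vf = dd[1] * dd[2], n_t = length(bidx))
}

#' Null distribution of the maximum Z statistic
#'
#' For each permutation, a uniformly random `floor(N * swap_fraction)`-trial
#' subset (without replacement) has its baseline and signal segments
#' exchanged in source-magnitude space; the trial-summed amplitude, its
#' baseline Z map and the maximum statistic are then recomputed. Exactly
#' reproducible from `spec$seed`.
#'
#' @param j source-domain [tf_coefficients()], or a numeric magnitude array
#'   sources x freqs x times x trials (then `time_s` is required).
#' @param spec a [perm_spec()].
#' @param time_s time axis when `j` is a plain array.
#' @return numeric vector of `spec$n_perm` null maxima.
#' @export
permutation_null <- function(j, spec, time_s = NULL) {
  stop_if_not(inherits(spec, "perm_spec"), "spec must be a perm_spec")
  if (inherits(j, "tf_coefficients")) {
    stop_if_not(j$domain == "source", "j must be source-domain coefficients")
    mag <- Mod(j$coef); time_s <- j$time_s; valid <- j$valid
  } else {
    stop_if_not(is.array(j) && length(dim(j)) == 4 && !is.null(time_s),
                "j must be tf_coefficients or a 4-d magnitude array with time_s")
    mag <- j; valid <- NULL
  }
  w <- window_magnitudes(mag, time_s, valid, spec$baseline_s, spec$signal_s)
  perm_null_windows(w$mb, w$ms, w$n_vf, w$n_t, spec$n_perm, spec$seed,
                    spec$swap_fraction)
}

#' Permutation p-value (add-one rule)
#'
#' `p = (1 + #\{null >= observed\}) / (1 + B)`, so p = 0 is impossible and
#' ties count against rejection.
#'
#' @param observed observed maximum statistic.
#' @param null_max numeric vector of null maxima.
#' @return p-value in (0, 1].
#' @export
perm_pvalue <- function(observed, null_max) {
  stop_if_not(length(null_max) >= 1, "need at least one null value")
  (1 + sum(null_max >= observed)) / (1 + length(null_max))
}
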