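# Front door: fit the source-level high-gamma Z map for a trial set and a
# leadfield in one call, keeping the per-trial window magnitudes needed by
# the permutation test. Internals stream trial by trial so memory scales
# with sources x freqs x times, not trials.

#' Fit a source-level high-gamma Z map
#'
#' Runs the full mapping chain: broadband LCMV weights from the pooled
#' trial covariance, complex Morlet decomposition of each retained trial,
#' projection to source space, trial-summed amplitude, and baseline
#' Z-scoring. The analysis is restricted (plus wavelet edge margins) to the
#' baseline and signal windows unless `window = "full"`.
#'
#' @param trials a [trial_set()].
#' @param lf the matching [leadfield()].
#' @param freqs_hz frequency grid (default 70-100 Hz in 1 Hz steps).
#' @param n_cycles Morlet width in cycles (default 7 for the high-gamma
#'   band; 5 suits the 15-35 Hz beta band).
#' @param reg_lambda LCMV regularization, fraction of the mean covariance
#'   diagonal (default 0.05).
#' @param baseline_s,signal_s half-open analysis windows in seconds
#'   (defaults `[-1, 0)` and `[0, 1)`).
#' @param decim output decimation factor; `NULL` picks the largest divisor
#'   of `fs` keeping the amplitude-envelope rate at or above `min_rate_hz`.
#' @param min_rate_hz target envelope sampling rate for the default
#'   decimation (default 50 Hz; the Morlet amplitude envelope at
#'   `n_cycles = 7` is band-limited well below that).
#' @param window `"windows"` (default; analyze `[baseline_s[1], signal_s[2])`
#'   plus edge margins) or `"full"` (whole trial, memory permitting).
#' @param exclude_artifacts drop artifact-flagged trials (default TRUE).
#' @return an object of class `hg_fit`: the Z-scored [source_tf_map()] in
#'   `$map`, the [lcmv_transfer()] in `$transfer`, retained trial ids, and
#'   the per-trial baseline/signal window magnitudes used by
#'   [hg_perm_test()].
#' @seealso [hg_perm_test()], [summary.hg_fit()], [plot.hg_fit()]
#' @export
hg_fit <- function(trials, lf, freqs_hz = 70:100, n_cycles = 7,
                   reg_lambda = 0.05, baseline_s = c(-1, 0),
                   signal_s = c(0, 1), decim = NULL, min_rate_hz = 50,
                   window = c("windows", "full"),
                   exclude_artifacts = TRUE) {
  stop_if_not(inherits(trials, "trial_set"), "trials must be a trial_set")
  stop_if_not(inherits(lf, "leadfield"), "lf must be a leadfield")
  window <- match.arg(window)
  fs <- trials$fs
  decim <- as.integer(decim %||% largest_divisor_rate(fs, min_rate_hz))
  stop_if_not(round(fs) %% decim == 0, "decim must divide fs")
  retain <- if (exclude_artifacts) which(!trials$artifact_flags) else
    seq_len(dim(trials$data)[1])
  stop_if_not(length(retain) >= 1, "all trials flagged: nothing to fit")

  C <- broadband_covariance(trials, exclude_flagged = exclude_artifacts)
  Tr <- lcmv_transfer(lf, C, reg_lambda)

  kernels <- morlet_kernels(freqs_hz, fs, n_cycles)
  hmax <- max(vapply(kernels, function(k) k$h, 0L))
  time_full <- trials$time_s
  if (window == "windows") {
    margin <- hmax / fs + decim / fs
    lo <- max(time_full[1], min(baseline_s[1], signal_s[1]) - margin)
    hi <- min(time_full[length(time_full)],
              max(baseline_s[2], signal_s[2]) + margin)
    cidx <- which(time_full >= lo - 1e-9 & time_full <= hi + 1e-9)
  } else {
    cidx <- seq_along(time_full)
  }
  ns_c <- length(cidx)
  # keep the decimated grid phase-aligned with the full trial's sample grid
  # so windowed and full fits sample the envelope at identical times
  phase <- (decim - (cidx[1] - 1L) %% decim) %% decim
  tout_local <- seq(1L + phase, ns_c, by = decim)
  time_out <- time_full[cidx[tout_local]]
  valid <- matrix(TRUE, length(freqs_hz), length(tout_local))
  for (k in seq_along(kernels)) {
    valid[k, ] <- tout_local > kernels[[k]]$h &
      tout_local <= ns_c - kernels[[k]]$h
  }

  nV <- nrow(Tr$T); nF <- length(freqs_hz); nT <- length(tout_local)
  bidx <- window_indices(time_out, baseline_s)
  sidx <- window_indices(time_out, signal_s)
  stop_if_not(length(bidx) >= 2 && length(sidx) >= 1,
              "analysis windows lie outside the trial")
  stop_if_not(all(valid[, c(bidx, sidx)]),
              "analysis windows overlap the wavelet edge region; enlarge the trial or reduce n_cycles")
  if (length(bidx) != length(sidx)) {
    n <- min(length(bidx), length(sidx))
    bidx <- bidx[seq_len(n)]; sidx <- sidx[seq_len(n)]
  }

  asum <- array(0, c(nV, nF, nT))
  psum <- array(0, c(nV, nF, nT))
  nwin <- length(bidx)
  mb <- matrix(0, nV * nF * nwin, length(retain))
  ms <- matrix(0, nV * nF * nwin, length(retain))
  for (k in seq_along(retain)) {
    X <- matrix(trials$data[retain[k], , cidx], nrow = dim(trials$data)[2])
    d <- morlet_apply(X, kernels, fs, tout = tout_local)   # ch x F x T
    j <- Tr$T %*% matrix(d, nrow = dim(d)[1])
    m <- Mod(j)
    dim(m) <- c(nV, nF, nT)
    asum <- asum + m
    psum <- psum + m^2
    mb[, k] <- m[, , bidx]
    ms[, k] <- m[, , sidx]
  }

  map <- source_tf_map(asum, psum, length(retain), freqs_hz, time_out,
                       valid, baseline_s, signal_s)
  map <- zscore_baseline(map)
  structure(list(map = map, transfer = Tr, covariance = C,
                 retained = retain, n_channels = dim(trials$data)[2],
                 freqs_hz = freqs_hz, time_s = time_out,
                 baseline_s = baseline_s, signal_s = signal_s,
                 windows = list(mb = mb, ms = ms, n_vf = nV * nF,
                                n_t = nwin),
                 decim = decim, n_cycles = n_cycles, fs = fs,
                 call = match.call()),
            class = "hg_fit")
}

#' @export
print.hg_fit <- function(x, ...) {
  d <- dim(x$map$a)
  pk <- max_statistic(x$map)
  cat("Source-level high-gamma map (LCMV beamformer + Morlet amplitudes)\n")
  cat(sprintf("  %d sources x %d freqs (%g-%g Hz) x %d times, %d trials retained\n",
              d[1], d[2], min(x$freqs_hz), max(x$freqs_hz), d[3],
              x$map$n_trials))
  cat(sprintf("  peak Z = %.2f at vertex %d, %g Hz, %.3f s (signal window [%g, %g) s)\n",
              pk$statistic, pk$vertex, pk$freq_hz, pk$time_s,
              x$signal_s[1], x$signal_s[2]))
  invisible(x)
}

#' Per-vertex peak table of a fitted high-gamma map
#'
#' For every source vertex, the maximum Z over the signal window and the
#' frequency grid, with its time and frequency.
#'
#' @param object an [hg_fit()].
#' @param ... unused.
#' @return data.frame: vertex, peak_z, peak_freq_hz, peak_time_s, ordered
#'   by decreasing peak_z.
#' @export
summary.hg_fit <- function(object, ...) {
  m <- object$map
  sidx <- window_indices(m$time_s, object$signal_s)
  zs <- m$z[, , sidx, drop = FALSE]
  zs[is.na(zs)] <- -Inf
  nV <- dim(zs)[1]
  out <- data.frame(vertex = seq_len(nV), peak_z = NA_real_,
                    peak_freq_hz = NA_real_, peak_time_s = NA_real_)
  for (v in seq_len(nV)) {
    zv <- zs[v, , , drop = FALSE]
    w <- which(zv == max(zv), arr.ind = TRUE)[1, ]
    out$peak_z[v] <- max(zv)
    out$peak_freq_hz[v] <- m$freqs_hz[w[2]]
    out$peak_time_s[v] <- m$time_s[sidx[w[3]]]
  }
  out[order(-out$peak_z), ]
}

#' @export
coef.hg_fit <- function(object, ...) {
  s <- summary(object)
  stats::setNames(s$peak_z[order(s$vertex)], paste0("v", sort(s$vertex)))
}

#' Plot the time-frequency Z map at a vertex
#'
#' Image of Z over time and frequency (default: the peak vertex), with the
#' cue and the signal window marked.
#'
#' @param x an [hg_fit()].
#' @param vertex vertex id (default: the argmax vertex).
#' @param ... passed to [graphics::image()].
#' @export
plot.hg_fit <- function(x, vertex = NULL, ...) {
  vertex <- vertex %||% max_statistic(x$map)$vertex
  z <- t(x$map$z[vertex, , ])
  graphics::image(x$map$time_s, x$freqs_hz, z,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "time relative to cue (s)", ylab = "frequency (Hz)",
                  main = sprintf("Z map, vertex %d", vertex), ...)
  graphics::abline(v = 0, lty = 2)
  graphics::abline(v = x$signal_s, lty = 3)
  invisible(x)
}

#' Peak frequency from the relative amplitude-change spectrum
#'
#' The event-related synchronization spectrum at a vertex: mean
#' signal-window amplitude divided by mean baseline amplitude, per
#' frequency. Its argmax estimates the burst's spectral peak. Unlike the
#' frequency of the maximum Z (which inherits the sampling noise of the
#' per-frequency baseline SD, a session-level error that does not average
#' out with trials), this ratio only involves baseline means and converges
#' on the true center as trials accumulate.
#'
#' @param fit an [hg_fit()].
#' @param vertex vertex id (default: the maximum-Z vertex).
#' @return the peak frequency in Hz; the full ratio spectrum is attached
#'   as attribute `"spectrum"` (named by frequency).
#' @export
peak_frequency <- function(fit, vertex = NULL) {
  stop_if_not(inherits(fit, "hg_fit"), "fit must be an hg_fit")
  vertex <- vertex %||% max_statistic(fit$map)$vertex
  m <- fit$map
  sidx <- window_indices(m$time_s, fit$signal_s)
  bidx <- window_indices(m$time_s, fit$baseline_s)
  ratio <- rowMeans(m$a[vertex, , sidx, drop = TRUE]) /
    rowMeans(m$a[vertex, , bidx, drop = TRUE])
  structure(m$freqs_hz[which.max(ratio)],
            spectrum = stats::setNames(ratio, m$freqs_hz))
}

#' Maximum-statistic permutation test of a fitted map
#'
#' Observed statistic: the maximum Z over the signal window, frequencies
#' and sources. Null: [permutation_null()] on the fit's stored per-trial
#' window magnitudes. Add-one p-value.
#'
#' @param fit an [hg_fit()].
#' @param n_perm permutation count (default 1000).
#' @param seed integer seed.
#' @param swap_fraction fraction of trials swapped (default 0.5).
#' @return object of class `hg_permtest`: `statistic`, `argmax`,
#'   `p.value`, `null_max`, `n_perm`, `seed`.
#' @export
hg_perm_test <- function(fit, n_perm = 1000, seed = 1, swap_fraction = 0.5) {
  stop_if_not(inherits(fit, "hg_fit"), "fit must be an hg_fit")
  obs <- max_statistic(fit$map)
  null_max <- perm_null_windows(fit$windows$mb, fit$windows$ms,
                                fit$windows$n_vf, fit$windows$n_t,
                                n_perm, seed, swap_fraction)
  structure(list(statistic = obs$statistic,
                 argmax = obs[c("vertex", "freq_hz", "time_s")],
                 p.value = perm_pvalue(obs$statistic, null_max),
                 null_max = null_max, n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 method = "maximum-statistic permutation test (baseline/signal segment swap)"),
            class = "hg_permtest")
}

#' @export
print.hg_permtest <- function(x, ...) {
  cat("\n\t", x$method, "\n\n")
  cat(sprintf("max Z = %.3f at vertex %d, %g Hz, %.3f s\n",
              x$statistic, x$argmax$vertex, x$argmax$freq_hz,
              x$argmax$time_s))
  cat(sprintf("p-value = %.4g (%d permutations, seed %d, add-one rule)\n",
              x$p.value, x$n_perm, x$seed))
  invisible(x)
}

#' Per-vertex p-values against the global null
#'
#' Each vertex's own maximum Z over the signal window and frequencies is
#' compared against the global maximum-statistic null histogram (one
#' interpretation of per-vertex significance under the joint test; it is
#' conservative for non-peak vertices). Vertices at `p <= 0.1` form the
#' EEG cluster input for the proximity analysis.
#'
#' @param fit an [hg_fit()].
#' @param test an [hg_perm_test()] result for the same fit.
#' @return numeric per-vertex p-value vector.
#' @export
vertex_pvalues <- function(fit, test) {
  s <- summary(fit)
  s <- s[order(s$vertex), ]
  vapply(s$peak_z, function(z) perm_pvalue(z, test$null_max), 0)
}
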