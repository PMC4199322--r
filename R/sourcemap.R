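# LCMV beamformer: broadband covariance -> per-source channel weights under
# a unit-gain constraint -> source-domain wavelet coefficients -> trial-
# summed amplitude maps Z-scored against the pre-cue baseline. A scalar
# beamformer (one weight row per source, dipole orientation fixed along the
# vertex normal in the forward model) is used throughout.

#' Broadband channel covariance pooled over trials
#'
#' Per-trial channel means are removed, then cross-products are pooled over
#' all retained trials and the full trial window. Result is symmetric PSD
#' and invariant to trial order.
#'
#' @param ts a [trial_set()].
#' @param exclude_flagged drop artifact-flagged trials (default TRUE).
#' @return channels x channels covariance matrix.
#' @export
broadband_covariance <- function(ts, exclude_flagged = TRUE) {
  stop_if_not(inherits(ts, "trial_set"), "ts must be a trial_set")
  keep <- if (exclude_flagged) which(!ts$artifact_flags) else
    seq_len(dim(ts$data)[1])
  stop_if_not(length(keep) >= 1, "no retained trials")
  nch <- dim(ts$data)[2]; ns <- dim(ts$data)[3]
  total <- length(keep) * ns
  if (total < nch)
    warning("fewer samples than channels: covariance is rank deficient, regularization is mandatory")
  else if (total < 10 * nch)
    warning("fewer than 10 samples per channel: covariance estimate is unstable")
  C <- matrix(0, nch, nch)
  for (i in keep) {
    X <- matrix(ts$data[i, , ], nrow = nch)
    X <- X - rowMeans(X)
    C <- C + tcrossprod(X)
  }
  C / max(1, total - length(keep))
}

#' LCMV transfer matrix (sources x channels)
#'
#' Per source v with leadfield column l_v, the weight row is
#' `w_v = (C_r^-1 l_v) / (l_v' C_r^-1 l_v)` with
#' `C_r = C + reg_lambda * mean(diag(C)) * I`, so that `w_v' l_v = 1`
#' (unit gain) and output variance is minimized.
#'
#' @param lf a [leadfield()].
#' @param C channel covariance (PSD).
#' @param reg_lambda regularization as a fraction of the mean diagonal
#'   (default 0.05).
#' @return an object of class `lcmv_transfer` with elements `T`
#'   (sources x channels), `reg_lambda`, `source_vertex_ids`.
#' @export
lcmv_transfer <- function(lf, C, reg_lambda = 0.05) {
  stop_if_not(inherits(lf, "leadfield"), "lf must be a leadfield")
  stop_if_not(reg_lambda >= 0, "reg_lambda must be >= 0")
  nch <- nrow(lf$gain)
  stop_if_not(nrow(C) == nch && ncol(C) == nch,
              "covariance does not match the leadfield channel count")
  Cr <- C + reg_lambda * mean(diag(C)) * diag(nch)
  W <- tryCatch(solve(Cr, lf$gain),
                error = function(e) stop("covariance is numerically singular; increase reg_lambda",
                                         call. = FALSE))
  denom <- colSums(lf$gain * W)
  stop_if_not(all(denom > 0),
              "l' C^-1 l <= 0 for some source: numerically broken covariance")
  Tm <- t(sweep(W, 2, denom, "/"))
  structure(list(T = Tm, reg_lambda = reg_lambda,
                 source_vertex_ids = lf$source_vertex_ids),
            class = "lcmv_transfer")
}

#' @export
print.lcmv_transfer <- function(x, ...) {
  cat(sprintf("LCMV transfer matrix: %d sources x %d channels (reg_lambda = %g)\n",
              nrow(x$T), ncol(x$T), x$reg_lambda))
  invisible(x)
}

#' Map channel-domain wavelet coefficients to source space
#'
#' Applies `j = T d` per trial, frequency and time point. Linear, and
#' commutes with the wavelet transform.
#'
#' @param Tm an [lcmv_transfer()] (or a plain sources x channels matrix).
#' @param d channel-domain [tf_coefficients()].
#' @return source-domain [tf_coefficients()].
#' @export
map_coefficients <- function(Tm, d) {
  stop_if_not(inherits(d, "tf_coefficients") && d$domain == "channel",
              "d must be channel-domain tf_coefficients")
  M <- if (inherits(Tm, "lcmv_transfer")) Tm$T else as.matrix(Tm)
  dd <- dim(d$coef)
  stop_if_not(ncol(M) == dd[1],
              "transfer matrix channel count (%d) does not match coefficients (%d)",
              ncol(M), dd[1])
  j <- M %*% matrix(d$coef, nrow = dd[1])
  dim(j) <- c(nrow(M), dd[2], dd[3], dd[4])
  tf_coefficients(j, d$freqs_hz, d$time_s, "source", d$valid, d$fs_out)
}

#' Source-space time-frequency map
#'
#' Holds the trial-summed amplitude `a(v, f, t) = sum_i |j_i(v, f, t)|`
#' (and its power twin `p` with squared moduli), the retained trial count,
#' and once [zscore_baseline()] has run, the baseline Z map.
#'
#' @param a,p numeric arrays, sources x freqs x times.
#' @param n_trials retained trial count N.
#' @param freqs_hz,time_s axes.
#' @param valid logical freq x time edge-validity mask.
#' @param baseline_s,signal_s analysis windows in seconds (half-open).
#' @return an object of class `source_tf_map`.
#' @export
source_tf_map <- function(a, p, n_trials, freqs_hz, time_s, valid,
                          baseline_s = c(-1, 0), signal_s = c(0, 1)) {
  stop_if_not(all(a >= 0), "amplitudes must be non-negative")
  structure(list(a = a, p = p, n_trials = n_trials, freqs_hz = freqs_hz,
                 time_s = time_s, valid = valid, z = NULL,
                 invalid_loc = NULL, baseline_s = baseline_s,
                 signal_s = signal_s),
            class = "source_tf_map")
}

#' @export
print.source_tf_map <- function(x, ...) {
  d <- dim(x$a)
  cat(sprintf("Source TF map: %d sources x %d freqs x %d times, N = %d trials%s\n",
              d[1], d[2], d[3], x$n_trials,
              if (is.null(x$z)) "" else " (Z-scored)"))
  invisible(x)
}

#' Trial-summed amplitude (and power) source map
#'
#' `a = sum_i |j_i|` and `p = sum_i |j_i|^2` over retained trials, exactly
#' as printed: no 1/N, since baseline Z-scoring cancels the scale.
#' Amplitudes are used downstream to reduce sensitivity to outliers.
#'
#' @param j source-domain [tf_coefficients()].
#' @param retain integer trial indices to keep (default: all).
#' @param baseline_s,signal_s windows stored for downstream stages.
#' @return a [source_tf_map()].
#' @export
average_amplitude <- function(j, retain = NULL,
                              baseline_s = c(-1, 0), signal_s = c(0, 1)) {
  stop_if_not(inherits(j, "tf_coefficients") && j$domain == "source",
              "j must be source-domain tf_coefficients")
  dd <- dim(j$coef)
  retain <- retain %||% seq_len(dd[4])
  stop_if_not(length(retain) >= 1, "all trials flagged: no retained trials")
  m <- Mod(j$coef[, , , retain, drop = FALSE])
  a <- rowSums(m, dims = 3)
  p <- rowSums(m^2, dims = 3)
  source_tf_map(a, p, length(retain), j$freqs_hz, j$time_s, j$valid,
                baseline_s, signal_s)
}

#' Baseline Z-scoring of a source amplitude map
#'
#' `z(v, f, t) = (a(v, f, t) - mu_b(v, f)) / sigma_b(v, f)` where mu/sigma
#' are the mean and (n-1) standard deviation of `a` over the baseline
#' times. Invariant to rescaling `a` by any positive constant. Locations
#' with zero baseline SD are marked invalid in `invalid_loc` and reported.
#'
#' @param m a [source_tf_map()].
#' @param baseline_s baseline window (default the map's own, `[-1, 0)`).
#' @return the map with `z` (and `invalid_loc`) filled in.
#' @export
zscore_baseline <- function(m, baseline_s = NULL) {
  stop_if_not(inherits(m, "source_tf_map"), "m must be a source_tf_map")
  baseline_s <- baseline_s %||% m$baseline_s
  bidx <- window_indices(m$time_s, baseline_s)
  stop_if_not(length(bidx) >= 2, "baseline window contains fewer than 2 samples")
  stop_if_not(all(m$valid[, bidx]),
              "baseline window overlaps the wavelet edge region")
  ab <- m$a[, , bidx, drop = FALSE]
  mu <- rowMeans(ab, dims = 2)
  nb <- length(bidx)
  sg <- sqrt(pmax(0, (rowSums(ab^2, dims = 2) - nb * mu^2) / (nb - 1)))
  bad <- sg <= 0
  sg[bad] <- NA_real_
  m$z <- sweep(sweep(m$a, c(1, 2), mu, "-"), c(1, 2), sg, "/")
  m$invalid_loc <- bad
  m$baseline_s <- baseline_s
  if (any(bad))
    message(sprintf("zscore_baseline: %d (source, freq) location(s) have zero baseline SD and were marked invalid",
                    sum(bad)))
  m
}
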