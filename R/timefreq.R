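# Complex Morlet wavelet decomposition. Kernels are Gaussian-windowed
# complex exponentials with sigma_t = n_cycles / (2 pi f), truncated at
# +/- 4 sigma_t and amplitude-normalized so that a unit-amplitude tone at
# the analyzing frequency yields |coef| ~ 1. Convolution is done in the
# frequency domain; edge samples inside one kernel half-width are carried
# in a validity mask, never silently zeroed.

#' Time-frequency coefficients
#'
#' Container for complex Morlet coefficients in channel or source space.
#' Coefficients are stored as a 4-d array `loc x freq x time x trial`
#' (locations are channels or source vertices).
#'
#' @param coef complex array loc x freq x time x trial.
#' @param freqs_hz strictly increasing frequency grid.
#' @param time_s output time axis (decimated if `decim > 1`).
#' @param domain `"channel"` or `"source"`.
#' @param valid logical freq x time matrix: FALSE inside the wavelet edge
#'   region.
#' @param fs_out output sampling rate.
#' @return an object of class `tf_coefficients`.
#' @export
tf_coefficients <- function(coef, freqs_hz, time_s, domain, valid, fs_out) {
  stop_if_not(length(dim(coef)) == 4, "coef must be loc x freq x time x trial")
  stop_if_not(all(diff(freqs_hz) > 0), "frequency grid must be strictly increasing")
  stop_if_not(dim(coef)[2] == length(freqs_hz) && dim(coef)[3] == length(time_s),
              "coef dimensions must match freq/time axes")
  stop_if_not(all(is.finite(Mod(coef))), "coefficients must be finite")
  structure(list(coef = coef, freqs_hz = freqs_hz, time_s = time_s,
                 domain = match.arg(domain, c("channel", "source")),
                 valid = valid, fs_out = fs_out),
            class = "tf_coefficients")
}

#' @export
print.tf_coefficients <- function(x, ...) {
  d <- dim(x$coef)
  cat(sprintf("TF coefficients [%s]: %d locations x %d freqs x %d times x %d trials @ %g Hz\n",
              x$domain, d[1], d[2], d[3], d[4], x$fs_out))
  invisible(x)
}

# Complex Morlet kernels for a frequency grid. Returns per-frequency
# complex vectors (odd length 2h+1) plus half-widths h in samples.
morlet_kernels <- function(freqs_hz, fs, n_cycles) {
  if (length(n_cycles) == 1) n_cycles <- rep(n_cycles, length(freqs_hz))
  stop_if_not(length(n_cycles) == length(freqs_hz),
              "n_cycles must be scalar or one per frequency")
  lapply(seq_along(freqs_hz), function(k) {
    f <- freqs_hz[k]
    sigma <- n_cycles[k] / (2 * pi * f)
    h <- max(3L, as.integer(ceiling(4 * sigma * fs)))
    t <- (-h:h) / fs
    g <- exp(-t^2 / (2 * sigma^2))
    w <- (2 / sum(g)) * g * exp(2i * pi * f * t)
    list(w = w, h = h)
  })
}

# Apply kernels to a channels x samples matrix via FFT cross-correlation;
# returns complex array channels x freqs x times at the requested output
# sample indices (default: every decim-th sample from the first).
morlet_apply <- function(X, kernels, fs, decim = 1L, tout = NULL) {
  nch <- nrow(X); ns <- ncol(X)
  hmax <- max(vapply(kernels, function(k) k$h, 0L))
  nfft <- stats::nextn(ns + 2L * hmax + 1L, 2)
  Xp <- matrix(0, nfft, nch)
  Xp[seq_len(ns), ] <- t(X)
  FX <- stats::mvfft(Xp)
  tout <- tout %||% seq(1L, ns, by = decim)
  out <- array(0i, c(nch, length(kernels), length(tout)))
  for (k in seq_along(kernels)) {
    ker <- kernels[[k]]
    wpad <- complex(length.out = nfft)
    # center kernel at lag zero: taps for lags -h..h wrap around the end
    wpad[seq_len(ker$h + 1L)] <- ker$w[(ker$h + 1L):(2L * ker$h + 1L)]
    wpad[(nfft - ker$h + 1L):nfft] <- ker$w[seq_len(ker$h)]
    FW <- stats::fft(wpad)
    C <- stats::mvfft(FX * Conj(FW), inverse = TRUE) / nfft
    out[, k, ] <- t(C[tout, , drop = FALSE])
  }
  out
}

#' Complex Morlet wavelet transform of a trial set
#'
#' Linear in the input; delaying the input delays the coefficients. Edge
#' samples closer than one kernel half-width to either trial end are
#' flagged invalid in the `valid` mask.
#'
#' @param ts a [trial_set()].
#' @param freqs_hz frequency grid in Hz (default 70-100 in 1 Hz steps; all
#'   below Nyquist).
#' @param n_cycles kernel width in cycles, scalar or per frequency
#'   (default 7; must be >= 3).
#' @param decim integer decimation factor for the output time axis
#'   (default 1: no decimation; must divide `round(fs)`).
#' @return a [tf_coefficients()] in the channel domain.
#' @export
morlet_transform <- function(ts, freqs_hz = 70:100, n_cycles = 7, decim = 1L) {
  stop_if_not(inherits(ts, "trial_set"), "ts must be a trial_set")
  stop_if_not(max(freqs_hz) < ts$fs / 2,
              "frequencies must be below Nyquist (fs/2)")
  stop_if_not(all(n_cycles >= 3), "n_cycles must be >= 3")
  decim <- as.integer(decim)
  stop_if_not(decim >= 1L && round(ts$fs) %% decim == 0L,
              "decim must be a positive integer dividing fs")
  d <- dim(ts$data)
  kernels <- morlet_kernels(freqs_hz, ts$fs, n_cycles)
  tout <- seq(1L, d[3], by = decim)
  coef <- array(0i, c(d[2], length(freqs_hz), length(tout), d[1]))
  for (i in seq_len(d[1])) {
    coef[, , , i] <- morlet_apply(
      matrix(ts$data[i, , ], nrow = d[2]), kernels, ts$fs, decim)
  }
  valid <- matrix(TRUE, length(freqs_hz), length(tout))
  for (k in seq_along(kernels)) {
    valid[k, ] <- tout > kernels[[k]]$h & tout <= d[3] - kernels[[k]]$h
  }
  tf_coefficients(coef, freqs_hz, ts$time_s[tout], "channel", valid,
                  ts$fs / decim)
}
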