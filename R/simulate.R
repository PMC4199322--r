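# Synthetic cue-locked motor-imagery sessions with known ground truth.
# The generator emulates the study protocol: 54-channel EEG sampled at
# 1200 Hz, 100 trials per hand segmented to [-2, 3) s around the cue,
# a narrowband high-gamma burst (center drawn in 70-96 Hz) at the
# contralateral source between 0.3 and 1.0 s post-cue, beta-band
# desynchronization after the cue, spatially mixed 1/f background noise,
# occasional broadband (20-300 Hz) muscle artifacts, bipolar EMG/EOG
# channels, and matched synthetic fMRI vertex Z maps.

#' Simulation configuration
#'
#' Defaults mirror the study protocol. `hg_snr` is the amplitude ratio of
#' the projected high-gamma burst to the background noise within the
#' 70-100 Hz band at the channels (the study does not quantify scalp-level
#' high-gamma SNR; this is a free simulation parameter).
#'
#' @param n_trials_per_hand trials per hand (default 100).
#' @param n_channels EEG channel count (default 54).
#' @param fs sampling rate in Hz (default 1200).
#' @param trial_window seconds relative to cue, half-open (default
#'   `c(-2, 3)`; must span exactly 5 s).
#' @param hg_center high-gamma burst center(s) in Hz; `NULL` (default)
#'   draws one integer per source uniformly in 70-96. Must lie in
#'   `[70, 100]`.
#' @param hg_bandwidth burst bandwidth in Hz (default 6).
#' @param burst_window seconds, burst support (default `c(0.3, 1.0)`,
#'   must lie within `[0, 3)`).
#' @param hg_snr in-band amplitude ratio (default 1; 0 disables the burst).
#' @param beta_erd_depth fractional attenuation of the 15-35 Hz rhythm
#'   after the cue (default 0.3).
#' @param noise_exponent 1/f^alpha noise slope (default 1).
#' @param artifact_rate fraction of trials receiving a broadband artifact
#'   burst (default 0.05; must be in `[0, 1)`).
#' @param emg_task_snr amplitude of task-locked EMG/EOG contamination
#'   relative to the EMG noise floor (default 0: none).
#' @param seed master seed; per-trial substreams are derived from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_trials_per_hand = 100, n_channels = 54, fs = 1200,
                       trial_window = c(-2, 3), hg_center = NULL,
                       hg_bandwidth = 6, burst_window = c(0.3, 1.0),
                       hg_snr = 1, beta_erd_depth = 0.3,
                       noise_exponent = 1, artifact_rate = 0.05,
                       emg_task_snr = 0, seed = 1) {
  stop_if_not(abs(diff(trial_window) - 5) < 1e-9,
              "trial_window must span exactly 5 s")
  stop_if_not(burst_window[1] >= 0 && burst_window[2] < 3 &&
                burst_window[2] > burst_window[1],
              "burst_window must lie within [0, 3)")
  stop_if_not(artifact_rate >= 0 && artifact_rate < 1,
              "artifact_rate must be in [0, 1)")
  if (!is.null(hg_center))
    stop_if_not(all(hg_center >= 70 & hg_center <= 100),
                "hg_center must lie in [70, 100]")
  stop_if_not(hg_snr >= 0, "hg_snr must be >= 0")
  stop_if_not(n_trials_per_hand >= 1 && n_channels >= 1 && fs > 0,
              "invalid counts")
  structure(list(n_trials_per_hand = n_trials_per_hand,
                 n_channels = n_channels, fs = fs,
                 trial_window = trial_window, hg_center = hg_center,
                 hg_bandwidth = hg_bandwidth, burst_window = burst_window,
                 hg_snr = hg_snr, beta_erd_depth = beta_erd_depth,
                 noise_exponent = noise_exponent,
                 artifact_rate = artifact_rate,
                 emg_task_snr = emg_task_snr, seed = seed),
            class = "sim_config")
}

# 1/f^alpha noise, one column per channel, generated in the frequency
# domain (amplitude ~ f^(-alpha/2), random phases).
one_over_f_noise <- function(n_samples, n_series, fs, alpha) {
  nf <- floor(n_samples / 2)
  f <- seq_len(nf) * fs / n_samples
  amp <- f^(-alpha / 2)
  ph <- matrix(stats::runif(nf * n_series, 0, 2 * pi), nf, n_series)
  spec <- matrix(0 + 0i, n_samples, n_series)
  spec[2:(nf + 1), ] <- amp * exp(1i * ph)
  if (n_samples %% 2 == 0) {
    spec[nf + 1, ] <- Re(spec[nf + 1, ])
    src <- 2:nf
  } else {
    src <- 2:(nf + 1)
  }
  spec[n_samples + 2 - src, ] <- Conj(spec[src, , drop = FALSE])
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n_samples
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

# Narrowband noise by band-pass filtering white noise (order-2 zero-phase
# Butterworth), unit RMS.
narrowband_noise <- function(n_samples, fs, band) {
  x <- stats::rnorm(n_samples)
  y <- bandpass_filter(x, fs, band, order = 2)
  y / rms(y)
}

#' Simulate a cue-locked motor-imagery EEG session
#'
#' Each trial is leadfield-projected source activity (a Hann-windowed
#' narrowband high-gamma burst at the hand's contralateral source during
#' the burst window, plus a beta rhythm attenuated by `beta_erd_depth`
#' after the cue) added to spatially mixed 1/f channel noise. Artifact
#' trials receive a large broadband burst on a random channel subset.
#' EMG/EOG channels carry noise, plus task-locked high-gamma contamination
#' only when `emg_task_snr > 0`. Pure function of `(cfg, mesh, lf)`:
#' identical seeds give identical sessions.
#'
#' @param cfg a [sim_config()].
#' @param mesh the source-space [triangle_mesh()].
#' @param lf the matching [leadfield()].
#' @return list with elements `trials` (a [trial_set()]), `emg`
#'   (trials x 2 x samples), `eog` (trials x 2 x samples) and `truth`
#'   (list: `source_vertex_ids` named by hand, `source_centers_hz`,
#'   `burst_onset`, `burst_offset`, `artifact_trial_ids`).
#' @export
simulate_session <- function(cfg, mesh, lf) {
  stop_if_not(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  nch <- nrow(lf$gain)
  stop_if_not(nch == cfg$n_channels,
              "leadfield channel count (%d) does not match cfg (%d)",
              nch, cfg$n_channels)
  stop_if_not(ncol(lf$gain) == mesh$n, "leadfield does not match mesh")
  fs <- cfg$fs
  ns <- as.integer(round(5 * fs))
  time_s <- cfg$trial_window[1] + (seq_len(ns) - 1) / fs
  ntr <- 2L * cfg$n_trials_per_hand

  # session-level draws
  sess <- with_seed(cfg$seed, {
    labels <- sample(rep(c("left", "right"), cfg$n_trials_per_hand))
    centers <- cfg$hg_center %||% sample(70:96, 2, replace = TRUE)
    if (length(centers) == 1) centers <- rep(centers, 2)
    n_art <- round(cfg$artifact_rate * ntr)
    art_ids <- if (n_art > 0) sort(sample.int(ntr, n_art)) else integer(0)
    list(labels = labels, centers = centers, art_ids = art_ids)
  })
  stop_if_not(max(sess$centers) + cfg$hg_bandwidth / 2 <= fs / 2,
              "hg_center + bandwidth/2 exceeds Nyquist (fs/2)")

  # contralateral sources: left-hand imagery activates the right-hemisphere
  # vertex and vice versa (x > 0 is the right hemisphere here)
  vright <- which.max(mesh$vertices %*% c(1, 0, 0.3))
  vleft <- which.max(mesh$vertices %*% c(-1, 0, 0.3))
  src_of_hand <- c(left = vright, right = vleft)
  centers_of_hand <- c(left = sess$centers[1], right = sess$centers[2])

  # spatially smooth noise mixing from sensor geometry (fallback: seeded
  # random orthogonal-ish mixing when positions are unknown)
  if (!is.null(lf$channel_positions)) {
    d2 <- as.matrix(stats::dist(lf$channel_positions))^2
    K <- exp(-d2 / (2 * 40^2))
    K <- K / sqrt(rowSums(K^2))
    M <- 0.7 * K + 0.3 * diag(nch)
  } else {
    M <- with_seed(cfg$seed + 1L, {
      A <- matrix(stats::rnorm(nch * nch), nch)
      0.7 * qr.Q(qr(A)) + 0.3 * diag(nch)
    })
  }

  burst_idx <- window_indices(time_s, cfg$burst_window)
  post_idx <- which(time_s >= 0)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(burst_idx)))
  erd_env <- rep(1, ns)
  ramp <- which(time_s >= 0 & time_s < 0.2)
  erd_env[post_idx] <- 1 - cfg$beta_erd_depth
  erd_env[ramp] <- 1 - cfg$beta_erd_depth *
    (0.5 - 0.5 * cos(pi * seq_along(ramp) / length(ramp)))

  data <- array(0, c(ntr, nch, ns))
  emg <- array(0, c(ntr, 2, ns))
  eog <- array(0, c(ntr, 2, ns))
  hg_noise_rms <- beta_noise_rms <- emg_noise_rms <- NULL

  for (i in seq_len(ntr)) {
    set.seed(substream_seed(cfg$seed, i))
    Xn <- t(M %*% t(one_over_f_noise(ns, nch, fs, cfg$noise_exponent)))
    if (i == 1L) {
      hg_noise_rms <- mean(apply(bandpass_filter(Xn, fs, c(70, 100)), 2, rms))
      beta_noise_rms <- mean(apply(bandpass_filter(Xn, fs, c(15, 35)), 2, rms))
    }
    X <- t(Xn)                                   # channels x samples
    hand <- sess$labels[i]
    v <- src_of_hand[[hand]]
    g <- lf$gain[, v]
    gn <- sqrt(mean(g^2))

    # beta rhythm with post-cue desynchronization at the active source
    xb <- narrowband_noise(ns, fs, c(15, 35)) * erd_env
    beta_scale <- 1.5 * beta_noise_rms / gn
    X <- X + g %o% (beta_scale * xb)

    # high-gamma burst
    if (cfg$hg_snr > 0) {
      f0 <- centers_of_hand[[hand]]
      bb <- c(f0 - cfg$hg_bandwidth / 2, f0 + cfg$hg_bandwidth / 2)
      s <- numeric(ns)
      s[burst_idx] <- hann * narrowband_noise(ns, fs, bb)[burst_idx]
      sc <- cfg$hg_snr * hg_noise_rms / (gn * rms(s[burst_idx]))
      X <- X + g %o% (sc * s)
    }

    # broadband muscle artifact on a random channel subset
    if (i %in% sess$art_ids) {
      chs <- sample.int(nch, max(2L, ceiling(nch / 4)))
      hi <- min(300, 0.45 * fs)
      dur <- round(0.4 * fs)
      on <- sample.int(ns - dur, 1)
      w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = dur))
      for (ch in chs) {
        burst <- narrowband_noise(ns, fs, c(20, hi))[on:(on + dur - 1)]
        X[ch, on:(on + dur - 1)] <- X[ch, on:(on + dur - 1)] +
          8 * stats::sd(Xn[, ch]) * w * burst
      }
    }
    data[i, , ] <- X

    # bipolar EMG (2) and EOG (2 -> stored as 2 bipolar pairs of 4 sites)
    aux <- one_over_f_noise(ns, 4, fs, 0.5)
    if (i == 1L) emg_noise_rms <- rms(aux[, 1])
    if (cfg$emg_task_snr > 0) {
      cont <- numeric(ns)
      cont[burst_idx] <- hann * narrowband_noise(ns, fs, c(70, 100))[burst_idx]
      side <- if (hand == "left") 1L else 2L
      aux[, side] <- aux[, side] +
        cfg$emg_task_snr * emg_noise_rms * cont / max(1e-12, rms(cont[burst_idx]))
    }
    emg[i, , ] <- t(aux[, 1:2])
    eog[i, , ] <- t(aux[, 3:4])
  }

  trials <- trial_set(data, fs = fs, time_s = time_s, labels = sess$labels)
  truth <- list(source_vertex_ids = src_of_hand,
                source_centers_hz = centers_of_hand,
                burst_onset = cfg$burst_window[1],
                burst_offset = cfg$burst_window[2],
                artifact_trial_ids = sess$art_ids)
  list(trials = trials, emg = emg, eog = eog, truth = truth, cfg = cfg)
}

#' Simulate a per-vertex fMRI Z map matched to the EEG ground truth
#'
#' Smooth supra-threshold blobs (Gaussian in 3-D Euclidean distance)
#' centered on the true source vertices, plus `extra_clusters` distractor
#' blobs at well-separated random vertices, plus optional Gaussian noise.
#' At `noise_sd = 0` thresholding at Z > 2.3 yields exactly one cluster per
#' true source plus one per distractor.
#'
#' @param mesh the [triangle_mesh()].
#' @param truth ground-truth list from [simulate_session()] (only
#'   `source_vertex_ids` is used), or a vector of vertex ids.
#' @param extra_clusters number of distractor blobs (default 0).
#' @param noise_sd additive Gaussian noise in Z units (default 0).
#' @param seed integer seed.
#' @param peak_z blob peak height for true sources (default 4).
#' @param distractor_z blob peak height for distractors (default 3.5).
#' @param blob_sd Gaussian spatial scale in mm (default 8).
#' @return numeric per-vertex Z vector of length `mesh$n`.
#' @export
simulate_fmri_map <- function(mesh, truth, extra_clusters = 0, noise_sd = 0,
                              seed = 1, peak_z = 4, distractor_z = 3.5,
                              blob_sd = 8) {
  ids <- if (is.list(truth)) truth$source_vertex_ids else truth
  ids <- unique(as.integer(ids))
  stop_if_not(all(ids >= 1 & ids <= mesh$n), "truth vertex ids out of range")
  with_seed(seed, {
    centers <- ids
    heights <- rep(peak_z, length(ids))
    if (extra_clusters > 0) {
      for (k in seq_len(extra_clusters)) {
        dmin <- apply(mesh$vertices, 1, function(p) {
          min(sqrt(colSums((t(mesh$vertices[centers, , drop = FALSE]) - p)^2)))
        })
        elig <- which(dmin > 3.5 * blob_sd)
        stop_if_not(length(elig) > 0,
                    "mesh too small to place %d separated distractor clusters",
                    extra_clusters)
        centers <- c(centers, sample(elig, 1))
        heights <- c(heights, distractor_z)
      }
    }
    z <- numeric(mesh$n)
    for (k in seq_along(centers)) {
      d2 <- rowSums(sweep(mesh$vertices, 2, mesh$vertices[centers[k], ])^2)
      z <- z + heights[k] * exp(-d2 / (2 * blob_sd^2))
    }
    z + stats::rnorm(mesh$n, 0, noise_sd)
  })
}
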