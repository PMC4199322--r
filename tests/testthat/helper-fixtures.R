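# Shared fixtures, all generated in code.

# Small mesh + leadfield pair used across tests.
small_forward <- function(n_vertices = 50, n_channels = 20, seed = 3) {
  make_mesh_and_leadfield(n_vertices, n_channels, seed = seed)
}

# Quick synthetic session at reduced size; fs = 400 Hz keeps the 70-100 Hz
# grid and the 100-150 Hz artifact band below Nyquist.
quick_session <- function(n_per_hand = 10, n_channels = 20, n_vertices = 50,
                          hg_snr = 2, artifact_rate = 0, seed = 7,
                          fwd = NULL, ...) {
  fwd <- fwd %||% small_forward(n_vertices, n_channels, seed = seed)
  cfg <- sim_config(n_trials_per_hand = n_per_hand, n_channels = n_channels,
                    fs = 400, hg_snr = hg_snr, artifact_rate = artifact_rate,
                    seed = seed, ...)
  c(simulate_session(cfg, fwd$mesh, fwd$leadfield), list(fwd = fwd))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# trial_set holding a given trials x channels x samples array with a 5 s
# protocol time axis.
as_trials <- function(data, fs, labels = NULL) {
  trial_set(data, fs = fs, time_s = -2 + (seq_len(dim(data)[3]) - 1) / fs,
            labels = labels)
}

# Plain surface_cluster stub with a prescribed centroid and radius (for
# proximity arithmetic tests that need no mesh).
cluster_stub <- function(centroid, radius, size = 1L) {
  structure(list(vertex_ids = seq_len(size), centroid = centroid,
                 mean_radius = radius, size = size),
            class = "surface_cluster")
}

# Source-TF map with a prescribed amplitude array and regular time axis.
map_from_a <- function(a, time_s, freqs_hz = seq_len(dim(a)[2]),
                       baseline_s = c(-1, 0), signal_s = c(0, 1)) {
  source_tf_map(a, a^2, n_trials = 1, freqs_hz = freqs_hz, time_s = time_s,
                valid = matrix(TRUE, dim(a)[2], dim(a)[3]),
                baseline_s = baseline_s, signal_s = signal_s)
}
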