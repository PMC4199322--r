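# Forward model: channels x sources gain matrix. The simulated gain uses
# the infinite-homogeneous-medium current-dipole potential with fixed
# dipole orientation along the (outward) vertex normal, which preserves the
# spatial structure a realistic boundary-element model would give at desk
# scale; externally computed leadfields can be supplied through the same
# constructor.

#' Leadfield (forward model)
#'
#' @param gain numeric channels x sources matrix: scalp potential per unit
#'   dipole moment.
#' @param channel_names character vector, one per row.
#' @param source_vertex_ids integer vector, one mesh vertex id per column.
#' @param channel_positions optional channels x 3 sensor coordinates (mm);
#'   used by the synthetic-noise generator for spatially smooth mixing.
#' @return an object of class `leadfield`.
#' @export
leadfield <- function(gain, channel_names = NULL, source_vertex_ids = NULL,
                      channel_positions = NULL) {
  gain <- as.matrix(gain)
  stop_if_not(all(is.finite(gain)), "gain must be finite")
  cn <- colSums(gain^2)
  stop_if_not(all(cn > 0), "leadfield has an all-zero source column")
  channel_names <- channel_names %||% sprintf("ch%02d", seq_len(nrow(gain)))
  source_vertex_ids <- source_vertex_ids %||% seq_len(ncol(gain))
  stop_if_not(length(channel_names) == nrow(gain),
              "channel_names length must match rows of gain")
  stop_if_not(length(source_vertex_ids) == ncol(gain),
              "source_vertex_ids length must match columns of gain")
  structure(list(gain = gain, channel_names = channel_names,
                 source_vertex_ids = as.integer(source_vertex_ids),
                 channel_positions = channel_positions),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("Leadfield: %d channels x %d sources\n",
              nrow(x$gain), ncol(x$gain)))
  invisible(x)
}

#' Current-dipole potential in an infinite homogeneous medium
#'
#' V = p . (r - r0) / (4 pi sigma |r - r0|^3) for a dipole with moment
#' vector p at r0 observed at r. Vectorized over sensors and dipoles.
#'
#' @param src_pos k x 3 dipole positions (mm).
#' @param src_ori k x 3 unit moment orientations.
#' @param sens_pos n x 3 sensor positions (mm).
#' @param sigma conductivity (default 0.33 S/m; with mm coordinates the
#'   absolute scale is arbitrary, and every downstream statistic is scale
#'   invariant).
#' @return n x k matrix of potentials per unit dipole moment.
#' @export
dipole_potential <- function(src_pos, src_ori, sens_pos, sigma = 0.33) {
  src_pos <- matrix(src_pos, ncol = 3)
  src_ori <- matrix(src_ori, ncol = 3)
  sens_pos <- matrix(sens_pos, ncol = 3)
  k <- nrow(src_pos); n <- nrow(sens_pos)
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    dr <- sweep(sens_pos, 2, src_pos[j, ])
    r3 <- rowSums(dr^2)^1.5
    stop_if_not(all(r3 > 1e-9),
                "degenerate geometry: sensor coincides with a source")
    out[, j] <- (dr %*% src_ori[j, ]) / (4 * pi * sigma * r3)
  }
  out
}

#' Generate a sphere-like cortical mesh and its analytic leadfield
#'
#' Sources sit on a jittered sphere of radius `source_radius`; sensors on a
#' surrounding shell of radius `sensor_radius` (a Fibonacci lattice). Gains
#' come from [dipole_potential()] with dipole orientation along the outward
#' vertex normal. Deterministic given `seed`.
#'
#' @param n_vertices requested source count (>= 20); the mesh holds the
#'   smallest latitude-longitude grid count that is at least this large.
#' @param n_channels sensor count (>= 8).
#' @param seed integer seed controlling the radial jitter.
#' @param source_radius,sensor_radius shell radii in mm.
#' @param jitter radial jitter amplitude in mm.
#' @return list with elements `mesh` ([triangle_mesh()]) and `leadfield`
#'   ([leadfield()], with sensor positions attached).
#' @export
make_mesh_and_leadfield <- function(n_vertices, n_channels, seed = 1,
                                    source_radius = 70, sensor_radius = 95,
                                    jitter = 2) {
  stop_if_not(n_vertices >= 20, "n_vertices must be >= 20")
  stop_if_not(n_channels >= 8, "n_channels must be >= 8")
  stop_if_not(sensor_radius > source_radius + jitter,
              "sensor shell must lie outside the source shell")
  mesh <- sphere_mesh(n_vertices, radius = source_radius, jitter = jitter,
                      seed = seed)
  # Fibonacci lattice on the sensor shell
  i <- seq_len(n_channels)
  ga <- pi * (3 - sqrt(5))
  z <- 1 - (2 * i - 1) / n_channels
  rho <- sqrt(pmax(0, 1 - z^2))
  sens <- sensor_radius * cbind(rho * cos(ga * i), rho * sin(ga * i), z)
  ori <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))  # outward normals
  gain <- dipole_potential(mesh$vertices, ori, sens)
  list(mesh = mesh,
       leadfield = leadfield(gain, channel_positions = sens))
}
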