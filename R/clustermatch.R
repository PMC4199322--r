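# Contiguous supra-threshold clusters on the cortical mesh, the
# centroid/radius proximity measure between EEG high-gamma and fMRI cluster
# sets, and its resampling significance. Distances are 3-D Euclidean (mm),
# not geodesic: deviations are small against the gross mismatches the
# measure is meant to detect.

#' Surface cluster
#'
#' @param vertex_ids member vertex ids (>= 1 member).
#' @param mesh the [triangle_mesh()] supplying coordinates.
#' @return object of class `surface_cluster`: `vertex_ids`, `centroid`
#'   (mean member coordinate, mm), `mean_radius` (mean member-to-centroid
#'   Euclidean distance, mm), `size`.
#' @export
centroid_radius <- function(vertex_ids, mesh) {
  vertex_ids <- as.integer(vertex_ids)
  stop_if_not(length(vertex_ids) >= 1, "cluster must be non-empty")
  stop_if_not(all(vertex_ids >= 1 & vertex_ids <= mesh$n),
              "vertex ids out of range")
  xyz <- mesh$vertices[vertex_ids, , drop = FALSE]
  ctr <- colMeans(xyz)
  rad <- mean(sqrt(rowSums(sweep(xyz, 2, ctr)^2)))
  structure(list(vertex_ids = vertex_ids, centroid = ctr,
                 mean_radius = rad, size = length(vertex_ids)),
            class = "surface_cluster")
}

#' @export
print.surface_cluster <- function(x, ...) {
  cat(sprintf("Surface cluster: %d vertices, centroid (%.1f, %.1f, %.1f) mm, mean radius %.1f mm\n",
              x$size, x$centroid[1], x$centroid[2], x$centroid[3],
              x$mean_radius))
  invisible(x)
}

#' Extract contiguous supra-threshold clusters
#'
#' Connected components (two vertices adjacent iff they share a face edge)
#' of the supra-threshold vertex set: `v >= threshold` for `mode = "z"`,
#' `v <= threshold` for `mode = "p"`. An empty supra-threshold set yields
#' an empty list; disconnected meshes are handled per component.
#'
#' @param vmap per-vertex values, length `mesh$n`.
#' @param mesh the [triangle_mesh()].
#' @param threshold cut value (e.g. 2.3 for fMRI Z maps, 0.1 for EEG
#'   permutation p maps).
#' @param mode `"z"` (keep high values) or `"p"` (keep low values).
#' @return list of [centroid_radius()] clusters, ordered by smallest
#'   member vertex id.
#' @export
extract_clusters <- function(vmap, mesh, threshold, mode = c("z", "p")) {
  mode <- match.arg(mode)
  stop_if_not(length(vmap) == mesh$n,
              "vmap length (%d) does not match the mesh (%d vertices)",
              length(vmap), mesh$n)
  keep <- if (mode == "z") which(vmap >= threshold) else which(vmap <= threshold)
  if (length(keep) == 0) return(list())
  e <- mesh_edges(mesh)
  inset <- logical(mesh$n); inset[keep] <- TRUE
  e <- e[inset[e[, 1]] & inset[e[, 2]], , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e[, 1]), to = as.character(e[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(keep)))
  comp <- igraph::components(g)
  members <- split(keep[match(igraph::V(g)$name, as.character(keep))],
                   comp$membership)
  members <- members[order(vapply(members, min, 0))]
  lapply(members, centroid_radius, mesh = mesh)
}

#' Proximity between EEG and fMRI cluster sets
#'
#' Pairwise distance `d = max(0, |c1 - c2| - r1 - r2)` (centroid separation
#' minus both mean radii, floored at zero for overlapping clusters). Each
#' fMRI cluster takes its distance to the nearest EEG cluster; if there are
#' more fMRI clusters than EEG clusters, only the `#EEG` smallest are kept.
#' The compound measure is the median of the kept distances.
#'
#' @param eeg_clusters,fmri_clusters lists of [centroid_radius()] clusters.
#' @return object of class `hg_proximity`: `pair_distances` (per fMRI
#'   cluster min distance), `kept`, `compound` (mm), `p_value` (NA until
#'   [resample_significance()]), plus bookkeeping. If either side is empty
#'   the result is NA with a `reason`.
#' @export
proximity <- function(eeg_clusters, fmri_clusters) {
  if (length(eeg_clusters) == 0 || length(fmri_clusters) == 0) {
    return(structure(list(pair_distances = numeric(0), kept = numeric(0),
                          compound = NA_real_, p_value = NA_real_,
                          n_resamples = NA_integer_, seed = NA_integer_,
                          reason = "no clusters on one side: no match exists"),
                     class = "hg_proximity"))
  }
  dmin <- vapply(fmri_clusters, function(fc) {
    min(vapply(eeg_clusters, function(ec) {
      max(0, sqrt(sum((fc$centroid - ec$centroid)^2)) -
            fc$mean_radius - ec$mean_radius)
    }, 0))
  }, 0)
  k <- min(length(eeg_clusters), length(fmri_clusters))
  kept <- sort(dmin)[seq_len(k)]
  structure(list(pair_distances = dmin, kept = kept,
                 compound = stats::median(kept), p_value = NA_real_,
                 n_resamples = NA_integer_, seed = NA_integer_,
                 reason = NULL),
            class = "hg_proximity")
}

#' @export
print.hg_proximity <- function(x, ...) {
  if (is.na(x$compound)) {
    cat("EEG-fMRI proximity: NA (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("EEG-fMRI proximity: compound %.1f mm over %d matched cluster(s)\n",
              x$compound, length(x$kept)))
  if (!is.na(x$p_value))
    cat(sprintf("  resampling p = %.4g (%d resamples, seed %d)\n",
                x$p_value, x$n_resamples, x$seed))
  invisible(x)
}

# Grow a connected patch of exactly `size` vertices from a random seed
# vertex: breadth-first expansion with a uniformly random frontier pick at
# every step. Retries from a new seed if a component is too small.
grow_patch <- function(adj, n_vertices, size) {
  repeat {
    start <- sample.int(n_vertices, 1)
    members <- start
    frontier <- setdiff(adj[[start]], members)
    while (length(members) < size && length(frontier) > 0) {
      nxt <- frontier[sample.int(length(frontier), 1)]
      members <- c(members, nxt)
      frontier <- setdiff(union(frontier, adj[[nxt]]), members)
    }
    if (length(members) == size) return(members)
  }
}

#' Resampling significance of the proximity measure
#'
#' Each resample relocates every fMRI cluster to a random position on the
#' mesh as a connected patch of identical vertex count (breadth-first
#' growth with random frontier ordering), keeping the number of clusters
#' and each cluster's size constant, and recomputes the compound proximity
#' against the fixed EEG clusters. Smaller distance means a better match,
#' so `p = (1 + #\{null <= observed\}) / (1 + R)`.
#'
#' @param fmri_clusters,eeg_clusters lists of [centroid_radius()] clusters.
#' @param mesh the [triangle_mesh()].
#' @param n_resamples resample count (default 1000).
#' @param seed integer seed.
#' @return an `hg_proximity` object with `p_value`, `null` (vector of
#'   resampled compounds), `n_resamples` and `seed` filled in.
#' @export
resample_significance <- function(fmri_clusters, eeg_clusters, mesh,
                                  n_resamples = 1000, seed = 1) {
  obs <- proximity(eeg_clusters, fmri_clusters)
  if (is.na(obs$compound)) return(obs)
  sizes <- vapply(fmri_clusters, function(c) c$size, 0L)
  adj <- mesh_adjacency(mesh)
  comp_sizes <- igraph::components(
    igraph::graph_from_edgelist(mesh_edges(mesh), directed = FALSE))$csize
  stop_if_not(max(sizes) <= max(comp_sizes),
              "a cluster size exceeds the largest mesh component")
  null <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(b) {
      fake <- lapply(sizes, function(s) {
        centroid_radius(grow_patch(adj, mesh$n, s), mesh)
      })
      proximity(eeg_clusters, fake)$compound
    }, 0)
  })
  obs$p_value <- (1 + sum(null <= obs$compound)) / (1 + n_resamples)
  obs$null <- null
  obs$n_resamples <- as.integer(n_resamples)
  obs$seed <- as.integer(seed)
  obs
}

#' Vertex-wise group average of Z maps
#'
#' @param zmaps list of per-subject per-vertex vectors on a shared mesh, or
#'   a subjects x vertices matrix.
#' @return per-vertex mean vector.
#' @export
group_average <- function(zmaps) {
  if (is.list(zmaps)) {
    n <- unique(lengths(zmaps))
    stop_if_not(length(n) == 1,
                "all maps must live on the same mesh (equal lengths)")
    zmaps <- do.call(rbind, zmaps)
  }
  colMeans(zmaps)
}

#' Group-level threshold equivalent to a single-subject threshold
#'
#' The mean of n independent standard-normal Z maps has SD 1/sqrt(n), so
#' the group-average threshold with the same tail level as a single-map
#' threshold `z_single` is `z_single / sqrt(n)`. The companion one-sided
#' normal confidence level `pnorm(z_single)` is attached as attribute
#' `"confidence_level"` (2.3 corresponds to 99% to the nearest percent).
#'
#' @param z_single single-subject Z threshold (e.g. 2.3).
#' @param n_subjects number of averaged subjects (>= 1).
#' @return the group threshold (numeric), with attribute
#'   `"confidence_level"`.
#' @export
equivalent_group_threshold <- function(z_single, n_subjects) {
  stop_if_not(n_subjects >= 1, "n_subjects must be >= 1")
  structure(z_single / sqrt(n_subjects),
            confidence_level = stats::pnorm(z_single))
}
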