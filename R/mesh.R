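# Triangle meshes of the cortical source space, their adjacency structure,
# and graph (edge-hop) distances. Coordinates are in mm throughout.

#' Triangle mesh of a cortical source space
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates (mm).
#' @param faces integer M x 3 matrix of 1-based vertex indices.
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `n` (vertex count).
#' @details Invariants enforced: all face indices valid, every vertex
#'   referenced by at least one face, all coordinates finite.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stop_if_not(ncol(vertices) == 3, "vertices must be N x 3")
  stop_if_not(all(is.finite(vertices)), "vertex coordinates must be finite")
  n <- nrow(vertices)
  stop_if_not(all(faces >= 1L & faces <= n), "face indices out of range")
  stop_if_not(all(seq_len(n) %in% as.vector(faces)),
              "every vertex must be referenced by at least one face")
  structure(list(vertices = vertices, faces = faces, n = n),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d faces\n", x$n, nrow(x$faces)))
  invisible(x)
}

# Unique undirected edges of a mesh (two vertices are adjacent iff they
# share a face edge), as a 2-column matrix.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Vertex adjacency list of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return list of length `mesh$n`; element v holds the sorted integer ids
#'   of vertices sharing a face edge with v.
#' @export
mesh_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  adj <- vector("list", mesh$n)
  both <- rbind(e, e[, 2:1])
  sp <- split(both[, 2], both[, 1])
  for (nm in names(sp)) adj[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
  for (v in seq_len(mesh$n)) if (is.null(adj[[v]])) adj[[v]] <- integer(0)
  adj
}

#' Edge-hop distances from a vertex
#'
#' Breadth-first search over the mesh adjacency graph. Useful for judging
#' localization error in units of mesh edges.
#'
#' @param mesh a [triangle_mesh()].
#' @param from starting vertex id.
#' @return integer vector of hop counts (Inf for unreachable vertices).
#' @export
mesh_edge_distance <- function(mesh, from) {
  stop_if_not(from >= 1 && from <= mesh$n, "vertex id out of range")
  adj <- mesh_adjacency(mesh)
  d <- rep(Inf, mesh$n)
  d[from] <- 0
  frontier <- from
  k <- 0
  while (length(frontier) > 0) {
    k <- k + 1
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.infinite(d[nxt])]
    d[nxt] <- k
    frontier <- nxt
  }
  d
}

# Sphere-like mesh: latitude rings x longitude segments plus two poles,
# radius `radius` mm with seeded radial jitter. Vertex count is the
# smallest grid count >= n_vertices.
sphere_mesh <- function(n_vertices, radius = 70, jitter = 2, seed = 1) {
  stop_if_not(n_vertices >= 6, "need at least 6 vertices")
  ns <- max(3L, as.integer(ceiling(sqrt(2 * (n_vertices - 2)))))
  nr <- max(1L, as.integer(ceiling((n_vertices - 2) / ns)))
  n <- nr * ns + 2L
  theta <- pi * seq_len(nr) / (nr + 1)            # polar angle per ring
  phi <- 2 * pi * (seq_len(ns) - 1) / ns          # azimuth per segment
  verts <- matrix(0, n, 3)
  verts[1, ] <- c(0, 0, 1)
  for (i in seq_len(nr)) {
    idx <- 1L + (i - 1L) * ns + seq_len(ns)
    # stagger alternate rings for less degenerate triangles
    ph <- phi + (i %% 2) * pi / ns
    verts[idx, ] <- cbind(sin(theta[i]) * cos(ph),
                          sin(theta[i]) * sin(ph),
                          cos(theta[i]))
  }
  verts[n, ] <- c(0, 0, -1)
  r <- with_seed(seed, radius + stats::runif(n, -jitter, jitter))
  verts <- verts * r
  ring <- function(i) 1L + (i - 1L) * ns + seq_len(ns)
  faces <- list()
  r1 <- ring(1)
  faces[[1]] <- cbind(1L, r1, c(r1[-1], r1[1]))   # top fan
  for (i in seq_len(nr - 1L)) {
    a <- ring(i); b <- ring(i + 1L)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    faces[[length(faces) + 1]] <- cbind(a, b, b2)
    faces[[length(faces) + 1]] <- cbind(a, b2, a2)
  }
  rl <- ring(nr)
  faces[[length(faces) + 1]] <- cbind(n, c(rl[-1], rl[1]), rl)  # bottom fan
  triangle_mesh(verts, do.call(rbind, faces))
}
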