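# Surface clusters, the proximity measure, resampling significance and the
# group-threshold arithmetic.

test_that("cluster extraction finds the constructed components", {
  fwd <- small_forward(300, 10, seed = 9)
  mesh <- fwd$mesh
  truth <- list(source_vertex_ids = c(a = 10L, b = 250L))
  z <- simulate_fmri_map(mesh, truth, seed = 3)
  cl <- extract_clusters(z, mesh, 2.3, mode = "z")
  expect_length(cl, 2)
  got <- sort(unname(vapply(cl, function(c) c$vertex_ids[which.max(
    z[c$vertex_ids])], 0L)))
  expect_equal(got, c(10L, 250L))
  expect_true(all(vapply(cl, function(c) all(z[c$vertex_ids] >= 2.3), TRUE)))
  # nothing above threshold
  expect_length(extract_clusters(z, mesh, 99, mode = "z"), 0)
})

test_that("p-mode clusters nest as the threshold relaxes", {
  fwd <- small_forward(200, 10, seed = 10)
  set.seed(6)
  p <- runif(fwd$mesh$n)
  cl05 <- extract_clusters(p, fwd$mesh, 0.05, mode = "p")
  cl10 <- extract_clusters(p, fwd$mesh, 0.10, mode = "p")
  for (c5 in cl05) {
    contained <- any(vapply(cl10, function(c10)
      all(c5$vertex_ids %in% c10$vertex_ids), TRUE))
    expect_true(contained)
  }
})

test_that("centroid and mean spherical radius follow the geometry", {
  sq <- 4
  v <- rbind(c(0, 0, 0), c(sq, 0, 0), c(sq, sq, 0), c(0, sq, 0), c(0, 0, 10))
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 2, 5), c(3, 4, 5))
  mesh <- triangle_mesh(v, f)
  c1 <- centroid_radius(2, mesh)
  expect_equal(unname(c1$centroid), c(sq, 0, 0))
  expect_equal(c1$mean_radius, 0)
  c2 <- centroid_radius(c(1, 2), mesh)
  expect_equal(unname(c2$centroid), c(sq / 2, 0, 0))
  expect_equal(c2$mean_radius, sq / 2)
  c4 <- centroid_radius(1:4, mesh)          # square corners, side sq
  expect_equal(c4$mean_radius, sq / sqrt(2))
  expect_error(centroid_radius(integer(0), mesh), "non-empty")
})

test_that("proximity arithmetic matches the centroid-minus-radii rule", {
  e <- list(cluster_stub(c(0, 0, 0), 4))
  f_overlap <- list(cluster_stub(c(6, 0, 0), 3))
  expect_equal(proximity(e, f_overlap)$compound, 0)   # 6 - 4 - 3 < 0 -> 0

  e2 <- list(cluster_stub(c(0, 0, 0), 5))
  f2 <- list(cluster_stub(c(20, 0, 0), 3))
  expect_equal(proximity(e2, f2)$compound, 12)

  # 1 EEG cluster, 3 fMRI clusters at distances 4, 10, 25: keep the single
  # smallest, compound = 4
  e3 <- list(cluster_stub(c(0, 0, 0), 0))
  f3 <- list(cluster_stub(c(4, 0, 0), 0), cluster_stub(c(10, 0, 0), 0),
             cluster_stub(c(0, 25, 0), 0))
  px <- proximity(e3, f3)
  expect_equal(px$compound, 4)
  expect_equal(sort(px$pair_distances), c(4, 10, 25))
  expect_length(px$kept, 1)

  # an empty side yields NA with a reason, mirroring "no match exists"
  na <- proximity(list(), f3)
  expect_true(is.na(na$compound))
  expect_match(na$reason, "no clusters")
})

test_that("proximity is invariant under rigid motion and radius exchange", {
  e <- list(cluster_stub(c(1, 2, 3), 2))
  f <- list(cluster_stub(c(11, 2, 3), 5))
  base <- proximity(e, f)$compound
  # translate both by the same vector
  e2 <- list(cluster_stub(c(1, 2, 3) + c(-4, 7, 1), 2))
  f2 <- list(cluster_stub(c(11, 2, 3) + c(-4, 7, 1), 5))
  expect_equal(proximity(e2, f2)$compound, base)
  # swap the radii between the pair
  e3 <- list(cluster_stub(c(1, 2, 3), 5))
  f3 <- list(cluster_stub(c(11, 2, 3), 2))
  expect_equal(proximity(e3, f3)$compound, base)
})

test_that("resampling preserves cluster count and sizes and rewards overlap", {
  fwd <- small_forward(400, 10, seed = 14)
  mesh <- fwd$mesh
  truth <- list(source_vertex_ids = 37L)
  z <- simulate_fmri_map(mesh, truth, extra_clusters = 2, seed = 5)
  fcl <- extract_clusters(z, mesh, 2.3, mode = "z")
  expect_length(fcl, 3)
  # EEG cluster right on top of the true source
  adj <- mesh_adjacency(mesh)
  ecl <- list(centroid_radius(c(37L, adj[[37]][1:3]), mesh))
  res <- resample_significance(fcl, ecl, mesh, n_resamples = 99, seed = 8)
  expect_equal(res$n_resamples, 99L)
  expect_length(res$null, 99)
  expect_equal(res$compound, 0)
  expect_lte(res$p_value, 0.1)
  # reproducibility
  res2 <- resample_significance(fcl, ecl, mesh, n_resamples = 99, seed = 8)
  expect_identical(res$null, res2$null)
})

test_that("randomly grown patches are connected with the requested size", {
  fwd <- small_forward(150, 10, seed = 16)
  adj <- mesh_adjacency(fwd$mesh)
  set.seed(2)
  for (s in c(1, 4, 12)) {
    patch <- hgmap:::grow_patch(adj, fwd$mesh$n, s)
    expect_length(unique(patch), s)
    if (s > 1) {
      reach <- patch[1]
      repeat {
        nxt <- union(reach, intersect(unlist(adj[reach]), patch))
        if (length(nxt) == length(reach)) break
        reach <- nxt
      }
      expect_setequal(reach, patch)
    }
  }
})

test_that("group averaging and the equivalent threshold are exact", {
  m1 <- c(1, 2, 3)
  expect_equal(group_average(list(m1, m1, m1)), m1)
  expect_equal(group_average(list(m1, -m1)), c(0, 0, 0))
  set.seed(20)
  maps <- matrix(rnorm(10 * 4000), nrow = 10)
  expect_lt(abs(sd(group_average(maps)) - 1 / sqrt(10)) * sqrt(10), 0.05)
  expect_error(group_average(list(1:3, 1:4)), "same mesh")

  thr <- equivalent_group_threshold(2.3, 10)
  expect_equal(as.numeric(thr), 2.3 / sqrt(10))
  expect_equal(as.numeric(equivalent_group_threshold(2.3, 1)), 2.3)
  expect_equal(round(attr(thr, "confidence_level"), 2), 0.99)
  expect_error(equivalent_group_threshold(2.3, 0), "n_subjects")
})

test_that("null resamples match the distribution of random EEG placements", {
  fwd <- small_forward(300, 10, seed = 22)
  mesh <- fwd$mesh
  z <- simulate_fmri_map(mesh, list(source_vertex_ids = 11L),
                         extra_clusters = 1, seed = 9)
  fcl <- extract_clusters(z, mesh, 2.3, mode = "z")
  adj <- mesh_adjacency(mesh)
  set.seed(33)
  observed <- vapply(seq_len(200), function(i) {
    ecl <- list(centroid_radius(hgmap:::grow_patch(adj, mesh$n, 4), mesh))
    proximity(ecl, fcl)$compound
  }, 0)
  ecl0 <- list(centroid_radius(hgmap:::grow_patch(adj, mesh$n, 4), mesh))
  null <- resample_significance(fcl, ecl0, mesh, n_resamples = 200,
                                seed = 44)$null
  ks <- suppressWarnings(ks.test(observed, null))
  expect_gt(ks$p.value, 0.01)
})
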