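no_smooth <- conversion_config(smoothing_iterations = 0L)

test_that("a regular tetrahedron converts to 4 hexes with 15 nodes", {
  res <- convert_tet_to_hex(regular_tet_mesh(), no_smooth)
  expect_equal(res$stats$n_hex, 4L)
  expect_equal(nrow(res$hex_mesh$nodes), 15L)   # 4 V + 6 E + 4 F + 1 C
  expect_equal(nrow(res$boundary_quads$faces), 12L)  # 3 per boundary tri
  expect_equal(table(res$node_provenance$kind)[["vertex"]], 4L)
  expect_equal(table(res$node_provenance$kind)[["edge_midpoint"]], 6L)
  expect_equal(table(res$node_provenance$kind)[["face_centroid"]], 4L)
  expect_equal(table(res$node_provenance$kind)[["element_centroid"]], 1L)
  # the four hexes partition the tet exactly
  expect_equal(res$stats$volume_out, sqrt(2) / 12, tolerance = 1e-12)
  # every corner Jacobian positive for a positively oriented input
  sj <- hexamesh:::hex_corner_jacobians(res$hex_mesh$nodes,
                                        res$hex_mesh$elements)
  expect_gt(min(sj), 0)
})

test_that("two face-sharing tets share inserted nodes (conformality)", {
  res <- convert_tet_to_hex(two_tets(), no_smooth)
  expect_equal(res$stats$n_hex, 8L)
  expect_equal(nrow(res$hex_mesh$nodes), 23L)   # 5 V + 9 E + 7 F + 2 C
  # no two distinct nodes share coordinates
  nd <- res$hex_mesh$nodes
  key <- paste(round(nd[, 1L], 9L), round(nd[, 2L], 9L),
               round(nd[, 3L], 9L))
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(nrow(res$boundary_quads$faces), 18L)
})

test_that("node count identity N = V + E + F + T holds on random meshes", {
  set.seed(21)
  for (rep in 1:4) {
    m <- random_small_tet_mesh(sample(5:50, 1L))
    res <- convert_tet_to_hex(m, no_smooth)
    brute <- brute_edges_faces(m$elements)
    expect_equal(nrow(res$hex_mesh$nodes),
                 n_nodes(m) + brute$n_edges + brute$n_faces +
                   n_elements(m))
    expect_equal(res$stats$n_hex, 4L * n_elements(m))
  }
})

test_that("hex volume equals tet volume to 1e-9 relative before smoothing", {
  set.seed(33)
  for (rep in 1:3) {
    m <- random_small_tet_mesh(20L)
    res <- convert_tet_to_hex(m, no_smooth)
    expect_equal(res$stats$volume_out, mesh_volume(m),
                 tolerance = 1e-9)
  }
})

test_that("conversion is deterministic", {
  m <- random_small_tet_mesh(12L)
  r1 <- convert_tet_to_hex(m)
  r2 <- convert_tet_to_hex(m)
  expect_identical(r1$hex_mesh$nodes, r2$hex_mesh$nodes)
  expect_identical(r1$hex_mesh$elements, r2$hex_mesh$elements)
  expect_identical(r1$node_provenance, r2$node_provenance)
  expect_identical(r1$flagged_elements, r2$flagged_elements)
})

test_that("degenerate and duplicate-node inputs are reported", {
  flat <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                         c(0.5, 0.5, 1e-9)), matrix(1:4, 1L))
  flat$nodes[4L, 3L] <- 1e-14   # squash after construction checks
  expect_error(convert_tet_to_hex(flat), "degenerate")

  dup <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                        c(1, 0, 0)),
                  rbind(c(1L, 2L, 3L, 4L), c(5L, 3L, 4L, 1L)))
  expect_warning(convert_tet_to_hex(dup, no_smooth), "duplicate node")
})

test_that("equilateral faces yield quads with angles 120/90/60/90", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  quads <- subdivide_triangle(tri)
  expect_length(quads, 3L)
  for (q in quads) {
    ang <- sort(oracle_quad_angles(q))
    expect_equal(ang, c(60, 90, 90, 120), tolerance = 1e-9)
    expect_equal(sum(ang), 360, tolerance = 1e-9)
  }
})

test_that("triangle subdivision tiles the triangle exactly", {
  set.seed(5)
  for (rep in 1:5) {
    tri <- matrix(stats::rnorm(9L), 3L)
    area <- 0.5 * sqrt(sum(crossprod_vec(tri[2L, ] - tri[1L, ],
                                         tri[3L, ] - tri[1L, ])^2))
    quads <- subdivide_triangle(tri)
    qarea <- sum(vapply(quads, function(q) {
      a1 <- 0.5 * sqrt(sum(crossprod_vec(q[2L, ] - q[1L, ],
                                         q[3L, ] - q[1L, ])^2))
      a2 <- 0.5 * sqrt(sum(crossprod_vec(q[3L, ] - q[1L, ],
                                         q[4L, ] - q[1L, ])^2))
      a1 + a2
    }, numeric(1L)))
    expect_equal(qarea, area, tolerance = 1e-9)
  }
  expect_error(subdivide_triangle(rbind(c(0, 0, 0), c(1, 1, 1),
                                        c(2, 2, 2))), "degenerate")
})

test_that("right isoceles subdivision keeps 90 degrees at the right angle", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))  # right angle at vertex 1
  q <- subdivide_triangle(tri)[[1L]]
  expect_equal(oracle_quad_angles(q)[1L], 90, tolerance = 1e-9)
})

test_that("predicted quad angles match direct measurement", {
  pq <- predict_quad_angles(c(60, 60, 60))
  expect_equal(unname(pq[1L, ]), c(60, 90, 120, 90), tolerance = 1e-9)
  expect_equal(rowSums(pq), rep(360, 3L), tolerance = 1e-9)

  # independent oracle: explicit coordinates for a 90/45/45 triangle
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  direct <- t(vapply(subdivide_triangle(tri), oracle_quad_angles,
                     numeric(4L)))
  pq2 <- predict_quad_angles(c(90, 45, 45))
  expect_equal(sort(as.vector(pq2)), sort(as.vector(direct)),
               tolerance = 1e-6)
  expect_error(predict_quad_angles(c(90, 40, 40)), "sum to 180")
})

test_that("angle enforcement repairs or flags, and never deletes", {
  # regular tet: max angle 120, nothing to do
  res <- convert_tet_to_hex(regular_tet_mesh())
  expect_equal(res$stats$smoothing_iterations, 0L)
  expect_length(res$flagged_elements, 0L)
  expect_equal(res$stats$max_angle, 120, tolerance = 1e-9)

  # sheared sliver: initial conversion violates the bound
  sliver <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.98, 0.05, 0),
                           c(0.5, 0.3, 0.04)), matrix(1:4, 1L))
  raw <- convert_tet_to_hex(sliver, no_smooth)
  expect_gt(raw$stats$max_angle, 140)
  rep <- convert_tet_to_hex(sliver, conversion_config(
    smoothing_iterations = 50L))
  expect_equal(rep$stats$n_hex, 4L)
  ang <- hexamesh:::hex_max_corner_angles(rep$hex_mesh$nodes,
                                          rep$hex_mesh$elements)
  # contract dichotomy: each hex is either repaired or flagged
  expect_identical(rep$flagged_elements, which(ang > 140))
  not_flagged <- setdiff(seq_along(ang), rep$flagged_elements)
  if (length(not_flagged) > 0L) {
    expect_lte(max(ang[not_flagged]), 140)
  }
})

test_that("boundary-preserving enforcement keeps volume and boundary", {
  m <- sphere_tet_mesh(8, 2)
  res <- convert_tet_to_hex(m)
  expect_lte(res$stats$volume_drift, 0.01)
  # boundary quads still tile the input boundary: divergence volume of the
  # converted boundary equals the input volume
  expect_equal(enclosed_volume(res$boundary_quads, "mm3"),
               mesh_volume(m), tolerance = 1e-9)
  # original vertices untouched
  expect_identical(res$hex_mesh$nodes[seq_len(n_nodes(m)), ], m$nodes)
})
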