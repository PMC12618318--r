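test_that("a unit cube scores perfectly on every metric", {
  h <- unit_cube_hex()
  expect_equal(as.numeric(scaled_jacobian(h)), 1.0)
  expect_equal(as.numeric(aspect_ratio(h)), 1.0)
  expect_equal(skewness_deg(h), 0, tolerance = 1e-9)
  expect_equal(warping_deg(h), 0, tolerance = 1e-9)
  expect_equal(max_corner_angle_deg(h), 90, tolerance = 1e-9)
})

test_that("a fully flattened hex has zero scaled Jacobian", {
  h <- unit_cube_hex()
  h$nodes[, 3L] <- 0
  expect_equal(as.numeric(scaled_jacobian(h)), 0, tolerance = 1e-12)
})

test_that("regular-tet hexes score sqrt(1/2) against a determinant oracle", {
  res <- convert_tet_to_hex(regular_tet_mesh(),
                            conversion_config(smoothing_iterations = 0L))
  sj <- scaled_jacobian(res$hex_mesh)
  # independent oracle: base-R det() over all 32 corners
  nb <- rbind(c(2L, 4L, 5L), c(3L, 1L, 6L), c(4L, 2L, 7L), c(1L, 3L, 8L),
              c(8L, 6L, 1L), c(5L, 7L, 2L), c(6L, 8L, 3L), c(7L, 5L, 4L))
  oracle <- apply(res$hex_mesh$elements, 1L, function(e) {
    p <- res$hex_mesh$nodes[e, ]
    min(vapply(1:8, function(c0) {
      E <- t(p[nb[c0, ], ]) - p[c0, ]
      E <- sweep(E, 2L, sqrt(colSums(E^2)), "/")
      det(E)
    }, numeric(1L)))
  })
  expect_equal(as.numeric(sj), oracle, tolerance = 1e-12)
  expect_equal(min(sj), sqrt(0.5), tolerance = 1e-9)
})

test_that("tet scaled Jacobian is 1 for the regular tetrahedron", {
  expect_equal(as.numeric(scaled_jacobian(regular_tet_mesh())), 1,
               tolerance = 1e-12)
  # squashing reduces it below the tet acceptance bound
  squash <- regular_tet_mesh()
  squash$nodes[4L, 3L] <- squash$nodes[4L, 3L] * 0.1
  expect_lt(as.numeric(scaled_jacobian(squash)), 0.8)
})

test_that("metrics are invariant under rigid motion and scaling", {
  set.seed(17)
  res <- convert_tet_to_hex(random_small_tet_mesh(8L))
  h <- res$hex_mesh
  R <- random_rotation()
  moved <- rigid_transform_mesh(h, R, c(4, -2, 7))
  for (fn in list(scaled_jacobian, aspect_ratio, skewness_deg,
                  warping_deg, max_corner_angle_deg)) {
    expect_equal(as.numeric(fn(moved)), as.numeric(fn(h)),
                 tolerance = 1e-8)
  }
  scaled <- h
  scaled$nodes <- scaled$nodes * 3.7
  for (fn in list(scaled_jacobian, aspect_ratio, skewness_deg,
                  warping_deg, max_corner_angle_deg)) {
    expect_equal(as.numeric(fn(scaled)), as.numeric(fn(h)),
                 tolerance = 1e-9)
  }
  expect_lte(max(scaled_jacobian(h)), 1)
})

test_that("warping is zero for planar quads and positive for warped ones", {
  s <- boundary_surface(unit_cube_hex())
  expect_equal(warping_deg(s), rep(0, 6L), tolerance = 1e-9)
  warped <- unit_cube_hex()
  warped$nodes[7L, 3L] <- 1.3     # lift one corner of the top face
  expect_gt(max(warping_deg(warped)), 5)
})

test_that("equilateral-face quads from subdivision have max angle 120", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  q <- subdivide_triangle(tri)[[1L]]
  s <- surface_mesh(q, matrix(1:4, 1L))
  expect_equal(max_corner_angle_deg(s), 120, tolerance = 1e-9)
})

test_that("average mesh size matches brute-force edge statistics", {
  expect_equal(average_mesh_size(box_lattice_hex_mesh(3)),
               c(mean = 1, sd = 0), tolerance = 1e-12)
  expect_equal(average_mesh_size(regular_tet_mesh()),
               c(mean = 1, sd = 0), tolerance = 1e-12)
  set.seed(9)
  m <- random_small_tet_mesh(10L)
  lens <- unlist(lapply(seq_len(n_elements(m)), function(i) {
    tt <- m$elements[i, ]
    apply(utils::combn(tt, 2L), 2L, function(p) {
      sqrt(sum((m$nodes[p[1L], ] - m$nodes[p[2L], ])^2))
    })
  }))
  expect_equal(average_mesh_size(m),
               c(mean = mean(lens), sd = stats::sd(lens)),
               tolerance = 1e-12)
})

test_that("quality report summarizes a cube lattice correctly", {
  rep <- quality_report(box_lattice_hex_mesh(3))
  expect_equal(rep$summary$n_elements, 27L)
  expect_equal(rep$summary$min_jacobian, 1.0)
  expect_equal(rep$summary$pct_aspect_below_cutoff, 100)
  expect_equal(rep$summary$pct_pass_max_angle, 100)
  # summary is recomputable from the per-element records
  expect_equal(rep$summary$pct_aspect_below_cutoff,
               100 * mean(rep$elements$aspect_ratio <
                            rep$thresholds$aspect_report_cutoff))
  expect_equal(rep$summary$min_jacobian,
               min(rep$elements$scaled_jacobian))
  path <- withr::local_tempfile(fileext = ".csv")
  write_quality_csv(rep, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 27L)
  expect_equal(back$scaled_jacobian, rep$elements$scaled_jacobian)
})

test_that("converted regular tet passes the hex Jacobian threshold", {
  res <- convert_tet_to_hex(regular_tet_mesh())
  rep <- quality_report(res$hex_mesh)
  expect_gt(rep$summary$min_jacobian, 0.4)
  expect_equal(rep$summary$pct_pass_jacobian, 100)
})

test_that("thresholds round trip through YAML", {
  th <- quality_thresholds(aspect_ratio_max = 5, max_angle_deg = 150)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_thresholds_yaml(th, path)
  back <- read_thresholds_yaml(path)
  expect_equal(unclass(back), unclass(th))
  expect_error(quality_thresholds(max_angle_deg = 200), "is not TRUE")
})
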