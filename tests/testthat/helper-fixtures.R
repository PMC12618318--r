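# Fixtures and independent oracles built in code.

single_tet <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1L))
}

two_tets <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1, 1, 1)),
           rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L)))
}

unit_cube_hex <- function() {
  hex_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                 c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)),
           matrix(1:8, 1L))
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9L), 3L)
  qr_d <- qr(m)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

rigid_transform_mesh <- function(mesh, R, tvec) {
  mesh$nodes <- sweep(mesh$nodes %*% t(R), 2L, tvec, "+")
  mesh
}

# Random small sub-mesh of a lattice sphere: sample tets, renumber nodes.
random_small_tet_mesh <- function(n_tets = 30L) {
  base <- sphere_tet_mesh(6, 2)
  ids <- sort(sample.int(n_elements(base), min(n_tets, n_elements(base))))
  el <- base$elements[ids, , drop = FALSE]
  used <- sort.int(unique(as.vector(el)))
  el2 <- matrix(match(el, used), ncol = 4L)
  tet_mesh(base$nodes[used, , drop = FALSE], el2)
}

# Brute-force unique-edge / unique-face counter (independent of the
# package's canonical-key machinery).
brute_edges_faces <- function(el) {
  edges <- NULL
  faces <- NULL
  for (i in seq_len(nrow(el))) {
    tt <- el[i, ]
    edges <- rbind(edges, t(apply(t(utils::combn(tt, 2L)), 1L, sort)))
    faces <- rbind(faces, t(apply(t(utils::combn(tt, 3L)), 1L, sort)))
  }
  list(n_edges = nrow(unique(as.data.frame(edges))),
       n_faces = nrow(unique(as.data.frame(faces))))
}

crossprod_vec <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Interior angles of a planar/spatial quad, written independently of the
# package's angle code.
oracle_quad_angles <- function(q) {
  vapply(1:4, function(i) {
    u <- q[if (i == 1L) 4L else i - 1L, ] - q[i, ]
    w <- q[if (i == 4L) 1L else i + 1L, ] - q[i, ]
    acos(max(min(sum(u * w) / sqrt(sum(u^2) * sum(w^2)), 1), -1)) * 180 / pi
  }, numeric(1L))
}

# Icosphere surface (subdivided icosahedron, vertices projected onto the
# sphere), used as a smooth closed-surface fixture.
icosphere <- function(radius = 1, subdivisions = 2L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    f2 <- matrix(NA_integer_, 0L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c0 <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c0); ca <- midpoint(c0, a)
      f2 <- rbind(f2, c(a, ab, ca), c(b, bc, ab), c(c0, ca, bc),
                  c(ab, bc, ca))
    }
    f <- f2
  }
  surface_mesh(v * radius, f, part_label = "icosphere")
}
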