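# Tetrahedral-to-hexahedral conversion: each 4-node tetrahedron is cut
# into four 8-node hexahedra through its 6 edge midpoints, 4 face
# centroids and the element centroid. Inserted nodes on shared edges and
# faces are deduplicated through canonical sorted-id keys, so adjacent
# elements stay conformal. A face-corner angle constraint (140 degrees by
# default) is then enforced by geometry-preserving constrained Laplacian
# smoothing of the inserted nodes; residual violators are flagged, never
# deleted.

# For base vertex v of tet (1,2,3,4), the other three vertices in an
# orientation-preserving (even permutation) order.
TET_VERTEX_ORDERS <- rbind(c(2L, 3L, 4L),
                           c(1L, 4L, 3L),
                           c(4L, 1L, 2L),
                           c(3L, 2L, 1L))

# column of TET_EDGES holding the (sorted) pair (i, j)
tet_edge_col <- local({
  m <- matrix(NA_integer_, 4L, 4L)
  for (e in seq_len(nrow(TET_EDGES))) {
    m[TET_EDGES[e, 1L], TET_EDGES[e, 2L]] <- e
    m[TET_EDGES[e, 2L], TET_EDGES[e, 1L]] <- e
  }
  m
})

#' Conversion configuration
#'
#' @param max_angle_deg largest admissible hexahedral face-corner angle in
#'   degrees (default 140).
#' @param smoothing_iterations maximum constrained-smoothing sweeps used to
#'   enforce the angle constraint (default 10; 0 disables smoothing).
#' @param smoothing_relaxation under-relaxation factor in (0, 1] applied to
#'   each node displacement (default 0.5).
#' @param preserve_boundary keep the input boundary geometry fixed: original
#'   vertices never move, boundary edge midpoints may only slide along their
#'   edge, boundary face centroids only within their face plane
#'   (default `TRUE`).
#' @return a `conversion_config` list.
#' @export
conversion_config <- function(max_angle_deg = 140,
                              smoothing_iterations = 10L,
                              smoothing_relaxation = 0.5,
                              preserve_boundary = TRUE) {
  stopifnot(max_angle_deg > 0, max_angle_deg < 180,
            smoothing_iterations >= 0,
            smoothing_relaxation > 0, smoothing_relaxation <= 1)
  structure(list(max_angle_deg = max_angle_deg,
                 smoothing_iterations = as.integer(smoothing_iterations),
                 smoothing_relaxation = smoothing_relaxation,
                 preserve_boundary = isTRUE(preserve_boundary)),
            class = "conversion_config")
}

#' Convert a tetrahedral mesh to an all-hexahedral mesh
#'
#' Replaces every tetrahedron by four hexahedra. For each tet the 6 edge
#' midpoints, the 4 face centroids (vertex averages) and the element
#' centroid are inserted; the hex based at vertex `V1` has node cycle
#' `(V1, M12, F123, M13 | M14, F124, C, F134)` (bottom quad then top quad)
#' and the other three follow by vertex symmetry. Midpoints and centroids
#' on shared edges/faces are shared between neighbouring elements. After
#' construction the face-corner angle constraint is enforced with
#' [enforce_angle_constraint()] unless `smoothing_iterations` is 0 and any
#' residual violators are listed in `flagged_elements`.
#'
#' @param mesh a `tet_mesh`.
#' @param config a [conversion_config()].
#' @return a `tet2hex_result` with fields `hex_mesh`, `node_provenance`
#'   (data frame: `node_id`, `kind` in vertex / edge_midpoint /
#'   face_centroid / element_centroid, `key`), `boundary_quads` (a
#'   `surface_mesh`, three quads per input boundary triangle),
#'   `flagged_elements` (hex ids whose maximum face-corner angle still
#'   exceeds `max_angle_deg`) and `stats`.
#' @export
#' @examples
#' tet <- regular_tet_mesh()
#' res <- convert_tet_to_hex(tet)
#' res$stats$n_hex
convert_tet_to_hex <- function(mesh, config = conversion_config()) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(config, "conversion_config"))
  el <- mesh$elements
  if (nrow(el) == 0L) stop("cannot convert an empty mesh")
  vol <- tet_signed_volumes(mesh$nodes, el)
  degen <- which(abs(vol) < 1e-12)
  if (length(degen) > 0L) {
    stop("degenerate tetrahedra (|volume| < 1e-12 mm^3): element(s) ",
         toString(utils::head(degen, 5L)))
  }
  dupkey <- paste(sprintf("%.12g", mesh$nodes[, 1L]),
                  sprintf("%.12g", mesh$nodes[, 2L]),
                  sprintf("%.12g", mesh$nodes[, 3L]))
  if (anyDuplicated(dupkey)) {
    warning("input mesh has ", sum(duplicated(dupkey)),
            " duplicate node coordinate(s) under different ids; ",
            "the conversion will not merge them")
  }

  nv <- nrow(mesh$nodes)
  nt <- nrow(el)
  ef <- enumerate_edges_faces(mesh)
  edges <- ef$edges
  faces <- ef$faces
  ne <- nrow(edges)
  nf <- nrow(faces)
  n_out <- nv + ne + nf + nt

  nodes <- rbind(mesh$nodes,
                 (mesh$nodes[edges[, 1L], , drop = FALSE] +
                  mesh$nodes[edges[, 2L], , drop = FALSE]) / 2,
                 (mesh$nodes[faces[, 1L], , drop = FALSE] +
                  mesh$nodes[faces[, 2L], , drop = FALSE] +
                  mesh$nodes[faces[, 3L], , drop = FALSE]) / 3,
                 element_centroids(mesh))

  # per-tet lookup of inserted node ids
  n_ids <- nrow(mesh$nodes)
  ekeys <- edge_key(edges[, 1L], edges[, 2L], n_ids)
  fkeys <- face_key(faces[, 1L], faces[, 2L], faces[, 3L])
  mid_id <- matrix(NA_integer_, nt, 6L)    # column = TET_EDGES row
  for (e in 1:6) {
    k <- edge_key(el[, TET_EDGES[e, 1L]], el[, TET_EDGES[e, 2L]], n_ids)
    mid_id[, e] <- nv + match(k, ekeys)
  }
  fac_id <- matrix(NA_integer_, nt, 4L)    # column v = face opposite v
  for (v in 1:4) {
    oth <- setdiff(1:4, v)
    k <- face_key(el[, oth[1L]], el[, oth[2L]], el[, oth[3L]])
    fac_id[, v] <- nv + ne + match(k, fkeys)
  }
  cen_id <- nv + ne + nf + seq_len(nt)

  hexes <- matrix(NA_integer_, nt * 4L, 8L)
  for (v in 1:4) {
    o <- TET_VERTEX_ORDERS[v, ]
    rows <- seq.int(v, by = 4L, length.out = nt)  # tet-major, vertex sub-order
    hexes[rows, ] <- cbind(el[, v],
                           mid_id[, tet_edge_col[v, o[1L]]],
                           fac_id[, o[3L]],
                           mid_id[, tet_edge_col[v, o[2L]]],
                           mid_id[, tet_edge_col[v, o[3L]]],
                           fac_id[, o[2L]],
                           cen_id,
                           fac_id[, o[1L]])
  }
  hex <- hex_mesh(nodes, hexes, part_label = mesh$part_label)

  provenance <- data.frame(
    node_id = seq_len(n_out),
    kind = rep(c("vertex", "edge_midpoint", "face_centroid",
                 "element_centroid"), c(nv, ne, nf, nt)),
    key = c(as.character(seq_len(nv)),
            paste(edges[, 1L], edges[, 2L], sep = ":"),
            paste(faces[, 1L], faces[, 2L], faces[, 3L], sep = ":"),
            as.character(seq_len(nt))),
    stringsAsFactors = FALSE)

  # boundary quads: 3 per boundary triangle of the input mesh
  btri <- boundary_surface(mesh)$faces
  bquads <- NULL
  if (nrow(btri) > 0L) {
    fmatch <- nv + ne + match(face_key(btri[, 1L], btri[, 2L], btri[, 3L]),
                              fkeys)
    quads <- vector("list", 3L)
    for (v in 1:3) {
      a <- btri[, v]
      b <- btri[, if (v == 3L) 1L else v + 1L]
      c <- btri[, if (v == 1L) 3L else v - 1L]
      quads[[v]] <- cbind(a, nv + match(edge_key(a, b, n_ids), ekeys),
                          fmatch, nv + match(edge_key(c, a, n_ids), ekeys))
    }
    bquads <- do.call(rbind, quads)
    # interleave: triangle-major, vertex sub-order
    bquads <- bquads[as.vector(t(matrix(seq_len(nrow(bquads)),
                                        nrow(btri), 3L))), , drop = FALSE]
  } else {
    bquads <- matrix(integer(), 0L, 4L)
  }
  boundary_quads <- surface_mesh(nodes, bquads,
                                 part_label = mesh$part_label)

  res <- structure(list(
    hex_mesh = hex,
    node_provenance = provenance,
    boundary_quads = boundary_quads,
    flagged_elements = integer(),
    stats = list(n_tet_in = nt, n_hex = nrow(hexes),
                 n_inserted = c(edge_midpoint = ne, face_centroid = nf,
                                element_centroid = nt),
                 n_boundary_tris = nrow(btri),
                 smoothing_iterations = 0L,
                 volume_in = sum(vol), volume_out = sum(element_volumes(hex)),
                 volume_drift = 0),
    config = config,
    geom = list(nv = nv, ne = ne, nf = nf, nt = nt,
                edges = edges, faces = faces, boundary_tris = btri)),
    class = "tet2hex_result")

  if (config$smoothing_iterations > 0L) {
    res <- enforce_angle_constraint(res, config)
  } else {
    ang <- hex_max_corner_angles(hex$nodes, hex$elements)
    res$flagged_elements <- which(ang > config$max_angle_deg)
    res$stats$max_angle <- max(ang)
  }
  res
}

#' @export
print.tet2hex_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<tet2hex_result> %d tets -> %d hexes (%d nodes)\n",
              s$n_tet_in, s$n_hex, nrow(x$hex_mesh$nodes)))
  cat(sprintf("  inserted nodes: %d edge midpoints, %d face centroids, %d element centroids\n",
              s$n_inserted[["edge_midpoint"]],
              s$n_inserted[["face_centroid"]],
              s$n_inserted[["element_centroid"]]))
  cat(sprintf("  smoothing: %d iteration(s), volume drift %.3g%%\n",
              s$smoothing_iterations, 100 * s$volume_drift))
  cat(sprintf("  max face-corner angle %.2f deg, %d flagged element(s)\n",
              s$max_angle, length(x$flagged_elements)))
  invisible(x)
}

# Maximum face-corner angle (degrees) per hex, over the 24 corners of the
# 6 (possibly non-planar) faces; each corner angle is the 3D angle between
# the two edge vectors meeting there.
hex_max_corner_angles <- function(nodes, elements) {
  m <- nrow(elements)
  min_cos <- rep(1, m)
  for (f in seq_len(nrow(HEX_FACES))) {
    idx <- HEX_FACES[f, ]
    p <- lapply(1:4, function(i) nodes[elements[, idx[i]], , drop = FALSE])
    for (c0 in 1:4) {
      u <- p[[if (c0 == 1L) 4L else c0 - 1L]] - p[[c0]]
      w <- p[[if (c0 == 4L) 1L else c0 + 1L]] - p[[c0]]
      cosang <- vdot(u, w) / pmax(vnorm(u) * vnorm(w), .Machine$double.xmin)
      min_cos <- pmin(min_cos, cosang)
    }
  }
  acos(pmax(pmin(min_cos, 1), -1)) * 180 / pi
}

#' Enforce the hexahedral face-corner angle constraint
#'
#' Angle-driven constrained repositioning of the inserted nodes. In each
#' sweep every face corner whose angle exceeds `max_angle_deg` pushes its
#' apex node along the negative bisector of the two edge vectors meeting
#' there, with a step proportional to the violation and to the local edge
#' length, scaled by `smoothing_relaxation`. Node motion is constrained so
#' the conversion geometry is preserved (the default,
#' `preserve_boundary = TRUE`): original vertices never move, edge
#' midpoints may only slide along their (straight) parent edge, face
#' points only within their parent face plane, and element centroids move
#' freely. Under these constraints the three quads of every original
#' triangular face keep tiling that face, so the input boundary and the
#' per-tet partition (hence the total volume) are preserved exactly. With
#' `preserve_boundary = FALSE` all inserted nodes move unconstrained.
#' Iteration stops as soon as every face-corner angle is at most
#' `max_angle_deg` or the iteration budget is exhausted; any hex still
#' violating the bound is recorded in `flagged_elements` (elements are
#' never deleted). The relative volume change is reported in
#' `stats$volume_drift`.
#'
#' @param result a `tet2hex_result` from [convert_tet_to_hex()].
#' @param config a [conversion_config()]; defaults to the one stored in
#'   `result`.
#' @return the updated `tet2hex_result`.
#' @export
enforce_angle_constraint <- function(result, config = result$config) {
  stopifnot(inherits(result, "tet2hex_result"))
  hex <- result$hex_mesh
  nodes <- hex$nodes
  el <- hex$elements
  g <- result$geom
  vol0 <- result$stats$volume_in

  # per-node constraint data (from the fixed original vertices)
  vnodes <- nodes[seq_len(g$nv), , drop = FALSE]
  edge_dir <- vnodes[g$edges[, 2L], , drop = FALSE] -
    vnodes[g$edges[, 1L], , drop = FALSE]
  edge_dir <- edge_dir / pmax(vnorm(edge_dir), .Machine$double.xmin)
  p1 <- vnodes[g$faces[, 1L], , drop = FALSE]
  face_nrm <- vcross(vnodes[g$faces[, 2L], , drop = FALSE] - p1,
                     vnodes[g$faces[, 3L], , drop = FALSE] - p1)
  face_nrm <- face_nrm / pmax(vnorm(face_nrm), .Machine$double.xmin)
  is_edge_node <- function(id) id > g$nv & id <= g$nv + g$ne
  is_face_node <- function(id) id > g$nv + g$ne & id <= g$nv + g$ne + g$nf

  # aim slightly below the bound so repaired corners keep a margin
  target <- config$max_angle_deg - 2
  cos_bound <- cos(config$max_angle_deg * pi / 180)

  ang <- hex_max_corner_angles(nodes, el)
  iters_used <- 0L
  for (it in seq_len(config$smoothing_iterations)) {
    if (max(ang) <= config$max_angle_deg) break
    ids <- integer(); dsp <- NULL
    for (f in seq_len(nrow(HEX_FACES))) {
      idx <- HEX_FACES[f, ]
      p <- lapply(1:4, function(i) nodes[el[, idx[i]], , drop = FALSE])
      for (c0 in 1:4) {
        u <- p[[if (c0 == 1L) 4L else c0 - 1L]] - p[[c0]]
        w <- p[[if (c0 == 4L) 1L else c0 + 1L]] - p[[c0]]
        lu <- vnorm(u); lw <- vnorm(w)
        cosang <- vdot(u, w) / pmax(lu * lw, .Machine$double.xmin)
        bad <- which(cosang < cos_bound)
        if (length(bad) == 0L) next
        node <- el[bad, idx[c0]]
        keepm <- node > g$nv          # only inserted nodes move
        bad <- bad[keepm]; node <- node[keepm]
        if (length(bad) == 0L) next
        bis <- u[bad, , drop = FALSE] / lu[bad] +
          w[bad, , drop = FALSE] / lw[bad]
        bl <- vnorm(bis)
        ok <- bl > 1e-12
        bad <- bad[ok]; node <- node[ok]
        if (length(bad) == 0L) next
        bis <- bis[ok, , drop = FALSE] / bl[ok]
        theta <- acos(pmax(pmin(cosang[bad], 1), -1)) * 180 / pi
        step <- config$smoothing_relaxation *
          0.5 * (lu[bad] + lw[bad]) * (theta - target) / 180
        ids <- c(ids, node)
        dsp <- rbind(dsp, -step * bis)
      }
    }
    if (length(ids) == 0L) break
    disp_sum <- rowsum(dsp, ids, reorder = TRUE)
    who <- sort.int(unique(ids))
    cnt <- tabulate(ids, nrow(nodes))[who]
    disp <- disp_sum / cnt
    if (config$preserve_boundary) {
      em <- is_edge_node(who)
      if (any(em)) {
        d0 <- edge_dir[who[em] - g$nv, , drop = FALSE]
        disp[em, ] <- vdot(disp[em, , drop = FALSE], d0) * d0
      }
      fm <- is_face_node(who)
      if (any(fm)) {
        n0 <- face_nrm[who[fm] - g$nv - g$ne, , drop = FALSE]
        disp[fm, ] <- disp[fm, , drop = FALSE] -
          vdot(disp[fm, , drop = FALSE], n0) * n0
      }
    }
    nodes[who, ] <- nodes[who, , drop = FALSE] + disp
    ang <- hex_max_corner_angles(nodes, el)
    iters_used <- it
  }

  hex$nodes <- nodes
  result$hex_mesh <- hex
  result$boundary_quads$nodes <- nodes
  vol1 <- sum(element_volumes(hex))
  result$stats$smoothing_iterations <- iters_used
  result$stats$volume_out <- vol1
  result$stats$volume_drift <- abs(vol1 - vol0) / abs(vol0)
  result$stats$max_angle <- max(ang)
  result$flagged_elements <- which(ang > config$max_angle_deg)
  result
}

#' Split a triangle into three quadrilaterals
#'
#' Connects the triangle's edge midpoints to its centroid, yielding one
#' quadrilateral per vertex with node cycle (vertex, adjacent edge
#' midpoint, centroid, other adjacent edge midpoint). The three quads tile
#' the triangle exactly. For an equilateral triangle each quad has interior
#' angles 120 (centroid), 90 (midpoint), 60 (vertex), 90 (midpoint)
#' degrees.
#'
#' @param tri 3 x 3 matrix of triangle vertex coordinates (rows).
#' @return list of three 4 x 3 quad coordinate matrices, each with a
#'   `provenance` attribute naming the corner roles (cycle order `vertex`,
#'   `midpoint`, `centroid`, `midpoint`).
#' @export
subdivide_triangle <- function(tri) {
  tri <- as.matrix(tri)
  stopifnot(nrow(tri) == 3L, ncol(tri) %in% c(2L, 3L))
  if (ncol(tri) == 2L) tri <- cbind(tri, 0)
  area2 <- vnorm(vcross(matrix(tri[2L, ] - tri[1L, ], 1L),
                        matrix(tri[3L, ] - tri[1L, ], 1L)))
  scale <- max(vnorm(rbind(tri[2L, ] - tri[1L, ], tri[3L, ] - tri[1L, ])))
  if (area2 <= 1e-12 * scale^2) stop("degenerate (collinear) triangle")
  cen <- colMeans(tri)
  mids <- (tri + tri[c(2L, 3L, 1L), ]) / 2   # row i = midpoint of edge i,i+1
  lapply(1:3, function(v) {
    prv <- if (v == 1L) 3L else v - 1L
    q <- rbind(tri[v, ], mids[v, ], cen, mids[prv, ])
    rownames(q) <- NULL
    attr(q, "provenance") <- c("vertex", "midpoint", "centroid", "midpoint")
    q
  })
}

#' Predict the quadrilateral angles produced by triangle subdivision
#'
#' Given the three interior angles of a triangle, constructs a
#' representative triangle, applies [subdivide_triangle()] and measures the
#' interior angles of each resulting quad. Used as a pre-conversion screen
#' for faces that would produce distorted quads.
#'
#' @param angles_deg numeric length-3, positive, summing to 180.
#' @return 3 x 4 matrix: one row per quad (ordered by triangle vertex),
#'   columns in cycle order `vertex`, `midpoint`, `centroid`, `midpoint`.
#' @export
#' @examples
#' predict_quad_angles(c(60, 60, 60))   # 60, 90, 120, 90 for each quad
predict_quad_angles <- function(angles_deg) {
  stopifnot(length(angles_deg) == 3L, all(angles_deg > 0))
  if (abs(sum(angles_deg) - 180) > 1e-9) {
    stop("triangle angles must sum to 180 degrees")
  }
  a <- angles_deg * pi / 180
  # unit side AB; C by law of sines
  b_len <- sin(a[2L]) / sin(a[3L])
  tri <- rbind(c(0, 0, 0), c(1, 0, 0),
               c(b_len * cos(a[1L]), b_len * sin(a[1L]), 0))
  quads <- subdivide_triangle(tri)
  out <- t(vapply(quads, quad_interior_angles, numeric(4L)))
  colnames(out) <- c("vertex", "midpoint", "centroid", "midpoint")
  out
}

quad_interior_angles <- function(q) {
  vapply(1:4, function(c0) {
    u <- q[if (c0 == 1L) 4L else c0 - 1L, ] - q[c0, ]
    w <- q[if (c0 == 4L) 1L else c0 + 1L, ] - q[c0, ]
    cr <- c(u[2L] * w[3L] - u[3L] * w[2L],
            u[3L] * w[1L] - u[1L] * w[3L],
            u[1L] * w[2L] - u[2L] * w[1L])
    atan2(sqrt(sum(cr^2)), sum(u * w)) * 180 / pi
  }, numeric(1L))
}
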