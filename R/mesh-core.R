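# Mesh data model: node coordinate matrices plus element connectivity.
# Units are millimetres throughout; node ids are contiguous 1-based row
# indices into the node matrix, with original file ids kept in `orig_id`.

#' Construct a tetrahedral volume mesh
#'
#' A `tet_mesh` holds node coordinates (millimetres) and 4-node element
#' connectivity. On construction every element is checked against the node
#' table and negatively oriented tetrahedra are reordered (last two nodes
#' swapped) so that all signed volumes are positive.
#'
#' @param nodes numeric matrix, one row per node, columns x, y, z (mm).
#' @param elements integer matrix, one row per element, 4 node ids per row.
#' @param part_label part name carried through file export.
#' @param orig_id optional vector of original (file) node ids, one per node.
#' @return an object of class `c("tet_mesh", "fe_mesh")`.
#' @export
#' @examples
#' m <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'               matrix(1:4, 1))
#' mesh_volume(m)
tet_mesh <- function(nodes, elements, part_label = "part", orig_id = NULL) {
  m <- new_mesh(nodes, elements, 4L, part_label, orig_id,
                class = c("tet_mesh", "fe_mesh"))
  v <- tet_signed_volumes(m$nodes, m$elements)
  neg <- v < 0
  if (any(neg)) m$elements[neg, c(3L, 4L)] <- m$elements[neg, c(4L, 3L)]
  m
}

#' Construct a hexahedral volume mesh
#'
#' Elements use the standard 8-node brick ordering: bottom quad
#' counter-clockwise (nodes 1-4), then the top quad (nodes 5-8) with node 5
#' above node 1. If the mean corner Jacobian of an element is negative the
#' bottom and top quads are swapped on construction.
#'
#' @inheritParams tet_mesh
#' @param elements integer matrix, 8 node ids per row.
#' @return an object of class `c("hex_mesh", "fe_mesh")`.
#' @export
hex_mesh <- function(nodes, elements, part_label = "part", orig_id = NULL) {
  m <- new_mesh(nodes, elements, 8L, part_label, orig_id,
                class = c("hex_mesh", "fe_mesh"))
  sj <- hex_corner_jacobians(m$nodes, m$elements)
  neg <- rowMeans(sj) < 0
  if (any(neg)) m$elements[neg, ] <- m$elements[neg, c(5:8, 1:4), drop = FALSE]
  m
}

#' Construct a triangulated or quadrilateral surface mesh
#'
#' @inheritParams tet_mesh
#' @param faces integer matrix with 3 (triangles) or 4 (quads) node ids per
#'   row; a mesh is homogeneous in face kind.
#' @return an object of class `c("surface_mesh", "fe_mesh")`.
#' @export
surface_mesh <- function(nodes, faces, part_label = "part", orig_id = NULL) {
  k <- ncol(as.matrix(faces))
  if (!k %in% c(3L, 4L)) {
    stop("surface faces must have 3 or 4 nodes, got ", k)
  }
  m <- new_mesh(nodes, faces, k, part_label, orig_id,
                class = c("surface_mesh", "fe_mesh"))
  names(m)[names(m) == "elements"] <- "faces"
  m$face_kind <- if (k == 3L) "triangle" else "quad"
  m
}

#' Construct a beam element set (muscles or ligaments)
#'
#' Two-node line elements referencing a node table held elsewhere (typically
#' the volume mesh they attach to). Used to represent Hill-type muscle lines
#' of action and linear-spring ligaments.
#'
#' @param elements integer matrix with 2 distinct node ids per row.
#' @param kind `"muscle"` or `"ligament"`.
#' @param property_ref identifier into a material parameter registry.
#' @return an object of class `"beam_set"`.
#' @export
beam_set <- function(elements, kind = c("muscle", "ligament"),
                     property_ref = NULL) {
  kind <- match.arg(kind)
  elements <- as_element_matrix(elements, 2L)
  if (any(elements[, 1L] == elements[, 2L])) {
    stop("beam elements must reference two distinct nodes")
  }
  structure(list(elements = elements, kind = kind,
                 property_ref = property_ref),
            class = "beam_set")
}

new_mesh <- function(nodes, elements, width, part_label, orig_id, class) {
  nodes <- as.matrix(nodes)
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 coordinate matrix")
  storage.mode(nodes) <- "double"
  if (!all(is.finite(nodes))) stop("node coordinates must be finite")
  dimnames(nodes) <- list(NULL, c("x", "y", "z"))
  elements <- as_element_matrix(elements, width)
  if (nrow(elements) > 0L &&
      (min(elements) < 1L || max(elements) > nrow(nodes))) {
    stop("element connectivity references node ids outside 1..", nrow(nodes))
  }
  if (is.null(orig_id)) orig_id <- seq_len(nrow(nodes))
  if (anyDuplicated(orig_id)) stop("original node ids must be unique")
  structure(list(nodes = nodes, elements = elements,
                 part_label = as.character(part_label)[1L],
                 orig_id = orig_id),
            class = class)
}

as_element_matrix <- function(elements, width) {
  elements <- as.matrix(elements)
  if (nrow(elements) == 0L) {
    return(matrix(integer(), 0L, width))
  }
  if (ncol(elements) != width) {
    stop("elements must have ", width, " nodes per row, got ", ncol(elements))
  }
  storage.mode(elements) <- "integer"
  dimnames(elements) <- NULL
  elements
}

#' @export
print.fe_mesh <- function(x, ...) {
  kind <- class(x)[1L]
  elem <- if (kind == "surface_mesh") x$faces else x$elements
  cat(sprintf("<%s> part '%s': %d nodes, %d elements\n",
              kind, x$part_label, nrow(x$nodes), nrow(elem)))
  if (kind == "surface_mesh") cat("  face kind:", x$face_kind, "\n")
  invisible(x)
}

#' @export
print.beam_set <- function(x, ...) {
  cat(sprintf("<beam_set> %d %s beam elements\n", nrow(x$elements), x$kind))
  invisible(x)
}

#' Number of nodes / elements in a mesh
#' @param mesh a `tet_mesh`, `hex_mesh` or `surface_mesh`.
#' @return integer count.
#' @export
n_nodes <- function(mesh) nrow(mesh$nodes)

#' @rdname n_nodes
#' @export
n_elements <- function(mesh) {
  nrow(if (inherits(mesh, "surface_mesh")) mesh$faces else mesh$elements)
}

#' Element connectivity accessor
#' @param mesh a mesh object.
#' @return integer connectivity matrix (faces for a surface mesh).
#' @export
mesh_elements <- function(mesh) {
  if (inherits(mesh, "surface_mesh")) mesh$faces else mesh$elements
}

#' Node coordinate accessor
#' @param mesh a mesh object.
#' @return numeric n x 3 matrix of coordinates in mm.
#' @export
mesh_nodes <- function(mesh) mesh$nodes

# ---- geometry helpers --------------------------------------------------

vcross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

vdot <- function(a, b) rowSums(a * b)

vnorm <- function(a) sqrt(rowSums(a * a))

det3 <- function(a, b, c) {
  a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) -
  a[, 2L] * (b[, 1L] * c[, 3L] - b[, 3L] * c[, 1L]) +
  a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])
}

tet_signed_volumes <- function(nodes, elements) {
  p0 <- nodes[elements[, 1L], , drop = FALSE]
  det3(nodes[elements[, 2L], , drop = FALSE] - p0,
       nodes[elements[, 3L], , drop = FALSE] - p0,
       nodes[elements[, 4L], , drop = FALSE] - p0) / 6
}

# Hex faces in local corner indices, outward-oriented for the standard
# brick ordering (bottom 1-4 CCW seen from above, top 5-8).
HEX_FACES <- rbind(c(1L, 4L, 3L, 2L),   # bottom, normal -z
                   c(5L, 6L, 7L, 8L),   # top, normal +z
                   c(1L, 2L, 6L, 5L),
                   c(2L, 3L, 7L, 6L),
                   c(3L, 4L, 8L, 7L),
                   c(4L, 1L, 5L, 8L))

# Outward faces of a positively oriented tet (1,2,3,4).
TET_FACES <- rbind(c(1L, 3L, 2L),
                   c(1L, 2L, 4L),
                   c(2L, 3L, 4L),
                   c(1L, 4L, 3L))

# Corner triples (neighbour local indices) whose edge-vector determinant is
# +1 on the unit cube; used for corner Jacobians.
HEX_CORNER_NEIGHBOURS <- rbind(c(2L, 4L, 5L), c(3L, 1L, 6L), c(4L, 2L, 7L),
                               c(1L, 3L, 8L), c(8L, 6L, 1L), c(5L, 7L, 2L),
                               c(6L, 8L, 3L), c(7L, 5L, 4L))

HEX_EDGES <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L),
                   c(5L, 6L), c(6L, 7L), c(7L, 8L), c(8L, 5L),
                   c(1L, 5L), c(2L, 6L), c(3L, 7L), c(4L, 8L))

TET_EDGES <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                   c(2L, 3L), c(2L, 4L), c(3L, 4L))

# Raw (unnormalized by edge length) corner determinants of each hex,
# returned as an m x 8 matrix. Sign tells orientation.
hex_corner_jacobians <- function(nodes, elements, scaled = FALSE) {
  m <- nrow(elements)
  out <- matrix(NA_real_, m, 8L)
  for (c0 in 1:8) {
    nb <- HEX_CORNER_NEIGHBOURS[c0, ]
    p <- nodes[elements[, c0], , drop = FALSE]
    e1 <- nodes[elements[, nb[1L]], , drop = FALSE] - p
    e2 <- nodes[elements[, nb[2L]], , drop = FALSE] - p
    e3 <- nodes[elements[, nb[3L]], , drop = FALSE] - p
    d <- det3(e1, e2, e3)
    if (scaled) {
      len <- vnorm(e1) * vnorm(e2) * vnorm(e3)
      d <- ifelse(len > 0, d / len, 0)
    }
    out[, c0] <- d
  }
  out
}

# ---- canonical edge / face enumeration --------------------------------

edge_key <- function(a, b, n) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  (as.numeric(lo) - 1) * n + as.numeric(hi)
}

face_key <- function(a, b, c) {
  lo <- pmin(a, b, c)
  hi <- pmax(a, b, c)
  mid <- as.numeric(a) + as.numeric(b) + as.numeric(c) -
    as.numeric(lo) - as.numeric(hi)
  paste(lo, mid, hi, sep = ":")
}

#' Enumerate the unique edges and triangular faces of a tetrahedral mesh
#'
#' Each undirected edge and each face appears exactly once under a
#' sorted-node-id canonical key, in order of first encounter (element order,
#' local edge/face order), which makes downstream id assignment
#' deterministic.
#'
#' @param mesh a `tet_mesh`.
#' @return list with `edges` (e x 2 integer matrix, sorted ids) and `faces`
#'   (f x 3 integer matrix, sorted ids).
#' @export
enumerate_edges_faces <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  el <- mesh$elements
  if (nrow(el) == 0L) {
    return(list(edges = matrix(integer(), 0L, 2L),
                faces = matrix(integer(), 0L, 3L)))
  }
  n <- nrow(mesh$nodes)
  ea <- el[, TET_EDGES[, 1L]]
  eb <- el[, TET_EDGES[, 2L]]
  dim(ea) <- NULL; dim(eb) <- NULL
  ek <- edge_key(ea, eb, n)
  keep <- !duplicated(ek)
  edges <- cbind(pmin(ea, eb)[keep], pmax(ea, eb)[keep])
  storage.mode(edges) <- "integer"

  fa <- el[, TET_FACES[, 1L]]
  fb <- el[, TET_FACES[, 2L]]
  fc <- el[, TET_FACES[, 3L]]
  dim(fa) <- NULL; dim(fb) <- NULL; dim(fc) <- NULL
  fk <- face_key(fa, fb, fc)
  keepf <- !duplicated(fk)
  f3 <- cbind(fa, fb, fc)[keepf, , drop = FALSE]
  f3 <- t(apply(f3, 1L, sort.int))
  if (nrow(f3) == 1L) dim(f3) <- c(1L, 3L)
  storage.mode(f3) <- "integer"
  list(edges = edges, faces = f3)
}

# ---- boundary extraction ----------------------------------------------

#' Extract the boundary surface of a volume mesh
#'
#' Returns the faces that belong to exactly one element, oriented outward
#' (consistent with the positively oriented parent elements).
#'
#' @param mesh a `tet_mesh` or `hex_mesh`.
#' @return a `surface_mesh` over the same node table (triangles for a tet
#'   mesh, quads for a hex mesh).
#' @export
boundary_surface <- function(mesh) {
  if (inherits(mesh, "tet_mesh")) {
    face_tbl <- TET_FACES
  } else if (inherits(mesh, "hex_mesh")) {
    face_tbl <- HEX_FACES
  } else {
    stop("boundary_surface needs a tet_mesh or hex_mesh")
  }
  el <- mesh$elements
  k <- ncol(face_tbl)
  # stack all element faces, element-major then local-face order
  cols <- lapply(seq_len(k), function(j) {
    m <- el[, face_tbl[, j], drop = FALSE]   # n_elem x n_faces
    as.vector(t(m))
  })
  faces <- do.call(cbind, cols)
  key <- canonical_face_key(faces)
  once <- !(key %in% key[duplicated(key)])
  boundary <- faces[once, , drop = FALSE]
  surface_mesh(mesh$nodes, boundary, part_label = mesh$part_label,
               orig_id = mesh$orig_id)
}

# Vectorized order-independent key for 3- or 4-node faces.
canonical_face_key <- function(faces) {
  if (ncol(faces) == 3L) {
    a <- faces[, 1L]; b <- faces[, 2L]; c <- faces[, 3L]
    lo <- pmin(a, b, c); hi <- pmax(a, b, c)
    paste(lo, a + b + c - lo - hi, hi, sep = ":")
  } else {
    a <- faces[, 1L]; b <- faces[, 2L]; c <- faces[, 3L]; d <- faces[, 4L]
    # 5-comparator sorting network for 4 values
    l1 <- pmin(a, b); h1 <- pmax(a, b)
    l2 <- pmin(c, d); h2 <- pmax(c, d)
    s1 <- pmin(l1, l2); m1 <- pmax(l1, l2)
    m2 <- pmin(h1, h2); s4 <- pmax(h1, h2)
    s2 <- pmin(m1, m2); s3 <- pmax(m1, m2)
    paste(s1, s2, s3, s4, sep = ":")
  }
}

# ---- volume ------------------------------------------------------------

#' Signed volumes of the elements of a volume mesh
#'
#' Tet volumes are corner determinants / 6. Hex volumes decompose the
#' element into 24 tetrahedra spanned by the element centroid, each face
#' centroid and each face edge, which is exact for the (possibly
#' non-planar-faced) trilinear hexahedron in the sense of the standard
#' divergence construction.
#'
#' @param mesh a `tet_mesh` or `hex_mesh`.
#' @return numeric vector of per-element signed volumes in cubic mm.
#' @export
element_volumes <- function(mesh) {
  nodes <- mesh$nodes
  el <- mesh$elements
  if (inherits(mesh, "tet_mesh")) {
    return(tet_signed_volumes(nodes, el))
  }
  if (!inherits(mesh, "hex_mesh")) {
    stop("element_volumes needs a tet_mesh or hex_mesh")
  }
  if (nrow(el) == 0L) return(numeric())
  cen <- element_centroids(mesh)
  vol <- numeric(nrow(el))
  for (f in seq_len(nrow(HEX_FACES))) {
    idx <- HEX_FACES[f, ]
    p <- lapply(1:4, function(i) nodes[el[, idx[i]], , drop = FALSE])
    fc <- (p[[1L]] + p[[2L]] + p[[3L]] + p[[4L]]) / 4
    for (e in 1:4) {
      a <- p[[e]]
      b <- p[[if (e == 4L) 1L else e + 1L]]
      vol <- vol + det3(a - cen, b - cen, fc - cen) / 6
    }
  }
  vol
}

element_centroids <- function(mesh) {
  el <- mesh_elements(mesh)
  nodes <- mesh$nodes
  out <- matrix(0, nrow(el), 3L)
  for (j in seq_len(ncol(el))) {
    out <- out + nodes[el[, j], , drop = FALSE]
  }
  out / ncol(el)
}

#' Total mesh volume
#'
#' Sum of signed element volumes. Inverted elements (negative volume)
#' trigger a warning naming the first offending element; their signed
#' contribution is kept.
#'
#' @param mesh a `tet_mesh` or `hex_mesh`.
#' @return total volume in cubic millimetres.
#' @export
mesh_volume <- function(mesh) {
  v <- element_volumes(mesh)
  if (any(v < 0)) {
    warning("mesh contains ", sum(v < 0), " inverted element(s), first id ",
            which(v < 0)[1L], "; signed contributions kept")
  }
  sum(v)
}

#' Divergence-theorem volume enclosed by a closed oriented surface
#'
#' Quadrilateral faces are fanned into triangles about their first node.
#' An inward-oriented surface gives the magnitude with a warning; an open
#' surface (edges used by only one face) is an error.
#'
#' @param surface a closed `surface_mesh`.
#' @param units `"mm3"` or `"cm3"` for the returned value.
#' @return enclosed volume.
#' @export
enclosed_volume <- function(surface, units = c("cm3", "mm3")) {
  stopifnot(inherits(surface, "surface_mesh"))
  units <- match.arg(units)
  faces <- surface$faces
  n <- nrow(surface$nodes)
  tri <- if (ncol(faces) == 3L) {
    faces
  } else {
    rbind(faces[, c(1L, 2L, 3L)], faces[, c(1L, 3L, 4L)])
  }
  # closedness: every undirected edge of the face set must be used twice
  ea <- c(faces[, 1L], faces[, 2L], faces[, 3L],
          if (ncol(faces) == 4L) faces[, 4L])
  eb <- c(faces[, 2L], faces[, 3L],
          if (ncol(faces) == 4L) faces[, 4L], faces[, 1L])
  ek <- edge_key(ea, eb, n)
  open_edges <- sum(table(ek) != 2L)
  if (open_edges > 0L) {
    stop("surface is not closed: ", open_edges,
         " boundary/non-manifold edge(s)")
  }
  v <- sum(det3(surface$nodes[tri[, 1L], , drop = FALSE],
                surface$nodes[tri[, 2L], , drop = FALSE],
                surface$nodes[tri[, 3L], , drop = FALSE])) / 6
  if (v < 0) {
    warning("surface is oriented inward; returning magnitude")
    v <- -v
  }
  if (units == "cm3") v / 1000 else v
}
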