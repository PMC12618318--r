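# Deterministic synthetic fixture generators: every input the other
# modules need can be generated in code, with a fixed seed where noise is
# involved, so the full analysis surface runs without any external data.

#' Unit regular tetrahedron mesh
#'
#' One tetrahedron with edge length `edge`, a convenient worked example for
#' the tet-to-hex conversion (its four hexahedra have a maximum face-corner
#' angle of 120 degrees and minimum scaled Jacobian sqrt(1/2)).
#'
#' @param edge edge length in mm.
#' @return a `tet_mesh` with one element.
#' @export
regular_tet_mesh <- function(edge = 1) {
  nodes <- edge * rbind(c(0, 0, 0),
                        c(1, 0, 0),
                        c(0.5, sqrt(3) / 2, 0),
                        c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  tet_mesh(nodes, matrix(1:4, 1L), part_label = "regular_tet")
}

# 6-tet (Kuhn) subdivision of the unit cube along vertex-order chains:
# for each permutation of the axes, the tet (origin, +axis1, +axis1+axis2,
# +axis1+axis2+axis3). Identical in every cell, so face diagonals agree
# across neighbouring cells and the lattice is conformal.
KUHN_PERMS <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

lattice_tet_template <- function() {
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  corner_id <- function(v) 1L + v[1L] + 2L * v[2L] + 4L * v[3L]
  tets <- matrix(NA_integer_, 6L, 4L)
  for (p in 1:6) {
    v <- c(0L, 0L, 0L)
    ids <- corner_id(v)
    for (ax in KUHN_PERMS[p, ]) {
      v[ax] <- 1L
      ids <- c(ids, corner_id(v))
    }
    tets[p, ] <- ids
  }
  list(corners = corners, tets = tets)
}

# Tetrahedralize the cells of a cubic lattice for which `keep_fun(centroid)`
# is TRUE. Nodes are shared across cells (conformal); tets are positively
# oriented by the tet_mesh constructor.
lattice_tet_mesh <- function(cell_edge, lower, upper, keep_fun,
                             part_label = "lattice") {
  tpl <- lattice_tet_template()
  nx <- max(1L, ceiling((upper[1L] - lower[1L]) / cell_edge))
  ny <- max(1L, ceiling((upper[2L] - lower[2L]) / cell_edge))
  nz <- max(1L, ceiling((upper[3L] - lower[3L]) / cell_edge))
  cells <- as.matrix(expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L),
                                 k = 0:(nz - 1L)))
  cen <- sweep(cells * cell_edge + cell_edge / 2, 2L, lower, "+")
  keep <- keep_fun(cen)
  if (!any(keep)) stop("no lattice cell satisfies the shape predicate; ",
                       "reduce cell_edge or enlarge the domain")
  cells <- cells[keep, , drop = FALSE]
  # global grid-point ids for the 8 corners of each kept cell
  gx <- nx + 1L; gy <- ny + 1L
  pid <- function(i, j, k) 1 + i + gx * (j + gy * k)
  corner_ids <- matrix(NA_real_, nrow(cells), 8L)
  for (c0 in 1:8) {
    off <- tpl$corners[c0, ]
    corner_ids[, c0] <- pid(cells[, 1L] + off[1L], cells[, 2L] + off[2L],
                            cells[, 3L] + off[3L])
  }
  used <- sort.int(unique(as.vector(corner_ids)))
  local_id <- match(corner_ids, used)
  dim(local_id) <- dim(corner_ids)
  k0 <- (used - 1) %/% (gx * gy)
  j0 <- ((used - 1) %% (gx * gy)) %/% gx
  i0 <- (used - 1) %% gx
  nodes <- cbind(lower[1L] + i0 * cell_edge,
                 lower[2L] + j0 * cell_edge,
                 lower[3L] + k0 * cell_edge)
  tets <- matrix(NA_integer_, nrow(cells) * 6L, 4L)
  for (t0 in 1:6) {
    rows <- seq.int(t0, by = 6L, length.out = nrow(cells))
    tets[rows, ] <- local_id[, tpl$tets[t0, ], drop = FALSE]
  }
  tet_mesh(nodes, tets, part_label = part_label)
}

#' Lattice-based tetrahedral sphere mesh
#'
#' Cubic lattice of cells with edge `cell_edge`, each cell split into six
#' tetrahedra by a fixed template; cells whose centroid lies inside the
#' sphere are retained. The mesh is conformal and positively oriented; its
#' staircase boundary approximates the sphere as `cell_edge` decreases.
#'
#' @param radius sphere radius, mm.
#' @param cell_edge lattice cell edge, mm; must be positive and smaller
#'   than `radius`.
#' @return a `tet_mesh`.
#' @export
#' @examples
#' m <- sphere_tet_mesh(10, 5)
#' mesh_volume(m)
sphere_tet_mesh <- function(radius, cell_edge) {
  stopifnot(cell_edge > 0, cell_edge < radius)
  lattice_tet_mesh(cell_edge, rep(-radius - cell_edge, 3L),
                   rep(radius + cell_edge, 3L),
                   function(cen) rowSums(cen^2) < radius^2,
                   part_label = "sphere")
}

#' Two-layer (core plus shell) tetrahedral mesh
#'
#' Same lattice construction as [sphere_tet_mesh()] up to `outer_radius`;
#' elements are labelled `"brain"` (centroid radius below `inner_radius`)
#' or `"csf"` (shell), emulating a soft core surrounded by a fluid layer.
#' Both labels index one shared conformal node table.
#'
#' @param inner_radius,outer_radius radii in mm, `inner_radius <
#'   outer_radius`.
#' @param cell_edge lattice cell edge, mm.
#' @return a `tet_mesh` with an extra `element_label` character vector
#'   (one entry per element).
#' @export
two_layer_tet_mesh <- function(inner_radius, outer_radius, cell_edge) {
  stopifnot(inner_radius > 0, inner_radius < outer_radius, cell_edge > 0)
  if (outer_radius - inner_radius < cell_edge) {
    warning("shell thinner than cell_edge; the shell layer may have gaps")
  }
  m <- lattice_tet_mesh(cell_edge, rep(-outer_radius - cell_edge, 3L),
                        rep(outer_radius + cell_edge, 3L),
                        function(cen) rowSums(cen^2) < outer_radius^2,
                        part_label = "two_layer")
  cen <- element_centroids(m)
  m$element_label <- ifelse(rowSums(cen^2) < inner_radius^2, "brain", "csf")
  m
}

#' Axis-aligned hexahedral box lattice
#'
#' `nx x ny x nz` unit-spacing hexahedra scaled by `spacing`, the reference
#' fixture for quality metrics (every element is a perfect cube).
#'
#' @param nx,ny,nz number of cells per axis.
#' @param spacing cell edge in mm.
#' @return a `hex_mesh`.
#' @export
box_lattice_hex_mesh <- function(nx = 3L, ny = nx, nz = nx, spacing = 1) {
  gx <- nx + 1L; gy <- ny + 1L; gz <- nz + 1L
  g <- as.matrix(expand.grid(i = 0:nx, j = 0:ny, k = 0:nz))
  nodes <- g * spacing
  pid <- function(i, j, k) 1L + i + gx * (j + gy * k)
  cells <- as.matrix(expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L),
                                 k = 0:(nz - 1L)))
  el <- cbind(pid(cells[, 1L], cells[, 2L], cells[, 3L]),
              pid(cells[, 1L] + 1L, cells[, 2L], cells[, 3L]),
              pid(cells[, 1L] + 1L, cells[, 2L] + 1L, cells[, 3L]),
              pid(cells[, 1L], cells[, 2L] + 1L, cells[, 3L]),
              pid(cells[, 1L], cells[, 2L], cells[, 3L] + 1L),
              pid(cells[, 1L] + 1L, cells[, 2L], cells[, 3L] + 1L),
              pid(cells[, 1L] + 1L, cells[, 2L] + 1L, cells[, 3L] + 1L),
              pid(cells[, 1L], cells[, 2L] + 1L, cells[, 3L] + 1L))
  hex_mesh(nodes, el, part_label = "box_lattice")
}

#' Parametric vertebra point cloud with ground-truth landmarks
#'
#' Generates a box-like vertebral body (anterior/posterior heights,
#' superior/inferior depths) plus a spinous process, in the mid-sagittal
#' plane convention (x anterior, z superior, y out of plane), then applies
#' a rigid pose. Returns both the posed point cloud and the true posed
#' landmarks, so morphometric measures can be checked against the
#' generating parameters exactly.
#'
#' @param height_ant,height_post anterior / posterior body heights, mm.
#' @param depth_sup,depth_inf superior / inferior body depths, mm.
#' @param spinous_len spinous process length, mm.
#' @param body_to_spinous distance from the posterior body wall to the
#'   distal end of the spinous process, mm.
#' @param rotation 3 x 3 proper rotation applied to all points.
#' @param translation length-3 offset, mm.
#' @param n_fill points sampled deterministically on the body box faces so
#'   the cloud has full-rank covariance for PCA.
#' @return list with `points` (cloud, n x 3), `landmarks` (a
#'   [vertebral_landmarks()] object) and `truth` (named generating
#'   dimensions).
#' @export
parametric_vertebra <- function(height_ant = 12, height_post = 14,
                                depth_sup = 16, depth_inf = 15,
                                spinous_len = 20, body_to_spinous = 32,
                                rotation = diag(3), translation = c(0, 0, 0),
                                n_fill = 6L) {
  stopifnot(height_ant > 0, height_post > 0, depth_sup > 0, depth_inf > 0,
            spinous_len > 0, body_to_spinous > 0)
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      det(rotation) < 0) {
    stop("rotation must be a proper orthogonal 3 x 3 matrix")
  }
  # Mid-sagittal plane y = 0; x anterior, z superior. The posterior wall is
  # vertical; the inferior endplate is horizontal; the anterior-superior
  # corner is placed so that all four declared corner distances hold
  # exactly (two-circle intersection in the sagittal plane).
  ps2 <- c(0, height_post / 2)                 # (x, z)
  pi2 <- c(0, -height_post / 2)
  ai2 <- pi2 + c(depth_inf, 0)
  d <- ai2 - ps2
  D <- sqrt(sum(d^2))
  aa <- (depth_sup^2 - height_ant^2 + D^2) / (2 * D)
  h2 <- depth_sup^2 - aa^2
  if (h2 < 0) {
    stop("vertebra dimensions are not geometrically realizable ",
         "(corner circles do not intersect)")
  }
  u <- d / D
  perp <- c(-u[2L], u[1L])
  cand1 <- ps2 + aa * u + sqrt(h2) * perp
  cand2 <- ps2 + aa * u - sqrt(h2) * perp
  as2 <- if (cand1[2L] >= cand2[2L]) cand1 else cand2
  lm <- rbind(anterior_superior  = c(as2[1L], 0, as2[2L]),
              anterior_inferior  = c(ai2[1L], 0, ai2[2L]),
              posterior_superior = c(ps2[1L], 0, ps2[2L]),
              posterior_inferior = c(pi2[1L], 0, pi2[2L]))
  # spinous process extends posteriorly (negative x) from the midpoint of
  # the posterior corners, which sits at the origin
  distal <- c(-body_to_spinous, 0, 0)
  proximal <- c(distal[1L] + spinous_len, 0, 0)
  # body fill points: deterministic grid on the box surface (half-width 5)
  s <- seq(0, 1, length.out = n_fill)
  grid <- as.matrix(expand.grid(u = s, v = s))
  width <- 5
  fill <- rbind(
    cbind(grid[, 1L] * depth_sup, -width + 2 * width * grid[, 2L],
          height_post / 2),
    cbind(grid[, 1L] * depth_inf, -width + 2 * width * grid[, 2L],
          -height_post / 2),
    cbind(0, -width + 2 * width * grid[, 1L],
          -height_post / 2 + height_post * grid[, 2L]),
    cbind(depth_sup, -width + 2 * width * grid[, 1L],
          -height_ant / 2 + height_ant * grid[, 2L]))
  pts <- rbind(lm, spinous_distal = distal, spinous_proximal = proximal,
               fill)
  posed <- sweep(pts %*% t(rotation), 2L, translation, "+")
  landmarks <- vertebral_landmarks(
    anterior_superior = posed["anterior_superior", ],
    anterior_inferior = posed["anterior_inferior", ],
    posterior_superior = posed["posterior_superior", ],
    posterior_inferior = posed["posterior_inferior", ],
    spinous_distal = posed["spinous_distal", ],
    spinous_proximal = posed["spinous_proximal", ])
  list(points = unname(posed),
       landmarks = landmarks,
       truth = c(height_ant = height_ant, height_post = height_post,
                 depth_sup = depth_sup, depth_inf = depth_inf,
                 spinous_len = spinous_len,
                 body_to_spinous = body_to_spinous))
}

#' Seeded damped-oscillation time series
#'
#' `A * exp(-decay * t) * sin(2 * pi * f * t)` plus Gaussian noise with a
#' named seed, a stand-in for displacement and flexion-angle validation
#' curves.
#'
#' @param amplitude peak amplitude (mm or degrees).
#' @param frequency oscillation frequency per unit time.
#' @param decay exponential decay constant per unit time.
#' @param duration total duration (same time unit).
#' @param dt sample spacing, > 0.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed for the noise (local to this call).
#' @return a [time_series()] object.
#' @export
damped_oscillation <- function(amplitude = 10, frequency = 0.02,
                               decay = 0.01, duration = 200, dt = 1,
                               noise_sd = 0, seed = 0L) {
  stopifnot(dt > 0, duration > 0)
  t <- seq(0, duration, by = dt)
  v <- amplitude * exp(-decay * t) * sin(2 * pi * frequency * t)
  if (noise_sd > 0) {
    v <- v + with_local_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  }
  time_series(t, v)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  expr
}

#' Deterministic per-element strain fields
#'
#' Assigns a symmetric 3 x 3 Green-Lagrange strain tensor to every element
#' of a mesh, for exercising batch erosion checks and principal-strain
#' fields. Rules: `uniform` (same principal strain everywhere), `radial`
#' (strain grows linearly with centroid radius up to `peak` at `radius`)
#' and `hotspot` (Gaussian bump of amplitude `peak` around `center` with
#' length scale `width`).
#'
#' @param mesh a volume mesh.
#' @param rule `"uniform"`, `"radial"` or `"hotspot"`.
#' @param value uniform principal strain (rule `"uniform"`).
#' @param peak peak principal strain (rules `"radial"`, `"hotspot"`).
#' @param radius radius at which `peak` is reached (rule `"radial"`).
#' @param center hotspot centre, length-3 (rule `"hotspot"`).
#' @param width hotspot Gaussian length scale, mm.
#' @return list of symmetric 3 x 3 matrices, one per element, with the
#'   assigned principal strain as attribute `"principal"`.
#' @export
strain_field <- function(mesh, rule = c("uniform", "radial", "hotspot"),
                         value = 0.1, peak = 0.8, radius = NULL,
                         center = c(0, 0, 0), width = 5) {
  rule <- match.arg(rule)
  cen <- element_centroids(mesh)
  s <- switch(rule,
              uniform = rep(value, nrow(cen)),
              radial = {
                r <- sqrt(rowSums(cen^2))
                if (is.null(radius)) radius <- max(r)
                peak * r / radius
              },
              hotspot = {
                d2 <- rowSums(sweep(cen, 2L, center)^2)
                peak * exp(-d2 / (2 * width^2))
              })
  out <- lapply(s, function(si) diag(c(si, si / 4, -si / 4)))
  attr(out, "principal") <- s
  out
}
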