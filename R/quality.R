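# Element quality metrics and mesh reports. Standard textbook definitions
# are used: the acceptance thresholds (aspect ratio 4, skewness 45,
# warping 20, maximum angle 140) are meaningful under angle-in-degrees and
# edge-length-ratio conventions, which these match. "Jacobian" is the
# scaled (normalized) Jacobian, a unit-free value in [-1, 1].

#' Mesh quality thresholds
#'
#' Acceptance thresholds applied during mesh generation and reporting:
#' aspect ratio below 4, skewness below 45 degrees, warping below 20
#' degrees, face-corner angles below 140 degrees, scaled Jacobian above
#' 0.4 for hexahedra and above 0.8 for tetrahedra. `aspect_report_cutoff`
#' (default 3) is the bound used for the "% of elements with aspect ratio
#' < 3" summary column.
#'
#' @param aspect_ratio_max,skewness_max_deg,warping_max_deg,max_angle_deg,jacobian_min_hex,jacobian_min_tet,aspect_report_cutoff
#'   numeric thresholds; see description for defaults.
#' @return a `quality_thresholds` list.
#' @export
quality_thresholds <- function(aspect_ratio_max = 4,
                               skewness_max_deg = 45,
                               warping_max_deg = 20,
                               max_angle_deg = 140,
                               jacobian_min_hex = 0.4,
                               jacobian_min_tet = 0.8,
                               aspect_report_cutoff = 3) {
  th <- list(aspect_ratio_max = aspect_ratio_max,
             skewness_max_deg = skewness_max_deg,
             warping_max_deg = warping_max_deg,
             max_angle_deg = max_angle_deg,
             jacobian_min_hex = jacobian_min_hex,
             jacobian_min_tet = jacobian_min_tet,
             aspect_report_cutoff = aspect_report_cutoff)
  stopifnot(all(unlist(th) > 0), skewness_max_deg < 180,
            warping_max_deg < 180, max_angle_deg < 180)
  structure(th, class = "quality_thresholds")
}

#' Read/write quality thresholds as YAML
#' @param path YAML file whose keys mirror [quality_thresholds()] fields.
#' @return a `quality_thresholds` object.
#' @export
read_thresholds_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(quality_thresholds, vals)
}

#' @rdname read_thresholds_yaml
#' @param thresholds a [quality_thresholds()] object.
#' @export
write_thresholds_yaml <- function(thresholds, path) {
  yaml::write_yaml(unclass(thresholds), path)
  invisible(path)
}

#' Scaled Jacobian of every element in a mesh
#'
#' Hexahedra: minimum over the 8 corners of the determinant of the three
#' unit edge vectors meeting there (1 for an orthogonal corner frame).
#' Tetrahedra: corner determinant of unit edge vectors, normalized by
#' sqrt(2)/2 so a regular tetrahedron scores 1, minimized over the 4
#' corners. Degenerate elements (coincident nodes) return 0 and are listed
#' in the `degenerate` attribute.
#'
#' @param mesh a `tet_mesh` or `hex_mesh`.
#' @return numeric vector in [-1, 1], one value per element.
#' @export
scaled_jacobian <- function(mesh) {
  nodes <- mesh$nodes
  el <- mesh$elements
  if (inherits(mesh, "hex_mesh")) {
    sj <- hex_corner_jacobians(nodes, el, scaled = TRUE)
    out <- apply(sj, 1L, min)
  } else if (inherits(mesh, "tet_mesh")) {
    out <- rep(Inf, nrow(el))
    corner_orders <- rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 1L, 4L),
                           c(3L, 1L, 2L, 4L), c(4L, 2L, 1L, 3L))
    for (r in 1:4) {
      o <- corner_orders[r, ]
      p <- nodes[el[, o[1L]], , drop = FALSE]
      e1 <- nodes[el[, o[2L]], , drop = FALSE] - p
      e2 <- nodes[el[, o[3L]], , drop = FALSE] - p
      e3 <- nodes[el[, o[4L]], , drop = FALSE] - p
      len <- vnorm(e1) * vnorm(e2) * vnorm(e3)
      d <- ifelse(len > 0, det3(e1, e2, e3) / len, 0) / (sqrt(2) / 2)
      out <- pmin(out, d)
    }
  } else {
    stop("scaled_jacobian needs a tet_mesh or hex_mesh")
  }
  degen <- !is.finite(out) | element_edge_stats(mesh)$min_edge == 0
  out[degen] <- 0
  out <- pmax(pmin(out, 1), -1)
  if (any(degen)) attr(out, "degenerate") <- which(degen)
  out
}

element_edge_table <- function(mesh) {
  if (inherits(mesh, "hex_mesh")) {
    HEX_EDGES
  } else if (inherits(mesh, "tet_mesh")) {
    TET_EDGES
  } else if (inherits(mesh, "surface_mesh")) {
    k <- ncol(mesh$faces)
    cbind(seq_len(k), c(seq_len(k)[-1L], 1L))
  } else {
    stop("unsupported mesh type")
  }
}

# per-element min/max edge lengths and pooled edge lengths
element_edge_stats <- function(mesh) {
  el <- mesh_elements(mesh)
  nodes <- mesh$nodes
  et <- element_edge_table(mesh)
  mn <- rep(Inf, nrow(el)); mx <- rep(0, nrow(el))
  all_len <- matrix(NA_real_, nrow(el), nrow(et))
  for (e in seq_len(nrow(et))) {
    len <- vnorm(nodes[el[, et[e, 2L]], , drop = FALSE] -
                   nodes[el[, et[e, 1L]], , drop = FALSE])
    mn <- pmin(mn, len); mx <- pmax(mx, len)
    all_len[, e] <- len
  }
  list(min_edge = mn, max_edge = mx, lengths = all_len)
}

#' Aspect ratio of every element
#'
#' Longest element edge divided by shortest. Degenerate elements (zero
#' shortest edge) are reported as the capped sentinel 1e6 and listed in
#' the `degenerate` attribute.
#'
#' @param mesh a volume or surface mesh.
#' @return numeric vector >= 1.
#' @export
aspect_ratio <- function(mesh) {
  es <- element_edge_stats(mesh)
  degen <- es$min_edge == 0
  out <- ifelse(degen, 1e6, es$max_edge / pmax(es$min_edge,
                                               .Machine$double.xmin))
  if (any(degen)) attr(out, "degenerate") <- which(degen)
  out
}

element_face_corner_angles <- function(mesh) {
  nodes <- mesh$nodes
  el <- mesh_elements(mesh)
  m <- nrow(el)
  if (inherits(mesh, "hex_mesh")) {
    faces <- lapply(seq_len(nrow(HEX_FACES)), function(f) HEX_FACES[f, ])
  } else if (inherits(mesh, "tet_mesh")) {
    faces <- lapply(seq_len(nrow(TET_FACES)), function(f) TET_FACES[f, ])
  } else {
    k <- ncol(el)
    faces <- list(seq_len(k))
  }
  angs <- NULL
  for (fc in faces) {
    k <- length(fc)
    p <- lapply(seq_len(k), function(i) nodes[el[, fc[i]], , drop = FALSE])
    fa <- matrix(NA_real_, m, k)
    for (c0 in seq_len(k)) {
      u <- p[[if (c0 == 1L) k else c0 - 1L]] - p[[c0]]
      w <- p[[if (c0 == k) 1L else c0 + 1L]] - p[[c0]]
      cr <- vcross(u, w)
      fa[, c0] <- atan2(vnorm(cr), vdot(u, w)) * 180 / pi
    }
    angs <- cbind(angs, fa)
  }
  attr(angs, "corners_per_face") <- if (inherits(mesh, "tet_mesh")) 3L else
    length(faces[[1L]])
  angs
}

#' Skewness, warping and maximum corner angle of every element
#'
#' `skewness_deg`: maximum deviation of any face corner angle from the
#' ideal angle (60 degrees for triangular faces, 90 for quadrilateral).
#' `warping_deg`: for each quadrilateral face, the angle between the
#' normals of the two triangles obtained by cutting along a diagonal,
#' maximized over both diagonals and all faces (0 for planar faces and for
#' triangles). `max_corner_angle_deg`: largest face corner angle of the
#' element in degrees.
#'
#' @param mesh a volume or surface mesh.
#' @return numeric vector in degrees, one value per element.
#' @export
skewness_deg <- function(mesh) {
  angs <- element_face_corner_angles(mesh)
  tri_faces <- inherits(mesh, "tet_mesh") ||
    (inherits(mesh, "surface_mesh") && mesh$face_kind == "triangle")
  ideal <- if (tri_faces) 60 else 90
  apply(abs(angs - ideal), 1L, max)
}

#' @rdname skewness_deg
#' @export
max_corner_angle_deg <- function(mesh) {
  angs <- element_face_corner_angles(mesh)
  apply(angs, 1L, max)
}

#' @rdname skewness_deg
#' @export
warping_deg <- function(mesh) {
  nodes <- mesh$nodes
  el <- mesh_elements(mesh)
  if (inherits(mesh, "tet_mesh") ||
      (inherits(mesh, "surface_mesh") && mesh$face_kind == "triangle")) {
    return(rep(0, nrow(el)))
  }
  faces <- if (inherits(mesh, "hex_mesh")) {
    lapply(seq_len(nrow(HEX_FACES)), function(f) HEX_FACES[f, ])
  } else {
    list(1:4)
  }
  out <- rep(0, nrow(el))
  for (fc in faces) {
    p <- lapply(1:4, function(i) nodes[el[, fc[i]], , drop = FALSE])
    for (diag0 in 1:2) {
      if (diag0 == 1L) {           # split along 1-3
        n1 <- vcross(p[[2L]] - p[[1L]], p[[3L]] - p[[1L]])
        n2 <- vcross(p[[3L]] - p[[1L]], p[[4L]] - p[[1L]])
      } else {                     # split along 2-4
        n1 <- vcross(p[[3L]] - p[[2L]], p[[4L]] - p[[2L]])
        n2 <- vcross(p[[4L]] - p[[2L]], p[[1L]] - p[[2L]])
      }
      ang <- atan2(vnorm(vcross(n1, n2)), vdot(n1, n2)) * 180 / pi
      out <- pmax(out, ang)
    }
  }
  out
}

#' Average mesh size
#'
#' Mean and standard deviation of all element edge lengths (pooled over
#' elements, so shared edges count once per adjacent element), the
#' mesh-size convention used in mesh summary tables.
#'
#' @param mesh any mesh object.
#' @return named vector `c(mean = , sd = )` in mm.
#' @export
average_mesh_size <- function(mesh) {
  len <- as.vector(element_edge_stats(mesh)$lengths)
  c(mean = mean(len), sd = if (length(len) > 1L) stats::sd(len) else 0)
}

#' Full mesh quality report
#'
#' Computes every per-element metric, applies the thresholds, and builds a
#' mesh summary (element count, average mesh size mean and SD, minimum
#' scaled Jacobian, percentage of elements with aspect ratio below the
#' report cutoff, percentage passing each threshold).
#'
#' @param mesh a `tet_mesh` or `hex_mesh` (surface meshes: angle metrics
#'   and aspect only).
#' @param thresholds a [quality_thresholds()].
#' @return a `quality_report`: list with `elements` (per-element data
#'   frame) and `summary` (named list).
#' @export
quality_report <- function(mesh, thresholds = quality_thresholds()) {
  stopifnot(inherits(thresholds, "quality_thresholds"))
  is_vol <- inherits(mesh, c("tet_mesh", "hex_mesh"))
  sj <- if (is_vol) as.numeric(scaled_jacobian(mesh)) else
    rep(NA_real_, n_elements(mesh))
  df <- data.frame(
    element = seq_len(n_elements(mesh)),
    scaled_jacobian = sj,
    aspect_ratio = as.numeric(aspect_ratio(mesh)),
    skewness_deg = skewness_deg(mesh),
    warping_deg = warping_deg(mesh),
    max_angle_deg = max_corner_angle_deg(mesh))
  jmin <- if (inherits(mesh, "hex_mesh")) thresholds$jacobian_min_hex else
    thresholds$jacobian_min_tet
  df$pass_jacobian <- if (is_vol) df$scaled_jacobian > jmin else NA
  df$pass_aspect <- df$aspect_ratio < thresholds$aspect_ratio_max
  df$pass_skewness <- df$skewness_deg < thresholds$skewness_max_deg
  df$pass_warping <- df$warping_deg < thresholds$warping_max_deg
  df$pass_max_angle <- df$max_angle_deg <= thresholds$max_angle_deg
  sz <- average_mesh_size(mesh)
  summary <- list(
    n_elements = nrow(df),
    element_type = class(mesh)[1L],
    mesh_size_mean = unname(sz["mean"]),
    mesh_size_sd = unname(sz["sd"]),
    min_jacobian = if (is_vol) min(df$scaled_jacobian) else NA_real_,
    max_angle = max(df$max_angle_deg),
    pct_aspect_below_cutoff =
      100 * mean(df$aspect_ratio < thresholds$aspect_report_cutoff),
    pct_pass_jacobian = if (is_vol) 100 * mean(df$pass_jacobian) else
      NA_real_,
    pct_pass_aspect = 100 * mean(df$pass_aspect),
    pct_pass_skewness = 100 * mean(df$pass_skewness),
    pct_pass_warping = 100 * mean(df$pass_warping),
    pct_pass_max_angle = 100 * mean(df$pass_max_angle))
  structure(list(elements = df, summary = summary,
                 thresholds = thresholds),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<quality_report> %d %s elements\n", s$n_elements,
              s$element_type))
  cat(sprintf("  mesh size %.2f +/- %.2f mm; min scaled Jacobian %s\n",
              s$mesh_size_mean, s$mesh_size_sd,
              if (is.na(s$min_jacobian)) "n/a" else
                sprintf("%.3f", s$min_jacobian)))
  cat(sprintf("  aspect < %g: %.1f%%; max corner angle %.1f deg (%.1f%% within %g)\n",
              x$thresholds$aspect_report_cutoff, s$pct_aspect_below_cutoff,
              s$max_angle, s$pct_pass_max_angle,
              x$thresholds$max_angle_deg))
  invisible(x)
}

#' Export a per-element quality table to CSV
#' @param report a [quality_report()].
#' @param path output CSV path.
#' @export
write_quality_csv <- function(report, path) {
  stopifnot(inherits(report, "quality_report"))
  utils::write.csv(report$elements, path, row.names = FALSE)
  invisible(path)
}
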