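# Geometry-verification measures for cervical vertebrae and head
# structures, plus the time-series statistics used to compare simulated
# and experimental validation curves. All lengths in millimetres, angles
# in degrees.

#' Vertebral landmark set
#'
#' The six mid-sagittal landmark points used for cervical morphometry:
#' the four corner-most points of the vertebral body and the distal /
#' proximal corner-most points of the spinous process.
#'
#' @param anterior_superior,anterior_inferior,posterior_superior,posterior_inferior
#'   3-vectors, mm: vertebral body corners.
#' @param spinous_distal,spinous_proximal 3-vectors, mm: spinous process
#'   end points.
#' @return a `vertebral_landmarks` object.
#' @export
vertebral_landmarks <- function(anterior_superior, anterior_inferior,
                                posterior_superior, posterior_inferior,
                                spinous_distal, spinous_proximal) {
  pts <- rbind(anterior_superior = as.numeric(anterior_superior),
               anterior_inferior = as.numeric(anterior_inferior),
               posterior_superior = as.numeric(posterior_superior),
               posterior_inferior = as.numeric(posterior_inferior),
               spinous_distal = as.numeric(spinous_distal),
               spinous_proximal = as.numeric(spinous_proximal))
  if (ncol(pts) != 3L || !all(is.finite(pts))) {
    stop("landmarks must be finite 3-vectors")
  }
  if (anyDuplicated(pts) > 0L) {
    stop("the six landmark points must be distinct")
  }
  structure(list(points = pts), class = "vertebral_landmarks")
}

#' Read vertebral landmarks from a label,x,y,z CSV
#'
#' @param path CSV with the six labels used by [vertebral_landmarks()].
#' @return a `vertebral_landmarks` object.
#' @export
read_landmarks_csv <- function(path) {
  df <- read_points_csv(path)
  need <- c("anterior_superior", "anterior_inferior", "posterior_superior",
            "posterior_inferior", "spinous_distal", "spinous_proximal")
  miss <- setdiff(need, df$label)
  if (length(miss) > 0L) stop("landmark CSV is missing: ", toString(miss))
  get <- function(lab) as.numeric(df[match(lab, df$label), c("x", "y", "z")])
  vertebral_landmarks(get(need[1L]), get(need[2L]), get(need[3L]),
                      get(need[4L]), get(need[5L]), get(need[6L]))
}

#' @export
print.vertebral_landmarks <- function(x, ...) {
  cat("<vertebral_landmarks>\n")
  print(round(x$points, 3))
  invisible(x)
}

lm_pt <- function(lm, name) lm$points[name, ]

dist3 <- function(a, b) sqrt(sum((a - b)^2))

#' Vertebral body height and depth
#'
#' Height is the average of the anterior (anterior-superior to
#' anterior-inferior) and posterior (posterior-superior to
#' posterior-inferior) body heights; depth is the average of the superior
#' (posterior-superior to anterior-superior) and inferior
#' (anterior-inferior to posterior-inferior) body widths.
#'
#' @param lm a [vertebral_landmarks()] object.
#' @return length in mm.
#' @export
vertebral_height <- function(lm) {
  (dist3(lm_pt(lm, "anterior_superior"), lm_pt(lm, "anterior_inferior")) +
   dist3(lm_pt(lm, "posterior_superior"),
         lm_pt(lm, "posterior_inferior"))) / 2
}

#' @rdname vertebral_height
#' @export
vertebral_depth <- function(lm) {
  (dist3(lm_pt(lm, "posterior_superior"), lm_pt(lm, "anterior_superior")) +
   dist3(lm_pt(lm, "anterior_inferior"),
         lm_pt(lm, "posterior_inferior"))) / 2
}

#' Spinous process length and body-to-spinous length
#'
#' `spinous_process_length` is the distance between the distal and proximal
#' corner-most points of the spinous process; `body_to_spinous_length` is
#' the distance between the distal end of the spinous process and the
#' posterior side of the vertebral body (taken as the midpoint of the two
#' posterior corners). A zero distance is returned with a warning.
#'
#' @param lm a [vertebral_landmarks()] object.
#' @return length in mm.
#' @export
spinous_process_length <- function(lm) {
  d <- dist3(lm_pt(lm, "spinous_distal"), lm_pt(lm, "spinous_proximal"))
  if (d == 0) warning("degenerate zero-length spinous process")
  d
}

#' @rdname spinous_process_length
#' @export
body_to_spinous_length <- function(lm) {
  post_mid <- (lm_pt(lm, "posterior_superior") +
                 lm_pt(lm, "posterior_inferior")) / 2
  d <- dist3(lm_pt(lm, "spinous_distal"), post_mid)
  if (d == 0) warning("degenerate zero body-to-spinous distance")
  d
}

#' All landmark-based vertebral measures at once
#'
#' @param lm a [vertebral_landmarks()] object.
#' @return named numeric vector (mm).
#' @export
vertebral_measures <- function(lm) {
  c(height = vertebral_height(lm),
    depth = vertebral_depth(lm),
    spinous_process_length = suppressWarnings(spinous_process_length(lm)),
    body_to_spinous_length = suppressWarnings(body_to_spinous_length(lm)))
}

#' Angle-corrected dimensionless intervertebral disk height
#'
#' Frobin-style construction: the mid-plane of each vertebral body is the
#' line through the midpoints of its anterior and posterior walls; the
#' bisectrix halves the angle between the two mid-planes. Disk height is
#' the distance between the midpoints of the two facing endplates measured
#' perpendicular to the bisectrix, normalized by the mean depth of the two
#' vertebral bodies. The ratio is invariant under rigid motion and uniform
#' scaling of the vertebra pair. Intersecting bodies give a negative
#' height, returned with attribute `flag = "intersecting"`.
#'
#' @param upper landmarks of the vertebra above the disk.
#' @param lower landmarks of the vertebra below the disk.
#' @return dimensionless ratio.
#' @export
dimensionless_disk_height <- function(upper, lower) {
  midline <- function(lm) {
    ant <- (lm_pt(lm, "anterior_superior") +
              lm_pt(lm, "anterior_inferior")) / 2
    post <- (lm_pt(lm, "posterior_superior") +
               lm_pt(lm, "posterior_inferior")) / 2
    d <- ant - post
    list(dir = d / sqrt(sum(d^2)), mid = (ant + post) / 2)
  }
  mu <- midline(upper)
  ml <- midline(lower)
  # bisectrix of the two mid-plane directions (sign-aligned first)
  d2 <- if (sum(mu$dir * ml$dir) < 0) -ml$dir else ml$dir
  bis <- mu$dir + d2
  bis <- bis / sqrt(sum(bis^2))
  # endplates facing the disk: inferior endplate of the upper vertebra,
  # superior endplate of the lower vertebra
  up_mid <- (lm_pt(upper, "anterior_inferior") +
               lm_pt(upper, "posterior_inferior")) / 2
  lo_mid <- (lm_pt(lower, "anterior_superior") +
               lm_pt(lower, "posterior_superior")) / 2
  gap <- up_mid - lo_mid
  h <- sqrt(sum(gap^2) - sum(gap * bis)^2)   # component perpendicular to bisectrix
  # sign: negative when the upper inferior plate lies below the lower
  # superior plate along the line joining the body centres
  axis <- mu$mid - ml$mid
  if (sum(gap * axis) < 0) h <- -h
  ratio <- h / mean(c(vertebral_depth(upper), vertebral_depth(lower)))
  if (h < 0) attr(ratio, "flag") <- "intersecting"
  ratio
}

#' Reorient a point cloud by principal component analysis
#'
#' Centres the cloud on its centroid and rotates it so the covariance
#' eigenvectors, in order of decreasing eigenvalue, map onto the global x,
#' y, z axes. Axis signs are chosen so each principal direction has a
#' positive dot product with the corresponding row of `reference`
#' (anatomical reference directions); the rotation is made proper
#' (determinant +1) by flipping the last axis if needed.
#'
#' @param points n x 3 point cloud, n >= 4, not coplanar.
#' @param reference 3 x 3 matrix of reference directions (rows), default
#'   the global axes.
#' @return list with `rotation` (proper orthogonal, applied as
#'   `(points - centroid) %*% t(rotation)`), `centroid`, and
#'   `aligned_points`.
#' @export
pca_reorient <- function(points, reference = diag(3)) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  if (nrow(points) < 4L) stop("need at least 4 points")
  centroid <- colMeans(points)
  centred <- sweep(points, 2L, centroid)
  cv <- stats::cov(centred)
  eg <- eigen(cv, symmetric = TRUE)
  rel <- eg$values / max(eg$values)
  if (rel[3L] < 1e-10) {
    stop("degenerate geometry: point cloud is (near-)coplanar")
  }
  if (min(abs(diff(eg$values))) / max(eg$values) < 1e-8) {
    stop("degenerate geometry: principal axes are ambiguous ",
         "(repeated covariance eigenvalues)")
  }
  axes <- eg$vectors                     # columns, descending eigenvalue
  for (j in 1:3) {
    if (sum(axes[, j] * reference[j, ]) < 0) axes[, j] <- -axes[, j]
  }
  if (det(axes) < 0) axes[, 3L] <- -axes[, 3L]
  rotation <- t(axes)                    # maps PC directions to x, y, z
  list(rotation = rotation, centroid = centroid,
       aligned_points = centred %*% t(rotation))
}

#' Thickness between two surfaces
#'
#' `mode = "minimum"`: minimum over the outer surface's nodes of the
#' distance to the inner surface (point-to-triangle). `mode = "sites"`:
#' for each site point (assumed on or near the outer surface) the distance
#' along the inward surface normal to the first intersection with the
#' inner surface; a site whose ray misses the inner surface is returned as
#' `NA` with a warning.
#'
#' @param inner,outer triangle `surface_mesh` objects, outer outside inner.
#' @param mode `"minimum"` or `"sites"`.
#' @param sites k x 3 matrix of site coordinates (mode `"sites"`).
#' @return minimum thickness (scalar) or per-site thicknesses (vector, mm).
#' @export
surface_thickness <- function(inner, outer, mode = c("minimum", "sites"),
                              sites = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(inner, "surface_mesh"), inner$face_kind == "triangle")
  tri <- inner$faces
  A <- inner$nodes[tri[, 1L], , drop = FALSE]
  B <- inner$nodes[tri[, 2L], , drop = FALSE]
  C <- inner$nodes[tri[, 3L], , drop = FALSE]
  if (mode == "minimum") {
    stopifnot(inherits(outer, "surface_mesh"))
    d <- point_surface_distance(outer$nodes, A, B, C)
    return(min(d))
  }
  stopifnot(is.matrix(sites) || is.data.frame(sites))
  sites <- as.matrix(sites)
  # inward direction: toward the inner surface's centroid
  cen <- colMeans(inner$nodes)
  out <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    p <- sites[i, ]
    dir <- cen - p
    nd <- sqrt(sum(dir^2))
    if (nd == 0) { out[i] <- NA_real_; next }
    dir <- dir / nd
    t0 <- ray_triangles_hit(p, dir, A, B, C)
    # hits beyond the inner surface's centroid belong to the far
    # (contralateral) wall, not the local thickness
    out[i] <- if (is.finite(t0) && t0 <= nd) t0 else NA_real_
  }
  if (anyNA(out)) {
    warning(sum(is.na(out)), " site ray(s) missed the inner surface")
  }
  out
}

# Distance from each point to the closest of the given triangles.
point_surface_distance <- function(points, A, B, C) {
  n <- nrow(points)
  best <- rep(Inf, n)
  for (f in seq_len(nrow(A))) {
    d <- point_triangle_distance(points, A[f, ], B[f, ], C[f, ])
    best <- pmin(best, d)
  }
  best
}

# Vectorized point-to-single-triangle distance (Eberly-style region tests
# via clamped barycentric projection).
point_triangle_distance <- function(P, a, b, c) {
  ab <- b - a; ac <- c - a
  ap <- sweep(P, 2L, a)
  d1 <- as.numeric(ap %*% ab)
  d2 <- as.numeric(ap %*% ac)
  dab <- sum(ab * ab); dac <- sum(ac * ac); dabc <- sum(ab * ac)
  denom <- dab * dac - dabc^2
  v <- (dac * d1 - dabc * d2) / denom
  w <- (dab * d2 - dabc * d1) / denom
  v <- pmax(0, v); w <- pmax(0, w)
  s <- v + w
  over <- s > 1
  v <- ifelse(over, v / s, v)
  w <- ifelse(over, w / s, w)
  # clamped point may still be off-edge; refine by clamping to each edge
  proj <- sweep(outer(v, ab) + outer(w, ac), 2L, a, "+")
  d <- vnorm(P - proj)
  for (edge in list(list(a, b), list(a, c), list(b, c))) {
    e <- edge[[2L]] - edge[[1L]]
    t0 <- pmax(0, pmin(1, as.numeric(sweep(P, 2L, edge[[1L]]) %*% e) /
                         sum(e * e)))
    q <- sweep(outer(t0, e), 2L, edge[[1L]], "+")
    d <- pmin(d, vnorm(P - q))
  }
  d
}

# Smallest positive ray parameter hitting any triangle (Moller-Trumbore).
ray_triangles_hit <- function(origin, dir, A, B, C) {
  e1 <- B - A
  e2 <- C - A
  dirm <- matrix(dir, nrow(A), 3L, byrow = TRUE)
  pv <- vcross(dirm, e2)
  det <- vdot(e1, pv)
  tv <- sweep(-A, 2L, origin, "+")
  u <- vdot(tv, pv) / det
  qv <- vcross(tv, e1)
  v <- vdot(dirm, qv) / det
  t0 <- vdot(e2, qv) / det
  ok <- abs(det) > 1e-12 & u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9 &
    t0 > 1e-9
  if (!any(ok)) return(Inf)
  min(t0[ok])
}

#' Neck flexion angle
#'
#' The angle between the vertical direction and the line joining the
#' anterior-most point of the foramen magnum and the anterior-inferior
#' corner of C7, both projected into the mid-sagittal plane. The sign is
#' positive for flexion (the head end of the line rotated anteriorly,
#' i.e. toward `vertical x sagittal_normal`).
#'
#' @param foramen_anterior 3-vector, anterior-most point of the foramen
#'   magnum, mm.
#' @param c7_anterior_inferior 3-vector, anterior-inferior corner-most
#'   point of C7, mm.
#' @param vertical unit 3-vector, upright direction.
#' @param sagittal_normal unit 3-vector, normal of the mid-sagittal plane.
#' @return signed angle in degrees.
#' @export
neck_flexion_angle <- function(foramen_anterior, c7_anterior_inferior,
                               vertical = c(0, 0, 1),
                               sagittal_normal = c(0, 1, 0)) {
  v <- as.numeric(foramen_anterior) - as.numeric(c7_anterior_inferior)
  n <- sagittal_normal / sqrt(sum(sagittal_normal^2))
  vp <- v - sum(v * n) * n
  up <- vertical - sum(vertical * n) * n
  if (sqrt(sum(vp^2)) < 1e-9 * sqrt(sum(v^2))) {
    stop("undefined angle: joining line is orthogonal to the sagittal plane")
  }
  anterior <- c(n[2L] * up[3L] - n[3L] * up[2L],
                n[3L] * up[1L] - n[1L] * up[3L],
                n[1L] * up[2L] - n[2L] * up[1L])
  ang <- atan2(sum(vp * anterior) / sqrt(sum(anterior^2)), sum(vp * up) /
                 sqrt(sum(up^2)))
  ang * 180 / pi
}

#' Maximum principal strain of a symmetric strain tensor
#'
#' Largest eigenvalue of a 3 x 3 (Green-Lagrange) strain tensor, the
#' standard brain-injury metric. Accepts a single tensor or a list of
#' per-element tensors; in batch mode the per-element field and the peak
#' (with its element id) are returned. Non-symmetric input is symmetrized
#' with a warning.
#'
#' @param strain symmetric 3 x 3 matrix, or a list of them.
#' @return scalar, or (batch) list with `field`, `peak`, `peak_element`.
#' @export
max_principal_strain <- function(strain) {
  if (is.list(strain)) {
    field <- vapply(strain, max_principal_strain, numeric(1L))
    i <- which.max(field)
    return(list(field = field, peak = field[i], peak_element = i))
  }
  strain <- as.matrix(strain)
  stopifnot(all(dim(strain) == c(3L, 3L)))
  if (max(abs(strain - t(strain))) > 1e-8 * max(1, max(abs(strain)))) {
    warning("non-symmetric strain tensor; symmetrizing")
  }
  s <- (strain + t(strain)) / 2
  max(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
}

# ---- time series -------------------------------------------------------

#' Scalar time series
#'
#' @param t strictly increasing times (ms).
#' @param values scalar samples (angle in degrees, displacement in mm, ...).
#' @return a `time_series` object.
#' @export
time_series <- function(t, values) {
  t <- as.numeric(t)
  values <- as.numeric(values)
  if (length(t) != length(values)) stop("t and values lengths differ")
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (!all(is.finite(t)) || !all(is.finite(values))) {
    stop("times and values must be finite")
  }
  structure(list(t = t, values = values), class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples on [%g, %g]\n", length(x$t),
              min(x$t), max(x$t)))
  invisible(x)
}

#' Read/write a time series as a two-column CSV (t, value)
#' @param path CSV file.
#' @return a [time_series()].
#' @export
read_time_series_csv <- function(path) {
  df <- utils::read.csv(path)
  time_series(df[[1L]], df[[2L]])
}

#' @rdname read_time_series_csv
#' @param ts a [time_series()].
#' @export
write_time_series_csv <- function(ts, path) {
  utils::write.csv(data.frame(t = ts$t, value = ts$values), path,
                   row.names = FALSE)
  invisible(path)
}

#' Compare two validation curves
#'
#' Series `b` is linearly resampled onto the times of `a` restricted to
#' the overlapping range; on the paired samples the Pearson correlation is
#' computed, together with each curve's peak (maximum absolute value) and
#' its time, and the average of absolute values (the displacement summary
#' used when a curve oscillates around zero).
#'
#' @param a,b [time_series()] objects with overlapping time ranges (at
#'   least 3 overlapping samples).
#' @return list with `pearson_r`, `peak_a`, `peak_time_a`, `peak_b`,
#'   `peak_time_b`, `avg_abs_a`, `avg_abs_b`, `n_overlap`.
#' @export
curve_compare <- function(a, b) {
  stopifnot(inherits(a, "time_series"), inherits(b, "time_series"))
  lo <- max(min(a$t), min(b$t))
  hi <- min(max(a$t), max(b$t))
  keep <- a$t >= lo & a$t <= hi
  if (sum(keep) < 3L) {
    stop("insufficient data: fewer than 3 overlapping samples")
  }
  ta <- a$t[keep]
  va <- a$values[keep]
  vb <- stats::approx(b$t, b$values, xout = ta)$y
  ia <- which.max(abs(va))
  ib <- which.max(abs(b$values))
  list(pearson_r = stats::cor(va, vb),
       peak_a = abs(va[ia]), peak_time_a = ta[ia],
       peak_b = abs(b$values[ib]), peak_time_b = b$t[ib],
       avg_abs_a = mean(abs(va)), avg_abs_b = mean(abs(vb)),
       n_overlap = sum(keep))
}
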