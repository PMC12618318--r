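rect_landmarks <- function(height = 14, depth = 16, shift = c(0, 0, 0)) {
  vertebral_landmarks(
    anterior_superior = c(depth, 0, height / 2) + shift,
    anterior_inferior = c(depth, 0, -height / 2) + shift,
    posterior_superior = c(0, 0, height / 2) + shift,
    posterior_inferior = c(0, 0, -height / 2) + shift,
    spinous_distal = c(-30, 0, 0) + shift,
    spinous_proximal = c(-10, 0, 0) + shift)
}

test_that("height and depth are averages of the stated corner distances", {
  lm <- rect_landmarks()
  expect_equal(vertebral_height(lm), 14)
  expect_equal(vertebral_depth(lm), 16)

  # trapezoid: anterior height 12, posterior height 14
  trap <- vertebral_landmarks(
    anterior_superior = c(16, 0, 6), anterior_inferior = c(16, 0, -6),
    posterior_superior = c(0, 0, 7), posterior_inferior = c(0, 0, -7),
    spinous_distal = c(-30, 0, 0), spinous_proximal = c(-10, 0, 0))
  expect_equal(vertebral_height(trap), 13)

  set.seed(2)
  pts <- matrix(stats::rnorm(18L, sd = 10), 6L)
  rand <- vertebral_landmarks(pts[1L, ], pts[2L, ], pts[3L, ], pts[4L, ],
                              pts[5L, ], pts[6L, ])
  expect_equal(vertebral_height(rand),
               (sqrt(sum((pts[1L, ] - pts[2L, ])^2)) +
                  sqrt(sum((pts[3L, ] - pts[4L, ])^2))) / 2)
  expect_equal(vertebral_depth(rand),
               (sqrt(sum((pts[3L, ] - pts[1L, ])^2)) +
                  sqrt(sum((pts[2L, ] - pts[4L, ])^2))) / 2)
})

test_that("spinous lengths are the stated Euclidean distances", {
  lm <- rect_landmarks()
  expect_equal(spinous_process_length(lm), 20)
  expect_equal(body_to_spinous_length(lm), 30)
  degen <- vertebral_landmarks(
    anterior_superior = c(16, 0, 7), anterior_inferior = c(16, 0, -7),
    posterior_superior = c(0, 0, 7), posterior_inferior = c(0, 0, -7),
    spinous_distal = c(0, 0, 0), spinous_proximal = c(-10, 0, 0))
  expect_warning(d <- body_to_spinous_length(degen), "degenerate")
  expect_equal(d, 0)
})

test_that("dimensionless disk height reduces to gap/depth for parallel bodies", {
  lower <- rect_landmarks(height = 14, depth = 15)
  upper <- rect_landmarks(height = 14, depth = 15, shift = c(0, 0, 19))
  r <- dimensionless_disk_height(upper, lower)
  expect_equal(as.numeric(r), 5 / 15, tolerance = 1e-12)

  # rigid motion invariance
  set.seed(6)
  R <- random_rotation()
  tv <- c(3, -8, 11)
  move <- function(lm) {
    p <- lm$points %*% t(R)
    p <- sweep(p, 2L, tv, "+")
    vertebral_landmarks(p[1L, ], p[2L, ], p[3L, ], p[4L, ], p[5L, ],
                        p[6L, ])
  }
  expect_equal(as.numeric(dimensionless_disk_height(move(upper),
                                                    move(lower))),
               5 / 15, tolerance = 1e-9)

  # uniform scaling invariance
  scale_lm <- function(lm, s) {
    p <- lm$points * s
    vertebral_landmarks(p[1L, ], p[2L, ], p[3L, ], p[4L, ], p[5L, ],
                        p[6L, ])
  }
  expect_equal(as.numeric(dimensionless_disk_height(scale_lm(upper, 2.5),
                                                    scale_lm(lower, 2.5))),
               5 / 15, tolerance = 1e-12)

  # wedged disk: oracle constructs the geometry explicitly
  th <- 10 * pi / 180
  Rz <- rbind(c(cos(th), 0, -sin(th)), c(0, 1, 0), c(sin(th), 0, cos(th)))
  pu <- sweep(rect_landmarks(14, 15)$points %*% t(Rz), 2L, c(0, 0, 19), "+")
  upper_w <- vertebral_landmarks(pu[1L, ], pu[2L, ], pu[3L, ], pu[4L, ],
                                 pu[5L, ], pu[6L, ])
  got <- as.numeric(dimensionless_disk_height(upper_w, lower))
  # oracle: project the facing endplate midpoints onto the bisectrix
  # normal, divide by the mean depth, all from explicit coordinates
  mid_dir <- function(p) {
    d <- (p[1L, ] + p[2L, ]) / 2 - (p[3L, ] + p[4L, ]) / 2
    d / sqrt(sum(d^2))
  }
  d1 <- mid_dir(pu)
  d2 <- mid_dir(lower$points)
  bis <- d1 + d2
  bis <- bis / sqrt(sum(bis^2))
  gap <- (pu[2L, ] + pu[4L, ]) / 2 -
    (lower$points[1L, ] + lower$points[3L, ]) / 2
  hperp <- sqrt(sum(gap^2) - sum(gap * bis)^2)
  expect_equal(got, hperp / 15, tolerance = 1e-9)
})

test_that("PCA reorientation recovers synthetic poses", {
  set.seed(4)
  v <- parametric_vertebra()
  pr0 <- pca_reorient(v$points)
  # aligned cloud: covariance is diagonal with descending entries
  cv <- stats::cov(pr0$aligned_points)
  expect_lt(max(abs(cv[upper.tri(cv)])) / cv[1L, 1L], 1e-8)
  expect_true(all(diff(diag(cv)) < 0))

  # exact recovery on a box cloud with descending x, y, z variances
  box <- as.matrix(expand.grid(x = seq(0, 10, length.out = 5L),
                               y = seq(0, 6, length.out = 5L),
                               z = seq(0, 3, length.out = 5L)))
  R <- random_rotation()
  posed_box <- sweep(box %*% t(R), 2L, c(10, 5, -4), "+")
  prb <- pca_reorient(posed_box, reference = t(R))
  expect_equal(abs(prb$rotation %*% R), diag(3), tolerance = 1e-6)

  # vertebra cloud: posed alignment equals unposed alignment up to axis sign
  posed <- parametric_vertebra(rotation = R, translation = c(10, 5, -4))
  A0 <- pca_reorient(v$points)$aligned_points
  A1 <- pca_reorient(posed$points)$aligned_points
  for (j in 1:3) {
    expect_lt(min(max(abs(A1[, j] - A0[, j])),
                  max(abs(A1[, j] + A0[, j]))), 1e-6)
  }
  # applying the recovered transform then undoing it restores coordinates
  pr <- pca_reorient(posed$points)
  restored <- sweep(pr$aligned_points %*% t(solve(pr$rotation)), 2L,
                    pr$centroid, "+")
  expect_equal(restored, unname(posed$points), tolerance = 1e-9)

  planar <- cbind(stats::rnorm(30L), stats::rnorm(30L), 0)
  expect_error(pca_reorient(planar), "coplanar")
  expect_error(pca_reorient(diag(3)), "at least 4")
})

test_that("surface thickness recovers concentric and offset sphere gaps", {
  inner <- icosphere(80, 3L)
  outer <- icosphere(85, 3L)
  expect_equal(surface_thickness(inner, outer, "minimum"), 5,
               tolerance = 1e-6)
  sites <- outer$nodes[c(1L, 100L, 400L), ]
  th <- surface_thickness(inner, outer, "sites", sites = sites)
  expect_true(all(th >= 5 - 1e-9 & th < 5.8))

  shifted <- inner
  shifted$nodes <- sweep(shifted$nodes, 2L, c(2, 0, 0), "+")
  gap <- surface_thickness(shifted, outer, "minimum")
  expect_lt(abs(gap - 3), 0.3)

  # a hole in the inner surface: rays through it report missing
  hole <- inner
  drop <- which(apply(hole$faces, 1L, function(f) {
    all(hole$nodes[f, 1L] > 75)
  }))
  hole$faces <- hole$faces[-drop, , drop = FALSE]
  site <- matrix(c(85, 0, 0), 1L)
  expect_warning(miss <- surface_thickness(hole, outer, "sites",
                                           sites = site), "missed")
  expect_true(is.na(miss))
})

test_that("icosphere enclosed volume approaches the analytic value", {
  s <- icosphere(50, 4L)
  expect_lt(abs(enclosed_volume(s, "cm3") - 4 / 3 * pi * 125) /
              (4 / 3 * pi * 125), 0.01)
})

test_that("neck flexion angle handles the canonical configurations", {
  expect_equal(neck_flexion_angle(c(0, 0, 100), c(0, 0, 0)), 0)
  expect_equal(neck_flexion_angle(c(100, 0, 0), c(0, 0, 0)), 90)
  expect_equal(neck_flexion_angle(c(-100, 0, 0), c(0, 0, 0)), -90)
  # arbitrary configuration vs direct trigonometry in the x-z plane
  p <- c(30, 12, 40)   # the y component is projected away
  expect_equal(neck_flexion_angle(p, c(0, 0, 0)),
               atan2(30, 40) * 180 / pi, tolerance = 1e-12)
  expect_error(neck_flexion_angle(c(0, 5, 0), c(0, 0, 0)), "undefined")
})

test_that("maximum principal strain is the top eigenvalue", {
  expect_equal(max_principal_strain(diag(c(0.1, 0.05, -0.2))), 0.1)
  expect_equal(max_principal_strain(matrix(0, 3L, 3L)), 0)
  set.seed(8)
  A <- matrix(stats::rnorm(9L), 3L)
  S <- (A + t(A)) / 2
  expect_equal(max_principal_strain(S), max(eigen(S)$values),
               tolerance = 1e-12)
  field <- strain_field(sphere_tet_mesh(6, 2), "radial", peak = 0.5)
  batch <- max_principal_strain(field)
  expect_equal(batch$peak, max(batch$field))
  expect_equal(batch$field[batch$peak_element], batch$peak)
})

test_that("curve comparison statistics behave as designed", {
  a <- damped_oscillation(amplitude = 12, noise_sd = 0)
  expect_equal(curve_compare(a, a)$pearson_r, 1)
  neg <- time_series(a$t, -a$values)
  expect_equal(curve_compare(a, neg)$pearson_r, -1)

  t <- seq(0, 10, by = 0.001)
  s <- time_series(t, sin(2 * pi * t))
  co <- time_series(t, cos(2 * pi * t))
  expect_lt(abs(curve_compare(s, co)$pearson_r), 1e-3)

  cc <- curve_compare(a, a)
  expect_equal(cc$peak_a, max(abs(a$values)))
  expect_equal(cc$peak_time_a, a$t[which.max(abs(a$values))])
  expect_equal(cc$avg_abs_a, mean(abs(a$values)))

  short <- time_series(c(500, 501, 502), c(1, 2, 3))
  expect_error(curve_compare(a, short), "insufficient|overlap|fewer")
  expect_error(time_series(c(1, 1, 2), c(0, 0, 0)), "strictly increasing")
})

test_that("landmark measures are invariant under rigid motion", {
  set.seed(10)
  v <- parametric_vertebra()
  base <- vertebral_measures(v$landmarks)
  for (rep in 1:3) {
    R <- random_rotation()
    tv <- stats::rnorm(3L, sd = 20)
    posed <- parametric_vertebra(rotation = R, translation = tv)
    expect_equal(vertebral_measures(posed$landmarks), base,
                 tolerance = 1e-9)
  }
})

test_that("landmark CSV round trips into the measurement pipeline", {
  v <- parametric_vertebra()
  pts <- v$landmarks$points
  path <- withr::local_tempfile(fileext = ".csv")
  write_points_csv(data.frame(label = rownames(pts), x = pts[, 1L],
                              y = pts[, 2L], z = pts[, 3L]), path)
  lm <- read_landmarks_csv(path)
  expect_equal(vertebral_measures(lm), vertebral_measures(v$landmarks))
  bad <- withr::local_tempfile(fileext = ".csv")
  write_points_csv(data.frame(label = "anterior_superior", x = 1, y = 2,
                              z = 3), bad)
  expect_error(read_landmarks_csv(bad), "missing")
})
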