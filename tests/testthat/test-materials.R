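reg <- material_registry()

test_that("registry presets hold the published parameter values", {
  expect_equal(reg$scalp$G0, 1.70)
  expect_equal(reg$scalp$Ginf, 0.68)
  expect_equal(reg$scalp$K, 20)
  expect_equal(reg$scalp$beta, 3e-5)
  expect_equal(reg$skull$E, 15000)       # 15.00 GPa in MPa
  expect_equal(reg$skull$nu, 0.21)
  expect_equal(reg$skull$rho, 1800)
  expect_equal(reg$gray_matter$mu0, 0.00506)   # 5.06 kPa in MPa
  expect_equal(reg$gray_matter$prony$G, c(0.50, 0.20))
  expect_equal(reg$gray_matter$prony$tau, c(0.015, 0.30))
  expect_equal(reg$gray_matter$Ginf, 0.29)
  expect_equal(reg$csf$coefficients$C, 0.0112)
  expect_equal(reg$disk$prony$G, c(1.70, 1.20, 2.00))
  expect_error(material_preset("adamantium"), "unknown material preset")
})

test_that("printed brain moduli are internally consistent", {
  for (nm in c("white_matter", "gray_matter")) {
    p <- reg[[nm]]
    expect_lt(abs(p$mu0 * p$Ginf - p$muinf) / p$muinf, 0.03)
    expect_lt(abs(p$Ginf + sum(p$prony$G) - 1), 0.02)
  }
  # violations are rejected at construction
  expect_error(hyper_viscoelastic_params(
    mu0 = 0.00763, muinf = 0.00158, Ginf = 0.5,
    prony = data.frame(G = c(0.3, 0.2), tau = c(0.02, 0.31)),
    K = 2190, rho = 1060), "inconsistent")
  expect_error(hyper_viscoelastic_params(
    mu0 = 0.00763, muinf = 0.00158, Ginf = 0.21,
    prony = data.frame(G = c(0.3, 0.2), tau = c(0.02, 0.31)),
    K = 2190, rho = 1060), "sum to 1")
})

test_that("relaxation moduli hit printed endpoints and decay monotonically", {
  expect_equal(relaxation_modulus(reg$scalp, 0), 1.70)
  expect_equal(relaxation_modulus(reg$scalp, 1e12), 0.68, tolerance = 1e-9)
  expect_equal(relaxation_modulus(reg$white_matter, 0), 1.00)
  expect_equal(relaxation_modulus(reg$white_matter, 1e9), 0.21,
               tolerance = 1e-9)
  tgrid <- seq(0, 100, by = 0.1)
  for (p in list(reg$scalp, reg$white_matter, reg$gray_matter, reg$disk)) {
    g <- relaxation_modulus(p, tgrid)
    expect_true(all(diff(g) <= 1e-12))
    # G(0) - G(inf) identity
    ginf <- relaxation_modulus(p, 1e12)
    drop <- relaxation_modulus(p, 0) - ginf
    expected_drop <- if (is.null(p$G0)) sum(p$prony$G) else p$G0 - p$Ginf
    expect_equal(drop, expected_drop, tolerance = 1e-9)
  }
  expect_error(relaxation_modulus(reg$scalp, -1), "non-negative")
  expect_error(relaxation_modulus(reg$csf, 1), "no Prony")
})

test_that("strain energy is zero at identity and matches hand arithmetic", {
  expect_equal(strain_energy(reg$white_matter, I1 = 3, J = 1), 0)
  expect_equal(strain_energy(reg$csf, I1 = 3, J2 = 3, J = 1), 0)
  expect_equal(strain_energy(reg$white_matter, I1 = 3.01, J = 1),
               0.00763 / 2 * 0.01, tolerance = 1e-12)
  # CSF at isochoric uniaxial stretch 1.1: oracle computes the invariant
  # from the deformation gradient
  lam <- 1.1
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  B <- F %*% t(F)
  I1 <- sum(diag(B))
  I2 <- 0.5 * (I1^2 - sum(diag(B %*% B)))
  expect_equal(strain_energy(reg$csf, I1 = I1, J2 = I2, J = 1),
               0.0112 * (I1 - 3), tolerance = 1e-12)
  expect_error(strain_energy(reg$csf, I1 = 3, J = -1), "positive")
})

test_that("analytic uniaxial stress agrees with finite differences", {
  lams <- seq(0.8, 1.3, by = 0.05)
  for (p in list(reg$csf, reg$disk, reg$white_matter, reg$gray_matter)) {
    expect_equal(uniaxial_cauchy_stress(p, 1), 0, tolerance = 1e-12)
    W <- function(l) {
      I1 <- l^2 + 2 / l
      I2 <- 2 * l + 1 / l^2
      strain_energy(p, I1 = I1, J2 = I2, J = 1)
    }
    h <- 1e-6
    fd <- vapply(lams, function(l) l * (W(l + h) - W(l - h)) / (2 * h),
                 numeric(1L))
    an <- uniaxial_cauchy_stress(p, lams)
    expect_equal(an, fd, tolerance = 1e-6)
  }
  # neo-Hookean closed form
  mu <- reg$white_matter$mu0
  expect_equal(uniaxial_cauchy_stress(reg$white_matter, lams),
               mu * (lams^2 - 1 / lams), tolerance = 1e-12)
  # stress strictly increasing near the identity
  expect_true(all(diff(uniaxial_cauchy_stress(reg$csf,
                                              seq(0.95, 1.05, 0.01))) > 0))
  expect_error(uniaxial_cauchy_stress(reg$csf, -2), "positive")
})

test_that("Hill muscle force obeys its limiting cases", {
  p <- hill_muscle_params(pcsa = 120, volume = 9600)
  expect_equal(p$lrest, 80)
  expect_equal(p$fmax, 0.3 * 120)
  expect_equal(p$vmax, 800)

  # no activation at resting length: zero force
  f0 <- hill_muscle_force(p, L = p$lrest, v = 0, activation = 0)
  expect_equal(f0$total, 0)
  # full activation, optimal length, zero velocity: Fmax
  f1 <- hill_muscle_force(p, L = p$lrest, v = 0, activation = 1)
  expect_equal(f1$total, p$fmax)
  expect_equal(f1$passive, 0)
  # passive force matches the printed exponential formula at 1.2 Lrest
  f2 <- hill_muscle_force(p, L = 1.2 * p$lrest, activation = 0)
  hand <- p$fmax / (exp(p$ksh) - 1) *
    (exp(p$ksh / p$lmax * (1.2 - 1)) - 1)
  expect_equal(f2$passive, hand, tolerance = 1e-12)
  expect_equal(f2$total, f2$passive)
  # shortening at vmax kills the active force
  f3 <- hill_muscle_force(p, L = p$lrest, v = -p$vmax, activation = 1)
  expect_equal(f3$active, 0)
  expect_error(hill_muscle_force(p, L = p$lrest, activation = 1.5),
               "\\[0, 1\\]")
})

test_that("ligament springs are linear and tension-only by default", {
  p <- ligament_spring_params(k = 2)
  expect_equal(ligament_force(p, 0), 0)
  expect_equal(ligament_force(p, 3), 6)
  expect_equal(ligament_force(p, -1), 0)
  expect_equal(ligament_force(p, -1, tension_only = FALSE), -2)
})

test_that("erosion check flags strains above the 60% threshold", {
  expect_false(erosion_check(diag(c(0.10, 0, 0)))$eroded)
  expect_true(erosion_check(diag(c(0.65, 0, 0)))$eroded)
  set.seed(3)
  for (rep in 1:5) {
    A <- matrix(stats::rnorm(9L), 3L)
    S <- (A + t(A)) / 2
    got <- erosion_check(S)
    expect_equal(got$strain, max(eigen(S)$values), tolerance = 1e-12)
  }
  expect_warning(erosion_check(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3L)),
                 "symmetriz")
})

test_that("batch erosion counts equal a brute-force recount", {
  m <- sphere_tet_mesh(6, 2)
  for (args in list(list(rule = "uniform", value = 0.65),
                    list(rule = "uniform", value = 0.10),
                    list(rule = "hotspot", peak = 0.8,
                         center = c(0, 0, 4)))) {
    field <- do.call(strain_field, c(list(m), args))
    got <- erosion_check(field, erosion_rule(0.60))
    brute <- vapply(field, function(S) max(eigen(S)$values) > 0.60,
                    logical(1L))
    expect_identical(got$eroded_ids, which(brute))
    expect_identical(got$surviving_ids, which(!brute))
  }
  u <- erosion_check(strain_field(m, "uniform", value = 0.65))
  expect_length(u$surviving_ids, 0L)
  u2 <- erosion_check(strain_field(m, "uniform", value = 0.10))
  expect_length(u2$eroded_ids, 0L)
})

test_that("the registry round trips exactly through a YAML config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_materials_yaml(reg, path)
  back <- read_materials_yaml(path)
  expect_equal(names(back), names(reg))
  for (nm in names(reg)) {
    expect_equal(unclass(back[[nm]]), unclass(reg[[nm]]), tolerance = 0,
                 info = nm)
    expect_s3_class(back[[nm]], class(reg[[nm]])[1L])
  }
})
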