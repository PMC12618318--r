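# Constitutive-law evaluators for the head-neck tissue models: linear
# elastic, linear viscoelastic (exponential relaxation), polynomial
# hyperelastic, hyper-viscoelastic (neo-Hookean + Prony series), Hill-type
# muscle, linear ligament springs, and the strain-based scalp erosion
# rule. Internal stress/modulus unit is MPa (the mm / ms / MPa explicit-FE
# convention); densities are kept in kg/m^3 as printed; Prony relaxation
# times in seconds as printed.

#' Linear elastic material parameters
#'
#' @param E elastic modulus, MPa.
#' @param nu Poisson ratio in (-1, 0.5).
#' @param rho density, kg/m^3.
#' @return a `linear_elastic_params` object.
#' @export
linear_elastic_params <- function(E, nu, rho) {
  stopifnot(E > 0, nu > -1, nu < 0.5, rho > 0)
  structure(list(E = E, nu = nu, rho = rho),
            class = c("linear_elastic_params", "material_params"))
}

#' Linear viscoelastic material parameters
#'
#' Shear relaxation `G(t) = Ginf + (G0 - Ginf) * exp(-beta * t)`. The
#' decay constant's time unit is not standardized across sources, so it is
#' carried explicitly (`beta_unit`, default `"1/ms"`) and surfaced in
#' every curve export.
#'
#' @param G0 short-term shear modulus, MPa.
#' @param Ginf long-term shear modulus, MPa; `G0 >= Ginf > 0`.
#' @param K bulk modulus, MPa.
#' @param beta decay constant, `>= 0`, in `beta_unit`.
#' @param rho density, kg/m^3.
#' @param beta_unit time unit of `beta` (informational tag).
#' @return a `linear_viscoelastic_params` object.
#' @export
linear_viscoelastic_params <- function(G0, Ginf, K, beta, rho,
                                       beta_unit = "1/ms") {
  stopifnot(G0 >= Ginf, Ginf > 0, K > 0, beta >= 0, rho > 0)
  structure(list(G0 = G0, Ginf = Ginf, K = K, beta = beta, rho = rho,
                 beta_unit = beta_unit),
            class = c("linear_viscoelastic_params", "material_params"))
}

#' Polynomial hyperelastic material parameters
#'
#' Strain energy `W(J1, J2, J) = sum_pq Cpq (J1-3)^p (J2-3)^q + WH(J)`
#' over the first-invariant / second-invariant powers, with volumetric
#' term `WH(J) = K/2 (J-1)^2`. The bulk modulus is derived from
#' near-incompressibility: `mu = 2 (C10 + C01)` and
#' `K = 2 mu (1 + nu) / (3 (1 - 2 nu))`.
#'
#' @param coefficients data frame with columns `p`, `q`, `C` (MPa); at
#'   least one nonzero `C`.
#' @param nu Poisson ratio (near 0.5 for soft tissue).
#' @param rho density, kg/m^3.
#' @param prony optional data frame with columns `G`, `tau` (s): shear
#'   relaxation coefficients stored and evaluated exactly as printed,
#'   `G(t) = sum_k Gk exp(-t / tauk)`.
#' @return a `polynomial_hyperelastic_params` object.
#' @export
polynomial_hyperelastic_params <- function(coefficients, nu, rho,
                                           prony = NULL) {
  stopifnot(all(c("p", "q", "C") %in% names(coefficients)),
            any(coefficients$C != 0), nu > -1, nu < 0.5, rho > 0)
  if (!is.null(prony)) {
    stopifnot(all(c("G", "tau") %in% names(prony)), all(prony$tau > 0))
  }
  mu <- 2 * sum(coefficients$C[(coefficients$p + coefficients$q) == 1L])
  K <- 2 * mu * (1 + nu) / (3 * (1 - 2 * nu))
  structure(list(coefficients = as.data.frame(coefficients), nu = nu,
                 rho = rho, prony = prony, mu = mu, K = K),
            class = c("polynomial_hyperelastic_params", "material_params"))
}

#' Hyper-viscoelastic brain tissue parameters
#'
#' Neo-Hookean strain energy `W = mu/2 (I1 - 3) + K/2 (J - 1)^2` with
#' normalized Prony shear relaxation
#' `G(t) = Ginf + sum_i Gi exp(-t / taui)`, so `G(0) = Ginf + sum Gi`
#' should equal 1 (checked within 2%). The printed long-term modulus is
#' cross-checked against `mu0 * Ginf` within 3%.
#'
#' @param mu0 instantaneous shear modulus, MPa.
#' @param muinf long-term shear modulus, MPa; `mu0 > muinf > 0`.
#' @param Ginf normalized long-term Prony coefficient.
#' @param prony data frame with columns `G` (normalized), `tau` (s).
#' @param K bulk modulus, MPa.
#' @param rho density, kg/m^3.
#' @return a `hyper_viscoelastic_params` object.
#' @export
hyper_viscoelastic_params <- function(mu0, muinf, Ginf, prony, K, rho) {
  stopifnot(mu0 > muinf, muinf > 0, Ginf > 0, K > 0, rho > 0,
            all(c("G", "tau") %in% names(prony)), all(prony$tau > 0))
  g0 <- Ginf + sum(prony$G)
  if (abs(g0 - 1) > 0.02) {
    stop("normalized Prony series must sum to 1 at t = 0 (within 2%); got ",
         signif(g0, 4L))
  }
  if (abs(mu0 * Ginf - muinf) / muinf > 0.03) {
    stop("inconsistent brain parameters: mu0 * Ginf = ",
         signif(mu0 * Ginf, 4L), " MPa vs muinf = ", muinf, " MPa (> 3%)")
  }
  structure(list(mu0 = mu0, muinf = muinf, Ginf = Ginf,
                 prony = as.data.frame(prony), K = K, rho = rho),
            class = c("hyper_viscoelastic_params", "material_params"))
}

#' Hill-type muscle parameters
#'
#' Total force is active plus passive. The active part is
#' `Fmax * fFL(L) * fFV(v) * A(t)` with `Fmax = sigma_max * pcsa`; the
#' passive part follows the exponential stretch law
#' `Fmax / (exp(Ksh) - 1) * (exp(Ksh / Lmax * (L / Lrest - 1)) - 1)` for
#' `L > Lrest`, zero otherwise. The resting length is muscle volume
#' divided by PCSA and the maximum contraction velocity is 10 resting
#' lengths per second.
#'
#' @param pcsa physiological cross-sectional area, mm^2.
#' @param volume muscle volume, mm^3.
#' @param sigma_max maximum isometric muscle stress, MPa (default 0.3).
#' @param ksh passive shape constant (dimensionless, default 3).
#' @param lmax maximum passive stretch ratio (default 1.5).
#' @param fl_width Gaussian force-length width parameter (default 0.5).
#' @param fv_shape Hill force-velocity shape parameter (default 0.25).
#' @return a `hill_muscle_params` object with derived `lrest` (mm),
#'   `fmax` (N) and `vmax` (mm/s).
#' @export
hill_muscle_params <- function(pcsa, volume, sigma_max = 0.3, ksh = 3,
                               lmax = 1.5, fl_width = 0.5,
                               fv_shape = 0.25) {
  stopifnot(pcsa > 0, volume > 0, sigma_max > 0, ksh > 0, lmax > 1,
            fl_width > 0, fv_shape > 0)
  lrest <- volume / pcsa
  structure(list(pcsa = pcsa, volume = volume, sigma_max = sigma_max,
                 ksh = ksh, lmax = lmax, fl_width = fl_width,
                 fv_shape = fv_shape, lrest = lrest,
                 fmax = sigma_max * pcsa, vmax = 10 * lrest),
            class = c("hill_muscle_params", "material_params"))
}

#' Linear ligament spring parameters
#' @param k spring stiffness, N/mm, `>= 0`.
#' @return a `ligament_spring_params` object.
#' @export
ligament_spring_params <- function(k) {
  stopifnot(k >= 0)
  structure(list(k = k),
            class = c("ligament_spring_params", "material_params"))
}

#' Strain-based element erosion rule
#'
#' Elements whose maximum principal Green-Lagrange strain exceeds the
#' threshold are marked eroded (removed from the simulation); the scalp
#' default is 60% strain.
#'
#' @param strain_threshold dimensionless failure strain, > 0 (default
#'   0.60).
#' @return an `erosion_rule` object.
#' @export
erosion_rule <- function(strain_threshold = 0.60) {
  stopifnot(strain_threshold > 0)
  structure(list(strain_threshold = strain_threshold,
                 strain_measure = "max-principal-Green-Lagrange"),
            class = "erosion_rule")
}

#' @export
print.material_params <- function(x, ...) {
  cat("<", class(x)[1L], ">\n", sep = "")
  flat <- x[!vapply(x, is.data.frame, logical(1L))]
  utils::str(flat, give.attr = FALSE, no.list = TRUE)
  if (!is.null(x$prony)) { cat("  prony:\n"); print(x$prony) }
  if (!is.null(x$coefficients)) { cat("  coefficients:\n")
    print(x$coefficients) }
  invisible(x)
}

# ---- relaxation modulus ------------------------------------------------

#' Shear relaxation modulus G(t)
#'
#' Exact closed-form evaluation, vectorized over `t`:
#' linear viscoelastic materials use
#' `G(t) = Ginf + (G0 - Ginf) exp(-beta t)` (MPa, `t` in the unit of
#' `beta`); hyper-viscoelastic brain materials use the normalized series
#' `G(t) = Ginf + sum Gi exp(-t / taui)` (dimensionless, `t` in seconds;
#' multiply by `mu0` for a modulus); polynomial materials with a Prony
#' table use `G(t) = sum Gk exp(-t / tauk)` with the coefficients exactly
#' as tabulated.
#'
#' @param params a parameter object carrying relaxation data.
#' @param t non-negative times.
#' @return modulus values, same length as `t`.
#' @export
relaxation_modulus <- function(params, t) {
  if (any(t < 0)) stop("relaxation time must be non-negative")
  UseMethod("relaxation_modulus")
}

#' @export
relaxation_modulus.linear_viscoelastic_params <- function(params, t) {
  if (any(t < 0)) stop("relaxation time must be non-negative")
  params$Ginf + (params$G0 - params$Ginf) * exp(-params$beta * t)
}

#' @export
relaxation_modulus.hyper_viscoelastic_params <- function(params, t) {
  if (any(t < 0)) stop("relaxation time must be non-negative")
  out <- rep(params$Ginf, length(t))
  for (i in seq_len(nrow(params$prony))) {
    out <- out + params$prony$G[i] * exp(-t / params$prony$tau[i])
  }
  out
}

#' @export
relaxation_modulus.polynomial_hyperelastic_params <- function(params, t) {
  if (any(t < 0)) stop("relaxation time must be non-negative")
  if (is.null(params$prony)) {
    stop("material has no Prony relaxation data")
  }
  out <- rep(0, length(t))
  for (i in seq_len(nrow(params$prony))) {
    out <- out + params$prony$G[i] * exp(-t / params$prony$tau[i])
  }
  out
}

# ---- strain energy and uniaxial stress --------------------------------

#' Strain energy density W
#'
#' Evaluates the stored strain-energy function at the given deformation
#' invariants. Hyper-viscoelastic (neo-Hookean) materials use
#' `W = mu/2 (I1 - 3) + K/2 (J - 1)^2` with `mu = mu0`; polynomial
#' materials use `sum Cpq (J1-3)^p (J2-3)^q + K/2 (J-1)^2`.
#'
#' @param params a hyperelastic parameter object.
#' @param I1 first deviatoric invariant (called J1 in the polynomial
#'   form).
#' @param J2 second invariant (polynomial materials; ignored otherwise).
#' @param J volume ratio, > 0.
#' @return energy density in MPa (mJ/mm^3).
#' @export
strain_energy <- function(params, I1, J2 = 3, J = 1) {
  if (any(J <= 0)) stop("volume ratio J must be positive")
  UseMethod("strain_energy")
}

#' @export
strain_energy.hyper_viscoelastic_params <- function(params, I1, J2 = 3,
                                                    J = 1) {
  if (any(J <= 0)) stop("volume ratio J must be positive")
  params$mu0 / 2 * (I1 - 3) + params$K / 2 * (J - 1)^2
}

#' @export
strain_energy.polynomial_hyperelastic_params <- function(params, I1,
                                                         J2 = 3, J = 1) {
  if (any(J <= 0)) stop("volume ratio J must be positive")
  co <- params$coefficients
  dev <- 0
  for (i in seq_len(nrow(co))) {
    dev <- dev + co$C[i] * (I1 - 3)^co$p[i] * (J2 - 3)^co$q[i]
  }
  dev + params$K / 2 * (J - 1)^2
}

#' Uniaxial Cauchy stress under isochoric stretch
#'
#' For an incompressible uniaxial deformation with stretch `lambda`
#' (deformation gradient `diag(lambda, lambda^-1/2, lambda^-1/2)`, J = 1)
#' the axial Cauchy stress is `sigma = lambda * dW/dlambda`, evaluated
#' analytically through the invariant derivatives
#' `dI1/dlambda = 2 lambda - 2 / lambda^2` and
#' `dI2/dlambda = 2 - 2 / lambda^3`.
#'
#' @param params a hyperelastic parameter object.
#' @param lambda stretch ratio, > 0 (vectorized).
#' @return Cauchy stress in MPa.
#' @export
uniaxial_cauchy_stress <- function(params, lambda) {
  if (any(lambda <= 0)) stop("stretch ratio must be positive")
  UseMethod("uniaxial_cauchy_stress")
}

#' @export
uniaxial_cauchy_stress.hyper_viscoelastic_params <- function(params,
                                                             lambda) {
  if (any(lambda <= 0)) stop("stretch ratio must be positive")
  params$mu0 * (lambda^2 - 1 / lambda)
}

#' @export
uniaxial_cauchy_stress.polynomial_hyperelastic_params <- function(params,
                                                                  lambda) {
  if (any(lambda <= 0)) stop("stretch ratio must be positive")
  co <- params$coefficients
  I1 <- lambda^2 + 2 / lambda
  I2 <- 2 * lambda + 1 / lambda^2
  dI1 <- 2 * lambda - 2 / lambda^2
  dI2 <- 2 - 2 / lambda^3
  dW <- 0
  for (i in seq_len(nrow(co))) {
    p <- co$p[i]; q <- co$q[i]; C <- co$C[i]
    if (p > 0) dW <- dW + C * p * (I1 - 3)^(p - 1) * (I2 - 3)^q * dI1
    if (q > 0) dW <- dW + C * q * (I1 - 3)^p * (I2 - 3)^(q - 1) * dI2
  }
  lambda * dW
}

# ---- muscle, ligament, erosion ----------------------------------------

#' Hill-type muscle force
#'
#' `F = Fmax * fFL(L) * fFV(v) * A + Fpassive(L)`. The force-length and
#' force-velocity shapes are not standardized across sources, so
#' configurable standard forms are used: a Gaussian force-length
#' `exp(-((L/Lrest - 1) / fl_width)^2)` and the classic Hill hyperbola
#' force-velocity `(1 + u) / (1 - u / a)` for shortening (`u = v / vmax
#' <= 0`, clamped at 0 below `u = -1`) with the standard eccentric
#' plateau `(1.8 - 0.8 (1 - u) / (1 + 7.56 u / a))` for lengthening,
#' shape `a = fv_shape`. The passive force follows the exponential
#' stretch law of [hill_muscle_params()], zero at or below resting
#' length.
#'
#' @param params a [hill_muscle_params()] object.
#' @param L current muscle length, mm, > 0.
#' @param v lengthening velocity, mm/s (negative = shortening).
#' @param activation activation level in [0, 1].
#' @return list with `total`, `active`, `passive` forces in N.
#' @export
hill_muscle_force <- function(params, L, v = 0, activation = 0) {
  stopifnot(inherits(params, "hill_muscle_params"), all(L > 0))
  if (any(activation < 0 | activation > 1)) {
    stop("activation must lie in [0, 1]")
  }
  lr <- L / params$lrest
  ffl <- exp(-((lr - 1) / params$fl_width)^2)
  u <- v / params$vmax
  a <- params$fv_shape
  ffv <- ifelse(u <= 0,
                pmax(0, (1 + u) / (1 - u / a)),
                1.8 - 0.8 * (1 - u) / (1 + 7.56 * u / a))
  active <- params$fmax * ffl * ffv * activation
  passive <- ifelse(lr > 1,
                    params$fmax / (exp(params$ksh) - 1) *
                      (exp(params$ksh / params$lmax * (lr - 1)) - 1),
                    0)
  list(total = active + passive, active = active, passive = passive)
}

#' Linear ligament spring force
#'
#' `F = k x`. By default the spring is tension-only: negative extensions
#' (compression) carry no force.
#'
#' @param params a [ligament_spring_params()] object.
#' @param x extension, mm (vectorized).
#' @param tension_only zero force for `x < 0` (default `TRUE`).
#' @return force in N.
#' @export
ligament_force <- function(params, x, tension_only = TRUE) {
  stopifnot(inherits(params, "ligament_spring_params"))
  f <- params$k * x
  if (tension_only) f[x < 0] <- 0
  f
}

#' Strain-based erosion check
#'
#' Computes the maximum principal strain of each symmetric Green-Lagrange
#' tensor and flags those exceeding the rule's threshold. A single tensor
#' returns its flag and governing strain; a list (per-element field)
#' returns the eroded and surviving element id lists.
#'
#' @param strain symmetric 3 x 3 matrix or a list of them.
#' @param rule an [erosion_rule()].
#' @return for one tensor: list `eroded`, `strain`; for a field: list
#'   `eroded_ids`, `surviving_ids`, `strains`.
#' @export
erosion_check <- function(strain, rule = erosion_rule()) {
  stopifnot(inherits(rule, "erosion_rule"))
  if (is.list(strain)) {
    mps <- max_principal_strain(strain)$field
    er <- mps > rule$strain_threshold
    return(list(eroded_ids = which(er), surviving_ids = which(!er),
                strains = mps))
  }
  s <- max_principal_strain(strain)
  list(eroded = s > rule$strain_threshold, strain = s)
}

# ---- registry ----------------------------------------------------------

#' Material parameter registry for the head-neck model
#'
#' Named presets for every modelled structure, holding the published
#' parameter values converted to the internal MPa convention: scalp
#' (linear viscoelastic, G0 = 1.70 MPa, Ginf = 0.68 MPa, K = 20 MPa,
#' beta = 3e-5), skull / dura mater / pia mater / vertebrae (linear
#' elastic; E = 15 GPa, 5 MPa, 2.3 GPa, 8 GPa), CSF (one-term polynomial
#' hyperelastic, C10 = 0.0112 MPa, nu = 0.499), white and gray matter
#' (hyper-viscoelastic; mu0 = 7.63 / 5.06 kPa with two-term normalized
#' Prony series), intervertebral disks (polynomial hyperelastic with a
#' three-term Prony table stored as printed), default muscle (Hill-type,
#' sigma_max = 0.3 MPa) and a ligament stiffness placeholder.
#' Construction runs the registry self-checks (Prony normalization,
#' mu0 * Ginf vs muinf consistency).
#'
#' @return named list of `material_params` objects.
#' @export
material_registry <- function() {
  list(
    scalp = linear_viscoelastic_params(G0 = 1.70, Ginf = 0.68, K = 20,
                                       beta = 0.00003, rho = 1100,
                                       beta_unit = "1/ms"),
    skull = linear_elastic_params(E = 15000, nu = 0.21, rho = 1800),
    dura_mater = linear_elastic_params(E = 5, nu = 0.45, rho = 1200),
    pia_mater = linear_elastic_params(E = 2300, nu = 0.45, rho = 1000),
    vertebrae = linear_elastic_params(E = 8000, nu = 0.22, rho = 1200),
    csf = polynomial_hyperelastic_params(
      coefficients = data.frame(p = 1L, q = 0L, C = 0.0112),
      nu = 0.499, rho = 1000),
    white_matter = hyper_viscoelastic_params(
      mu0 = 0.00763, muinf = 0.00158, Ginf = 0.21,
      prony = data.frame(G = c(0.57, 0.22), tau = c(0.02, 0.31)),
      K = 2190, rho = 1060),
    gray_matter = hyper_viscoelastic_params(
      mu0 = 0.00506, muinf = 0.00148, Ginf = 0.29,
      prony = data.frame(G = c(0.50, 0.20), tau = c(0.015, 0.30)),
      K = 2190, rho = 1060),
    disk = polynomial_hyperelastic_params(
      coefficients = data.frame(p = c(1L, 0L), q = c(0L, 1L),
                                C = c(0.15, 0.03)),
      nu = 0.499, rho = 1000,
      prony = data.frame(G = c(1.70, 1.20, 2.00),
                         tau = c(11.76, 1.10, 0.13))),
    muscle_default = hill_muscle_params(pcsa = 100, volume = 10000),
    ligament_default = ligament_spring_params(k = 10))
}

#' Look up one registry preset by name
#' @param name preset name, e.g. `"white_matter"`.
#' @param registry a registry list (default [material_registry()]).
#' @return the preset's `material_params` object.
#' @export
material_preset <- function(name, registry = material_registry()) {
  if (!name %in% names(registry)) {
    stop("unknown material preset '", name, "'; available: ",
         toString(names(registry)))
  }
  registry[[name]]
}

# ---- config-file serialization ----------------------------------------

#' Write / read a material registry as a YAML config file
#'
#' Every preset is serialized with its class tag and exact parameter
#' values; reading reconstructs the parameter objects through their
#' constructors (re-running all validity checks), so a round trip
#' preserves all values exactly.
#'
#' @param registry named list of `material_params` objects.
#' @param path YAML file path.
#' @export
write_materials_yaml <- function(registry, path) {
  ser <- lapply(registry, function(p) {
    out <- lapply(unclass(p), function(v) {
      if (is.data.frame(v)) as.list(v) else v
    })
    out$.type <- class(p)[1L]
    out
  })
  yaml::write_yaml(ser, path, precision = 15L)
  invisible(path)
}

#' @rdname write_materials_yaml
#' @return for the reader, the reconstructed registry list.
#' @export
read_materials_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(entry) {
    type <- entry$.type
    entry$.type <- NULL
    ctor <- switch(type,
                   linear_elastic_params = linear_elastic_params,
                   linear_viscoelastic_params = linear_viscoelastic_params,
                   polynomial_hyperelastic_params =
                     polynomial_hyperelastic_params,
                   hyper_viscoelastic_params = hyper_viscoelastic_params,
                   hill_muscle_params = hill_muscle_params,
                   ligament_spring_params = ligament_spring_params,
                   stop("unknown material type '", type, "' in ", path))
    for (fld in c("prony", "coefficients")) {
      if (!is.null(entry[[fld]])) entry[[fld]] <- as.data.frame(entry[[fld]])
    }
    drop <- switch(type,
                   polynomial_hyperelastic_params = c("mu", "K"),
                   hill_muscle_params = c("lrest", "fmax", "vmax"),
                   character())
    do.call(ctor, entry[setdiff(names(entry), drop)])
  })
}
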