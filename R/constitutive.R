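# Leaflet and chordae constitutive models: anisotropic fiber-reinforced
# hyperelasticity (modified Holzapfel-Gasser-Ogden form) for the mitral
# leaflets and an incompressible Ogden law for the chordae tendineae.

#' Material parameters for the modified Holzapfel-Gasser-Ogden leaflet model
#'
#' Bundles the constants of the fiber-reinforced strain-energy function used
#' for mitral leaflet tissue,
#' \deqn{W = C_{10}\{\exp[C_{01}(\bar I_1 - 3)] - 1\}
#'   + \frac{k_1}{2 k_2}\sum_{i=1}^{2}\{\exp(k_2[\kappa\bar I_1 +
#'     (1-3\kappa)\bar I_{4i} - 1]^2) - 1\} + \frac{1}{D}(J-1)^2.}
#' \eqn{C_{10}} (MPa) and \eqn{C_{01}} (-) describe the isotropic matrix,
#' \eqn{k_1} (MPa) and \eqn{k_2} (-) the collagen fiber response,
#' \eqn{\kappa \in [0, 1/3]} the in-plane fiber dispersion
#' (\eqn{\kappa = 1/3} is a fully dispersed, isotropic fiber distribution)
#' and \eqn{D} (MPa^-1) the volumetric penalty enforcing
#' near-incompressibility.
#'
#' @param c10 Matrix stiffness scale, MPa. Must be positive.
#' @param c01 Matrix exponential shape factor, dimensionless.
#' @param k1 Fiber stiffness scale, MPa. Must be non-negative.
#' @param k2 Fiber exponential shape factor, dimensionless, positive.
#' @param kappa Fiber dispersion, in `[0, 1/3]`.
#' @param d_incomp Volumetric compliance `D`, MPa^-1, positive. Smaller
#'   values penalise volume change more strongly.
#' @param fiber_angle_deg Half-angle (degrees) between each of the two
#'   symmetric fiber families and the local circumferential axis.
#' @param fiber_tension_only If `TRUE` (default) a fiber family contributes
#'   only when its dispersed pseudo-invariant argument
#'   \eqn{\kappa\bar I_1 + (1-3\kappa)\bar I_{4i} - 1} is positive, so
#'   collagen carries no compressive load.
#' @return An object of class `mhgo_params`.
#' @seealso [strain_energy_mhgo()], [stress_mhgo()], [fiber_directions()]
#' @examples
#' pars <- mhgo_params(c10 = 0.02, c01 = 5, k1 = 0.1, k2 = 10,
#'                     kappa = 0.1, d_incomp = 1e-3)
#' @export
mhgo_params <- function(c10, c01, k1, k2, kappa, d_incomp,
                        fiber_angle_deg = 40, fiber_tension_only = TRUE) {
  stopifnot(is.numeric(c10), is.numeric(c01), is.numeric(k1),
            is.numeric(k2), is.numeric(kappa), is.numeric(d_incomp))
  if (c10 <= 0) stop("mhgo_params: c10 must be positive", call. = FALSE)
  if (k1 < 0) stop("mhgo_params: k1 must be non-negative", call. = FALSE)
  if (k2 <= 0) stop("mhgo_params: k2 must be positive", call. = FALSE)
  if (kappa < 0 || kappa > 1 / 3 + 1e-12)
    stop("mhgo_params: kappa must lie in [0, 1/3]", call. = FALSE)
  if (d_incomp <= 0) stop("mhgo_params: d_incomp must be positive", call. = FALSE)
  structure(list(c10 = c10, c01 = c01, k1 = k1, k2 = k2,
                 kappa = min(kappa, 1 / 3), d_incomp = d_incomp,
                 fiber_angle_deg = fiber_angle_deg,
                 fiber_tension_only = isTRUE(fiber_tension_only)),
            class = "mhgo_params")
}

#' @export
print.mhgo_params <- function(x, ...) {
  cat("MHGO leaflet material parameters\n")
  cat(sprintf("  C10 = %g MPa, C01 = %g, k1 = %g MPa, k2 = %g\n",
              x$c10, x$c01, x$k1, x$k2))
  cat(sprintf("  kappa = %g, D = %g MPa^-1, fiber half-angle = %g deg\n",
              x$kappa, x$d_incomp, x$fiber_angle_deg))
  cat(sprintf("  fiber tension switch: %s\n",
              if (x$fiber_tension_only) "on" else "off"))
  invisible(x)
}

#' Two symmetric fiber families in the local leaflet frame
#'
#' Builds the two unit fiber directions at `+angle` and `-angle` about the
#' local circumferential axis (x) within the leaflet plane (x-y); z is the
#' leaflet normal.
#'
#' @param angle_deg Half-angle between each family and the circumferential
#'   axis, degrees.
#' @return A 3 x 2 matrix whose columns are unit vectors.
#' @export
fiber_directions <- function(angle_deg) {
  a <- angle_deg * pi / 180
  cbind(c(cos(a), sin(a), 0), c(cos(a), -sin(a), 0))
}

#' Kinematic state of a leaflet material point
#'
#' @param F 3 x 3 deformation gradient, `det(F) > 0`.
#' @param fiber_dirs 3 x 2 matrix of the two reference fiber directions
#'   (unit columns), e.g. from [fiber_directions()].
#' @return An object of class `deformation_state`.
#' @export
deformation_state <- function(F, fiber_dirs = fiber_directions(40)) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3, 3)) || any(!is.finite(F)))
    stop("deformation_state: F must be a finite 3x3 matrix", call. = FALSE)
  if (det(F) <= 0)
    stop("deformation_state: det(F) must be positive (invalid deformation)",
         call. = FALSE)
  fiber_dirs <- as.matrix(fiber_dirs)
  if (!all(dim(fiber_dirs) == c(3, 2)))
    stop("deformation_state: fiber_dirs must be a 3x2 matrix", call. = FALSE)
  nrm <- sqrt(colSums(fiber_dirs^2))
  if (any(abs(nrm - 1) > 1e-12))
    stop("deformation_state: fiber directions must have unit norm", call. = FALSE)
  structure(list(F = F, fiber_dirs = fiber_dirs), class = "deformation_state")
}

#' Deviatoric strain invariants of a deformation state
#'
#' Computes the isochoric invariants driving the leaflet strain energy:
#' \eqn{\bar I_1 = J^{-2/3}\mathrm{tr}(F^T F)},
#' \eqn{\bar I_{4i} = J^{-2/3}\, m_i \cdot (F^T F)\, m_i} for the two fiber
#' directions, and \eqn{J = \det F}.
#'
#' @param state A [deformation_state()].
#' @return A list with `i1bar` (scalar), `i4bar` (length-2 numeric) and
#'   `jdet` (scalar).
#' @examples
#' s <- deformation_state(diag(3))
#' deviatoric_invariants(s)  # i1bar = 3, i4bar = c(1, 1), jdet = 1
#' @export
deviatoric_invariants <- function(state) {
  stopifnot(inherits(state, "deformation_state"))
  F <- state$F
  J <- det(F)
  C <- crossprod(F)
  jm23 <- J^(-2 / 3)
  m <- state$fiber_dirs
  i4 <- vapply(1:2, function(i) jm23 * drop(m[, i] %*% C %*% m[, i]), 0)
  list(i1bar = jm23 * sum(diag(C)), i4bar = i4, jdet = J)
}

# Energy derivatives shared by strain_energy_mhgo and stress_mhgo.
# Returns invariants, the fiber arguments E_i and which families are active.
.mhgo_terms <- function(state, params) {
  inv <- deviatoric_invariants(state)
  e <- params$kappa * inv$i1bar + (1 - 3 * params$kappa) * inv$i4bar - 1
  active <- if (params$fiber_tension_only) e > 0 else rep(TRUE, 2)
  list(inv = inv, e = e, active = active)
}

#' Strain energy of the leaflet material model
#'
#' Evaluates the fiber-reinforced strain-energy density (MPa, per unit
#' reference volume) described in [mhgo_params()]. With the fiber tension
#' switch on, a fiber family is excluded while its dispersed pseudo-invariant
#' argument is non-positive (compressed collagen).
#'
#' @inheritParams deviatoric_invariants
#' @param params An [mhgo_params()] object.
#' @return Scalar energy density, MPa.
#' @export
strain_energy_mhgo <- function(state, params) {
  stopifnot(inherits(params, "mhgo_params"))
  t <- .mhgo_terms(state, params)
  w_matrix <- params$c10 * (exp(params$c01 * (t$inv$i1bar - 3)) - 1)
  w_fiber <- sum(ifelse(t$active,
                        params$k1 / (2 * params$k2) *
                          (exp(params$k2 * t$e^2) - 1), 0))
  w_vol <- (1 / params$d_incomp) * (t$inv$jdet - 1)^2
  w_matrix + w_fiber + w_vol
}

#' Stress of the leaflet material model
#'
#' Computes the second Piola-Kirchhoff stress analytically as
#' \eqn{S = 2\,\partial W/\partial C} and pushes it forward to the Cauchy
#' stress \eqn{\sigma = J^{-1} F S F^T}.
#'
#' @inheritParams strain_energy_mhgo
#' @return An object of class `stress_result`: list with `cauchy` and `pk2`
#'   (symmetric 3 x 3 matrices, MPa) and `energy` (scalar, MPa).
#' @examples
#' pars <- mhgo_params(0.02, 5, 0.1, 10, 0.1, 1e-3)
#' stress_mhgo(deformation_state(diag(3)), pars)$cauchy  # zero at reference
#' @export
stress_mhgo <- function(state, params) {
  stopifnot(inherits(params, "mhgo_params"))
  F <- state$F
  t <- .mhgo_terms(state, params)
  inv <- t$inv
  J <- inv$jdet
  C <- crossprod(F)
  Ci <- solve(C)
  jm23 <- J^(-2 / 3)
  I3 <- diag(3)

  # scalar energy derivatives w.r.t. the invariants
  psi <- ifelse(t$active, params$k1 * t$e * exp(params$k2 * t$e^2), 0)
  dW_dI1 <- params$c10 * params$c01 * exp(params$c01 * (inv$i1bar - 3)) +
    sum(psi) * params$kappa
  dW_dI4 <- psi * (1 - 3 * params$kappa)
  dW_dJ <- (2 / params$d_incomp) * (J - 1)

  # invariant derivatives w.r.t. C
  dI1_dC <- jm23 * I3 - (inv$i1bar / 3) * Ci
  S <- 2 * dW_dI1 * dI1_dC
  for (i in 1:2) {
    m <- state$fiber_dirs[, i]
    dI4_dC <- jm23 * tcrossprod(m) - (inv$i4bar[i] / 3) * Ci
    S <- S + 2 * dW_dI4[i] * dI4_dC
  }
  S <- S + dW_dJ * J * Ci

  S <- (S + t(S)) / 2
  cauchy <- (F %*% S %*% t(F)) / J
  cauchy <- (cauchy + t(cauchy)) / 2
  structure(list(cauchy = cauchy, pk2 = S,
                 energy = strain_energy_mhgo(state, params)),
            class = "stress_result")
}

#' @export
print.stress_result <- function(x, ...) {
  cat("Leaflet stress state (MPa)\n")
  cat(sprintf("  strain energy: %.6g MPa\n", x$energy))
  cat(sprintf("  max principal Cauchy stress: %.6g MPa\n",
              max_principal_stress(x$cauchy)))
  invisible(x)
}

#' Ogden parameters for chordae tendineae
#'
#' The chordae are modelled as an incompressible isotropic Ogden solid with
#' strain energy \eqn{W = \sum_p \mu_p/\alpha_p\,(\lambda_1^{\alpha_p} +
#' \lambda_2^{\alpha_p} + \lambda_3^{\alpha_p} - 3)}. The ground-state shear
#' modulus \eqn{\mu_0 = \frac12\sum_p \mu_p\alpha_p} must be positive.
#'
#' @param mu Numeric vector of moduli \eqn{\mu_p}, MPa.
#' @param alpha Numeric vector of exponents \eqn{\alpha_p}, same length.
#' @return An object of class `ogden_params`.
#' @export
ogden_params <- function(mu, alpha) {
  stopifnot(is.numeric(mu), is.numeric(alpha), length(mu) == length(alpha),
            length(mu) >= 1)
  if (sum(mu * alpha) <= 0)
    stop("ogden_params: sum(mu * alpha) must be positive", call. = FALSE)
  structure(list(mu = as.numeric(mu), alpha = as.numeric(alpha)),
            class = "ogden_params")
}

#' @export
print.ogden_params <- function(x, ...) {
  cat(sprintf("Ogden chordae model, %d term(s); mu0 = %.4g MPa\n",
              length(x$mu), sum(x$mu * x$alpha) / 2))
  for (p in seq_along(x$mu))
    cat(sprintf("  mu_%d = %g MPa, alpha_%d = %g\n", p, x$mu[p], p, x$alpha[p]))
  invisible(x)
}

#' Uniaxial nominal Ogden stress of an incompressible chord
#'
#' First Piola-Kirchhoff (nominal) stress of an incompressible uniaxial
#' Ogden bar at stretch `lambda`:
#' \eqn{P(\lambda) = \sum_p \mu_p(\lambda^{\alpha_p-1} -
#' \lambda^{-\alpha_p/2-1})}. For a one-term model with \eqn{\alpha = 2}
#' this reduces to the neo-Hookean \eqn{\mu(\lambda - \lambda^{-2})}.
#'
#' @param stretch Axial stretch(es), positive.
#' @param params An [ogden_params()] object.
#' @return Nominal stress, MPa (vectorised over `stretch`).
#' @export
ogden_nominal_stress <- function(stretch, params) {
  stopifnot(inherits(params, "ogden_params"))
  if (any(stretch <= 0))
    stop("ogden_nominal_stress: stretch must be positive (invalid kinematics)",
         call. = FALSE)
  vapply(stretch, function(l)
    sum(params$mu * (l^(params$alpha - 1) - l^(-params$alpha / 2 - 1))), 0)
}

#' Axial force carried by a tension-only chord
#'
#' Force (N) in a chordal truss element: reference cross-section times the
#' uniaxial incompressible nominal Ogden stress. Chordae are tension-only
#' cables; a slack chord (`stretch <= 1`) carries no force.
#'
#' @inheritParams ogden_nominal_stress
#' @param area0 Reference cross-sectional area, mm^2, positive.
#' @return Force in newtons (MPa times mm^2), vectorised over `stretch`.
#' @examples
#' nh <- ogden_params(mu = 1, alpha = 2)          # neo-Hookean limit
#' ogden_chord_force(1.5, nh, area0 = 1)          # 1.5 - 1.5^-2
#' @export
ogden_chord_force <- function(stretch, params, area0) {
  if (any(stretch <= 0))
    stop("ogden_chord_force: stretch must be positive (invalid kinematics)",
         call. = FALSE)
  if (area0 <= 0) stop("ogden_chord_force: area0 must be positive", call. = FALSE)
  f <- area0 * ogden_nominal_stress(pmax(stretch, 1), params)
  f[stretch <= 1] <- 0
  f
}

# Derivative dF/dlambda of the chord force, used by the truss tangent.
.ogden_chord_stiffness <- function(stretch, params, area0) {
  if (stretch <= 1) return(0)
  a <- params$alpha
  area0 * sum(params$mu * ((a - 1) * stretch^(a - 2) +
                             (a / 2 + 1) * stretch^(-a / 2 - 2)))
}

#' Maximum principal stress of a symmetric tensor
#'
#' Largest eigenvalue of a symmetric 3 x 3 stress tensor, the quantity
#' mapped over the leaflets when comparing loading between valve models.
#'
#' @param stress Symmetric 3 x 3 matrix (MPa).
#' @param tol Allowed asymmetry, relative to the largest entry.
#' @return Scalar largest eigenvalue.
#' @export
max_principal_stress <- function(stress, tol = 1e-8) {
  stress <- as.matrix(stress)
  stopifnot(all(dim(stress) == c(3, 3)))
  scale <- max(abs(stress), 1e-300)
  if (max(abs(stress - t(stress))) > tol * scale)
    stop("max_principal_stress: tensor is not symmetric within tolerance",
         call. = FALSE)
  max(eigen((stress + t(stress)) / 2, symmetric = TRUE,
            only.values = TRUE)$values)
}

#' Mean of a quantity over a labelled leaflet sub-region
#'
#' Arithmetic mean of sampled values over one of the labelled leaflet
#' sub-regions (e.g. the AML or a PML scallop). Sampling points flagged as
#' belonging to the coaptation zone or the annular attachment are excluded
#' from the average.
#'
#' @param values Numeric vector of point values.
#' @param region_labels Character vector of region labels, same length.
#' @param region Region label to average over.
#' @param exclude Labels (or an optional logical mask via `exclude_mask`)
#'   removed before averaging; defaults to coaptation and annulus flags.
#' @param exclude_mask Optional logical vector marking excluded points.
#' @return Scalar mean.
#' @export
region_average <- function(values, region_labels, region,
                           exclude = c("coaptation", "annulus"),
                           exclude_mask = NULL) {
  stopifnot(length(values) == length(region_labels))
  keep <- region_labels == region & !(region_labels %in% exclude)
  if (!is.null(exclude_mask)) {
    stopifnot(length(exclude_mask) == length(values))
    keep <- keep & !exclude_mask
  }
  if (!any(keep))
    stop(sprintf("region_average: no values in region '%s' after exclusions",
                 region), call. = FALSE)
  mean(values[keep])
}

#' Read leaflet and chordae material parameters from JSON
#'
#' Expects keys `c10, c01, k1, k2, kappa, d_incomp, fiber_angle_deg` for the
#' leaflet model (MPa and degrees) and `ogden`: a list of
#' `{mu_MPa, alpha}` terms for the chordae.
#'
#' @param path Path to a JSON file.
#' @return List with elements `mhgo` ([mhgo_params()]) and
#'   `ogden` ([ogden_params()]).
#' @export
read_material_params <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("c10", "c01", "k1", "k2", "kappa", "d_incomp")
  if (!all(need %in% names(j)))
    stop("read_material_params: missing keys: ",
         paste(setdiff(need, names(j)), collapse = ", "), call. = FALSE)
  mh <- mhgo_params(j$c10, j$c01, j$k1, j$k2, j$kappa, j$d_incomp,
                    fiber_angle_deg = if (is.null(j$fiber_angle_deg)) 40
                    else j$fiber_angle_deg)
  og <- NULL
  if (!is.null(j$ogden)) og <- ogden_params(j$ogden$mu_MPa, j$ogden$alpha)
  list(mhgo = mh, ogden = og)
}

#' Example (non-study) material parameter set
#'
#' A documented example parameter set in the physiological ballpark for
#' mitral tissue, intended for demonstrations and tests. These are NOT
#' fitted experimental values; real analyses must supply their own
#' parameters (e.g. via [read_material_params()]).
#'
#' @return List with `mhgo` and `ogden` components.
#' @export
example_materials <- function() {
  list(mhgo = mhgo_params(c10 = 0.02, c01 = 5, k1 = 0.12, k2 = 15,
                          kappa = 0.08, d_incomp = 5e-4,
                          fiber_angle_deg = 40),
       ogden = ogden_params(mu = 0.18, alpha = 20))
}
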