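#' Modified Mooney-Rivlin material parameters
#'
#' Holds the constants of the modified Mooney-Rivlin strain-energy density
#' W_iso = c1(I1b - 3) + c2(I2b - 3) + D1[exp(D2(I1b - 3)) - 1], evaluated
#' on isochoric invariants, plus for vessel tissue the circumferential
#' fiber term (K1/K2)\{exp[K2(I4b - 1)^2] - 1\}. Defaults are the literature
#' constants for lipid, calcification and vessel/fibrous tissue used in
#' coronary plaque models (stress-like constants in kPa).
#'
#' @param tissue "vessel", "lipid" or "calcification".
#' @param c1,c2,D1,D2 isotropic constants (c1, c2, D1 in kPa; D2 unitless).
#' @param K1,K2 fiber constants (K1 kPa, K2 unitless); vessel only.
#' @param vol_penalty_factor bulk penalty kappa as a multiple of the
#'   tissue's initial shear-modulus scale (near-incompressibility).
#' @return A `material_params` list with derived `mu0` (kPa) and `kappa` (kPa).
#' @export
material_params <- function(tissue = c("vessel", "lipid", "calcification"),
                            c1 = NULL, c2 = NULL, D1 = NULL, D2 = NULL,
                            K1 = NULL, K2 = NULL,
                            vol_penalty_factor = 1000) {
  tissue <- match.arg(tissue)
  def <- switch(tissue,
    lipid         = list(c1 = 0.5,    c2 = 0,    D1 = 0.5,   D2 = 1.5,
                         K1 = NULL,  K2 = NULL),
    calcification = list(c1 = 92,     c2 = 0,    D1 = 36,    D2 = 2.0,
                         K1 = NULL,  K2 = NULL),
    vessel        = list(c1 = -262.6, c2 = 22.9, D1 = 125.9, D2 = 2.0,
                         K1 = 7.19,  K2 = 23.5))
  m <- list(tissue = tissue,
            c1 = c1 %||% def$c1, c2 = c2 %||% def$c2,
            D1 = D1 %||% def$D1, D2 = D2 %||% def$D2,
            K1 = if (tissue == "vessel") (K1 %||% def$K1) else NULL,
            K2 = if (tissue == "vessel") (K2 %||% def$K2) else NULL)
  if (m$D2 <= 0) stop("D2 must be > 0")
  # initial shear modulus 2(dW/dI1 + dW/dI2) at the identity
  m$mu0 <- 2 * (m$c1 + m$c2 + m$D1 * m$D2)
  if (m$mu0 <= 0) stop("non-positive initial shear modulus; check constants")
  m$kappa <- vol_penalty_factor * m$mu0
  class(m) <- "material_params"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default tissue material map
#'
#' @param vol_penalty_factor see [material_params()].
#' @return Named list with elements `vessel`, `lipid`, `calcification`.
#' @export
default_materials <- function(vol_penalty_factor = 1000) {
  list(vessel = material_params("vessel", vol_penalty_factor = vol_penalty_factor),
       lipid = material_params("lipid", vol_penalty_factor = vol_penalty_factor),
       calcification = material_params("calcification",
                                       vol_penalty_factor = vol_penalty_factor))
}

#' Finite-deformation kinematics from a deformation gradient
#'
#' Computes the right Cauchy-Green tensor C = F'F, its invariants I1, I2,
#' the fiber pseudo-invariant I4 = n.Cn along the unit direction `fiber`,
#' and the volume ratio J = det F.
#'
#' @param F 3 x 3 deformation gradient.
#' @param fiber length-3 unit vector (circumferential direction).
#' @return A `kinematics` list: F, C, I1, I2, I4, J, fiber.
#' @export
kinematics <- function(F, fiber = c(1, 0, 0)) {
  F <- matrix(as.numeric(F), 3L, 3L)
  fiber <- fiber / sqrt(sum(fiber^2))
  C <- crossprod(F)
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * C)) / 2
  I4 <- drop(crossprod(fiber, C %*% fiber))
  J <- det(F)
  if (J <= 0) stop("non-positive volume ratio J")
  structure(list(F = F, C = C, I1 = I1, I2 = I2, I4 = I4, J = J,
                 fiber = fiber), class = "kinematics")
}

#' Strain-energy density
#'
#' Evaluates the modified Mooney-Rivlin energy on isochoric invariants
#' (I1b = J^(-2/3) I1, I2b = J^(-4/3) I2, I4b = J^(-2/3) I4) plus the
#' volumetric penalty kappa/2 (J - 1)^2; the anisotropic fiber term is
#' added for vessel tissue only.
#'
#' @param kin a [kinematics()] object.
#' @param mat a [material_params()] object.
#' @param kappa volumetric penalty (kPa); defaults to `mat$kappa`.
#' @return Energy density in kPa.
#' @export
strain_energy <- function(kin, mat, kappa = mat$kappa) {
  J <- kin$J
  I1b <- J^(-2 / 3) * kin$I1
  I2b <- J^(-4 / 3) * kin$I2
  W <- mat$c1 * (I1b - 3) + mat$c2 * (I2b - 3) +
    mat$D1 * (exp(mat$D2 * (I1b - 3)) - 1)
  if (identical(mat$tissue, "vessel")) {
    I4b <- J^(-2 / 3) * kin$I4
    W <- W + mat$K1 / mat$K2 * (exp(mat$K2 * (I4b - 1)^2) - 1)
  }
  W + kappa / 2 * (J - 1)^2
}

#' Cauchy stress from kinematics (analytic constitutive derivative)
#'
#' Second Piola-Kirchhoff stress S = 2 dW/dC of the penalised split form,
#' pushed forward to Cauchy stress sigma = F S F' / J.
#'
#' @inheritParams strain_energy
#' @return List with `S` (second Piola-Kirchhoff, kPa) and `sigma`
#'   (Cauchy, kPa), both symmetric 3 x 3.
#' @export
stress_from_kinematics <- function(kin, mat, kappa = mat$kappa) {
  J <- kin$J; C <- kin$C
  Cinv <- solve(C)
  I1 <- kin$I1; I2 <- kin$I2; I4 <- kin$I4
  I1b <- J^(-2 / 3) * I1
  I2b <- J^(-4 / 3) * I2
  I4b <- J^(-2 / 3) * I4
  Id <- diag(3)
  w1 <- mat$c1 + mat$D1 * mat$D2 * exp(mat$D2 * (I1b - 3))
  S <- 2 * w1 * J^(-2 / 3) * (Id - I1 / 3 * Cinv) +
    2 * mat$c2 * J^(-4 / 3) * (I1 * Id - C - 2 * I2 / 3 * Cinv)
  if (identical(mat$tissue, "vessel")) {
    w4 <- 2 * mat$K1 * (I4b - 1) * exp(mat$K2 * (I4b - 1)^2)
    nn <- tcrossprod(kin$fiber)
    S <- S + 2 * w4 * J^(-2 / 3) * (nn - I4 / 3 * Cinv)
  }
  S <- S + kappa * (J - 1) * J * Cinv
  S <- (S + t(S)) / 2
  sigma <- kin$F %*% S %*% t(kin$F) / J
  list(S = S, sigma = (sigma + t(sigma)) / 2)
}
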