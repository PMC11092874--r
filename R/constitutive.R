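#' Material model specification
#'
#' Selects one of the three hyperelastic constitutive laws and fixes its known
#' parameters. The spatially varying unknown is the Young's modulus `E`
#' (Neo-Hookean), the first Mooney-Rivlin constant `mu1`, or the Gent shear
#' modulus `mu`; the remaining parameters (`nu`, `mu2`, `Jm`) are known,
#' spatially constant hyperparameters.
#'
#' The Mooney-Rivlin and Gent laws are used in their unconstrained 2D form
#' (stress exactly as the energy derivative, no pressure term), so the forward
#' generator and the inverse losses are mutually consistent.
#'
#' @param kind One of `"neo_hookean_plane_strain"`, `"neo_hookean_plane_stress"`,
#'   `"mooney_rivlin"`, `"gent"`.
#' @param nu Poisson's ratio (Neo-Hookean only), `0 <= nu < 0.5`.
#' @param mu2 Second Mooney-Rivlin constant (known), `>= 0`.
#' @param Jm Gent stiffening parameter (limiting value of `I1 - 2`), `> 0`.
#'   The default 10 safely exceeds `I1 - 2 = 1.92` at 40% equibiaxial stretch.
#' @return An object of class `material_model`.
#' @export
material_model <- function(kind = c("neo_hookean_plane_strain",
                                    "neo_hookean_plane_stress",
                                    "mooney_rivlin", "gent"),
                           nu = 0.3, mu2 = 0.2, Jm = 10) {
  kind <- match.arg(kind)
  if (nu < 0 || nu >= 0.5) stop("nu must satisfy 0 <= nu < 0.5")
  if (mu2 < 0) stop("mu2 must be >= 0")
  if (Jm <= 0) stop("Jm must be > 0")
  unknown <- switch(kind, mooney_rivlin = "mu1", gent = "mu", "E")
  structure(list(kind = kind, nu = nu, mu2 = mu2, Jm = Jm,
                 unknown_field_name = unknown),
            class = "material_model")
}

#' @export
print.material_model <- function(x, ...) {
  cat(sprintf("Hyperelastic material model: %s (unknown field: %s)\n",
              x$kind, x$unknown_field_name))
  if (startsWith(x$kind, "neo_hookean")) cat(sprintf("  nu = %g\n", x$nu))
  if (x$kind == "mooney_rivlin") cat(sprintf("  mu2 = %g\n", x$mu2))
  if (x$kind == "gent") cat(sprintf("  Jm = %g\n", x$Jm))
  invisible(x)
}

#' Lame parameters from Young's modulus and Poisson's ratio
#'
#' Plane strain uses the 3D relations `lambda = E nu / ((1+nu)(1-2nu))` and
#' `mu = E / (2(1+nu))`; plane stress substitutes the effective
#' `lambda_bar = 2 lambda mu / (lambda + 2 mu)`.
#'
#' @param E Young's modulus (any positive scale).
#' @param nu Poisson's ratio.
#' @param plane `"strain"` or `"stress"`.
#' @return List with `lambda` and `mu` (vectors if `E` is a vector).
#' @export
lame_parameters <- function(E, nu, plane = c("strain", "stress")) {
  plane <- match.arg(plane)
  mu <- E / (2 * (1 + nu))
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  if (plane == "stress") lambda <- 2 * lambda * mu / (lambda + 2 * mu)
  list(lambda = lambda, mu = mu)
}

#' Kinematic quantities from a displacement gradient
#'
#' Populates the deformation gradient `F = I + grad_u`, the right Cauchy-Green
#' tensor `C = F^T F`, `J = det F`, the 2D invariants
#' `I1 = tr C` and `I2 = (I1^2 - tr(C C)) / 2`, and the Green-Lagrange strain
#' `eps = (C - I) / 2`.
#'
#' @param grad_u 2x2 displacement gradient (`grad_u[i, j]` = du_i/dx_j).
#' @return An object of class `kinematics` with fields `F`, `C`, `J`, `I1`,
#'   `I2`, `eps`.
#' @export
deformation_gradient <- function(grad_u) {
  stopifnot(is.matrix(grad_u), all(dim(grad_u) == c(2L, 2L)))
  F <- diag(2) + grad_u
  J <- F[1, 1] * F[2, 2] - F[1, 2] * F[2, 1]
  if (J <= 0) stop("inverted element: det F = ", signif(J, 4), " <= 0")
  C <- crossprod(F)
  I1 <- C[1, 1] + C[2, 2]
  I2 <- 0.5 * (I1^2 - sum(C * C))
  eps <- 0.5 * (C - diag(2))
  structure(list(F = F, C = C, J = J, I1 = I1, I2 = I2, eps = eps),
            class = "kinematics")
}

#' Strain energy and first Piola-Kirchhoff stress
#'
#' Evaluates the strain-energy density and the stress `P = dPsi/dF` of the
#' chosen model at one deformation state:
#' \describe{
#'   \item{Neo-Hookean}{`Psi = lambda/2 (log J)^2 - mu log J + mu/2 (I1 - 2)`;
#'     `P = mu F + (lambda log J - mu) F^-T`, with the plane-stress variant
#'     substituting the effective `lambda_bar`.}
#'   \item{Mooney-Rivlin}{`Psi = mu1/2 (I1 - 2) + mu2/2 (I2 - 2)`;
#'     `P = mu1 F + mu2 (I1 F - F C)`.}
#'   \item{Gent}{`Psi = -(mu Jm / 2) log(1 - (I1 - 2)/Jm)`;
#'     `P = mu Jm / (Jm - (I1 - 2)) F`, diverging at the locking stretch
#'     `I1 - 2 -> Jm`.}
#' }
#'
#' @param kin A `kinematics` object (see [deformation_gradient()]).
#' @param modulus The unknown modulus at this point: `E`, `mu1`, or `mu`
#'   depending on the model.
#' @param model A `material_model`.
#' @return List with `Psi` (scalar energy density) and `P` (2x2 stress).
#' @export
pk1_stress <- function(kin, modulus, model) {
  stopifnot(inherits(kin, "kinematics"), inherits(model, "material_model"))
  F <- kin$F
  Fv <- c(F[1, 1], F[1, 2], F[2, 1], F[2, 2])
  out <- pk1_stress_vec(matrix(Fv, 1), modulus, model, want = "psi")
  list(Psi = out$Psi[1],
       P = matrix(out$P[1, c(1, 3, 2, 4)], 2, 2))  # P stored (11,12,21,22)
}

#' Neo-Hookean energy and stress
#'
#' Convenience wrapper around [pk1_stress()] for the Neo-Hookean model.
#'
#' @inheritParams pk1_stress
#' @param E Young's modulus at this point.
#' @param model A Neo-Hookean `material_model` (plane strain or plane stress).
#' @return List with `Psi` and `P`.
#' @export
neo_hookean <- function(kin, E, model = material_model("neo_hookean_plane_strain")) {
  if (!startsWith(model$kind, "neo_hookean"))
    stop("model kind must be neo_hookean_*")
  pk1_stress(kin, E, model)
}

#' Mooney-Rivlin energy and stress
#'
#' @inheritParams pk1_stress
#' @param mu1 First material constant (the unknown field).
#' @param mu2 Second material constant (known).
#' @return List with `Psi` and `P`.
#' @export
mooney_rivlin <- function(kin, mu1, mu2 = 0.2) {
  pk1_stress(kin, mu1, material_model("mooney_rivlin", mu2 = mu2))
}

#' Gent energy and stress
#'
#' @inheritParams pk1_stress
#' @param mu Shear modulus (the unknown field).
#' @param Jm Stiffening parameter; requires `I1 - 2 < Jm`.
#' @return List with `Psi` and `P`.
#' @export
gent <- function(kin, mu, Jm = 10) {
  pk1_stress(kin, mu, material_model("gent", Jm = Jm))
}

# ---------------------------------------------------------------------------
# Vectorized constitutive kernels.
#
# F is an N x 4 matrix with columns (F11, F12, F21, F22); modulus is a
# length-N vector (recycled if scalar). Returns P (N x 4, same column order)
# and optionally:
#   Psi  : energy density (N)
#   K    : dP/dF, N x 16, column (i,J,m,n) at index 4*(idx4(i,J)-1)+idx4(m,n),
#          idx4 = (11,12,21,22) -> 1..4
#   PE   : dP/dmodulus, N x 4
# These kernels back the FEM residual/tangent, the PINN constitutive and PDE
# loss adjoints, and the adjoint-baseline gradient.
pk1_stress_vec <- function(F, modulus, model, want = c("p", "psi", "tangent")) {
  want <- match.arg(want, several.ok = TRUE)
  stopifnot(is.matrix(F), ncol(F) == 4L)
  N <- nrow(F)
  m <- rep_len(modulus, N)
  F11 <- F[, 1L]; F12 <- F[, 2L]; F21 <- F[, 3L]; F22 <- F[, 4L]
  J <- F11 * F22 - F12 * F21
  if (any(J <= 0)) stop("inverted element: det F <= 0")
  I1 <- F11^2 + F12^2 + F21^2 + F22^2
  out <- list()

  if (startsWith(model$kind, "neo_hookean")) {
    plane <- if (model$kind == "neo_hookean_plane_strain") "strain" else "stress"
    lp <- lame_parameters(m, model$nu, plane)
    mu <- lp$mu; lambda <- lp$lambda
    lJ <- log(J)
    beta <- lambda * lJ - mu
    # A = F^-T, columns (A11, A12, A21, A22)
    A11 <- F22 / J; A12 <- -F21 / J; A21 <- -F12 / J; A22 <- F11 / J
    P <- cbind(mu * F11 + beta * A11, mu * F12 + beta * A12,
               mu * F21 + beta * A21, mu * F22 + beta * A22)
    if ("psi" %in% want)
      out$Psi <- 0.5 * lambda * lJ^2 - mu * lJ + 0.5 * mu * (I1 - 2)
    if ("tangent" %in% want) {
      A <- cbind(A11, A12, A21, A22)
      K <- matrix(0, N, 16L)
      for (p in 1:4) for (q in 1:4) {
        i <- (p - 1L) %/% 2L + 1L; Jj <- (p - 1L) %% 2L + 1L
        mm <- (q - 1L) %/% 2L + 1L; nn <- (q - 1L) %% 2L + 1L
        v <- lambda * A[, q] * A[, p] -
             beta * A[, 2L * (i - 1L) + nn] * A[, 2L * (mm - 1L) + Jj]
        if (p == q) v <- v + mu
        K[, 4L * (p - 1L) + q] <- v
      }
      out$K <- K
      out$PE <- P / m  # P is linear in E (both Lame parameters scale with E)
    }
  } else if (model$kind == "mooney_rivlin") {
    mu1 <- m; mu2 <- model$mu2
    # C = F^T F: C11 = F11^2 + F21^2, C12 = F11 F12 + F21 F22, C22 = F12^2 + F22^2
    C11 <- F11^2 + F21^2; C12 <- F11 * F12 + F21 * F22; C22 <- F12^2 + F22^2
    # FC, columns (11, 12, 21, 22)
    FC1 <- F11 * C11 + F12 * C12; FC2 <- F11 * C12 + F12 * C22
    FC3 <- F21 * C11 + F22 * C12; FC4 <- F21 * C12 + F22 * C22
    M1 <- I1 * F11 - FC1; M2 <- I1 * F12 - FC2
    M3 <- I1 * F21 - FC3; M4 <- I1 * F22 - FC4
    P <- cbind(mu1 * F11 + mu2 * M1, mu1 * F12 + mu2 * M2,
               mu1 * F21 + mu2 * M3, mu1 * F22 + mu2 * M4)
    if ("psi" %in% want) {
      I2 <- 0.5 * (I1^2 - (C11^2 + 2 * C12^2 + C22^2))
      out$Psi <- 0.5 * mu1 * (I1 - 2) + 0.5 * mu2 * (I2 - 2)
    }
    if ("tangent" %in% want) {
      # d(FC)_{iJ}/dF_{mn} = delta_im C_{nJ} + F_in F_mJ + B_im delta_Jn,  B = F F^T
      B11 <- F11^2 + F12^2; B12 <- F11 * F21 + F12 * F22; B22 <- F21^2 + F22^2
      Bm <- list(`11` = B11, `12` = B12, `21` = B12, `22` = B22)
      Cm <- list(`11` = C11, `12` = C12, `21` = C12, `22` = C22)
      Fm <- list(`11` = F11, `12` = F12, `21` = F21, `22` = F22)
      Fcol <- cbind(F11, F12, F21, F22)
      K <- matrix(0, N, 16L)
      for (p in 1:4) for (q in 1:4) {
        i <- (p - 1L) %/% 2L + 1L; Jj <- (p - 1L) %% 2L + 1L
        mm <- (q - 1L) %/% 2L + 1L; nn <- (q - 1L) %% 2L + 1L
        dFC <- (if (i == mm) Cm[[paste0(nn, Jj)]] else 0) +
               Fm[[paste0(i, nn)]] * Fm[[paste0(mm, Jj)]] +
               (if (Jj == nn) Bm[[paste0(i, mm)]] else 0)
        v <- mu2 * (2 * Fcol[, q] * Fcol[, p] - dFC)
        if (p == q) v <- v + mu2 * I1 + mu1
        K[, 4L * (p - 1L) + q] <- v
      }
      out$K <- K
      out$PE <- Fcol  # dP/dmu1 = F
    }
  } else if (model$kind == "gent") {
    mu <- m; Jm <- model$Jm
    D <- Jm - (I1 - 2)
    bad <- D <= 0
    if (any(bad))
      stop("locking singularity: I1 - 2 = ", signif(max(I1[bad] - 2), 6),
           " >= Jm = ", Jm)
    cfac <- mu * Jm / D
    P <- cbind(cfac * F11, cfac * F12, cfac * F21, cfac * F22)
    if ("psi" %in% want) out$Psi <- -0.5 * mu * Jm * log(D / Jm)
    if ("tangent" %in% want) {
      Fcol <- cbind(F11, F12, F21, F22)
      dc <- 2 * mu * Jm / D^2   # dc/dF_mn = dc * F_mn
      K <- matrix(0, N, 16L)
      for (p in 1:4) for (q in 1:4) {
        v <- dc * Fcol[, p] * Fcol[, q]
        if (p == q) v <- v + cfac
        K[, 4L * (p - 1L) + q] <- v
      }
      out$K <- K
      out$PE <- P / mu
    }
  } else stop("unknown model kind: ", model$kind)

  out$P <- P
  out
}

# Green-Lagrange strain components from F columns (11,12,21,22):
# returns N x 3 (exx, eyy, exy).
green_lagrange_vec <- function(F) {
  cbind(0.5 * (F[, 1L]^2 + F[, 3L]^2 - 1),
        0.5 * (F[, 2L]^2 + F[, 4L]^2 - 1),
        0.5 * (F[, 1L] * F[, 2L] + F[, 3L] * F[, 4L]))
}
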