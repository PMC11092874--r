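#' Equibiaxial displacement boundary condition
#'
#' Prescribes the full displacement vector `u = (d (2x - 1), d (2y - 1))` on
#' the entire boundary of the unit square: each side moves outward by `d`, so
#' `d = 0.2` produces 40% total stretch (stretch ratio 1.4) and `d = 0.1`
#' produces 20%.
#'
#' @param d Outward displacement per side (dimensionless; `> -0.5`).
#' @return An object of class `equibiaxial_bc`.
#' @export
equibiaxial_bc <- function(d = 0.2) {
  if (d <= -0.5) stop("d must be > -0.5 (domain collapse)")
  structure(list(d = d), class = "equibiaxial_bc")
}

# Prescribed boundary displacement field at coordinates xy (N x 2).
bc_displacement <- function(bc, xy) {
  cbind(bc$d * (2 * xy[, 1L] - 1), bc$d * (2 * xy[, 2L] - 1))
}

#' Solve the static hyperelastic boundary-value problem
#'
#' Solves weak-form equilibrium `div P(F; E) = 0` on a crossed triangulation
#' with linear (P1) elements, element-wise constant modulus, and the full
#' displacement vector prescribed on the whole boundary. Newton's method with
#' uniform incremental load stepping; the consistent tangent is assembled from
#' the analytic `dP/dF` of the constitutive law.
#'
#' @param mesh An `elastinv_mesh`.
#' @param E Numeric vector of element moduli (all `> 0`).
#' @param model A `material_model`.
#' @param bc An `equibiaxial_bc`.
#' @param tol Relative Newton tolerance on the residual norm (default `1e-8`).
#' @param max_iter Maximum Newton iterations per load step (default 25).
#' @param load_steps Number of uniform load increments (default 5).
#' @return An object of class `forward_solution`:
#'   \describe{
#'     \item{u}{`n_nodes` x 2 matrix of nodal displacements.}
#'     \item{strains}{a [strain_field()] of nodal Green-Lagrange strains.}
#'     \item{residual_norm}{final Newton residual norm (free DOFs).}
#'     \item{converged}{logical.}
#'   }
#' @export
solve_forward <- function(mesh, E, model, bc = equibiaxial_bc(0.2),
                          tol = 1e-8, max_iter = 25L, load_steps = 5L) {
  stopifnot(inherits(mesh, "elastinv_mesh"), inherits(model, "material_model"),
            inherits(bc, "equibiaxial_bc"))
  if (length(E) != nrow(mesh$elements))
    stop("E must have one value per element")
  if (any(E <= 0)) stop("all moduli must be > 0")

  np <- nrow(mesh$nodes)
  sg <- shape_gradients(mesh)
  bn <- boundary_nodes(mesh)
  fixed <- c(bn, bn + np)              # dof order: all ux, then all uy
  free <- setdiff(seq_len(2L * np), fixed)
  ub_full <- bc_displacement(bc, mesh$nodes[bn, , drop = FALSE])
  asm <- assembly_pattern(mesh)

  u <- matrix(0, np, 2L)
  res_scale <- NA_real_
  for (step in seq_len(load_steps)) {
    t_load <- step / load_steps
    u[bn, ] <- t_load * ub_full
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      Fm <- element_def_grad(u, mesh, sg)
      ct <- pk1_stress_vec(Fm, E, model, want = "tangent")
      r <- assemble_residual(ct$P, mesh, sg)
      rn <- sqrt(sum(r[free]^2))
      if (it == 1L && step == 1L) res_scale <- max(rn, 1)
      if (rn <= tol * res_scale) { conv <- TRUE; break }
      K <- assemble_tangent(ct$K, mesh, sg, asm)
      du <- Matrix::solve(K[free, free, drop = FALSE], -r[free])
      u[free] <- u[free] + as.numeric(du)
      # guard against element inversion along the Newton path
      Ftry <- element_def_grad(u, mesh, sg)
      Jtry <- Ftry[, 1L] * Ftry[, 4L] - Ftry[, 2L] * Ftry[, 3L]
      if (any(Jtry <= 0))
        stop("element inverted during Newton iteration (load step ", step, ")")
    }
    if (!conv) {
      # one more residual check at the last iterate
      Fm <- element_def_grad(u, mesh, sg)
      P <- pk1_stress_vec(Fm, E, model, want = "p")$P
      r <- assemble_residual(P, mesh, sg)
      rn <- sqrt(sum(r[free]^2))
      if (rn > tol * res_scale)
        stop(sprintf(
          "Newton did not converge in load step %d (relative residual %.3e)",
          step, rn / res_scale))
    }
  }
  Fm <- element_def_grad(u, mesh, sg)
  P <- pk1_stress_vec(Fm, E, model, want = "p")$P
  r <- assemble_residual(P, mesh, sg)
  strains <- strains_from_displacement(mesh, u)
  structure(list(u = u, strains = strains,
                 residual_norm = sqrt(sum(r[free]^2)), converged = TRUE),
            class = "forward_solution")
}

#' @export
print.forward_solution <- function(x, ...) {
  cat(sprintf(
    "Forward hyperelastic solution: %d nodes, residual norm %.3e (%s)\n",
    nrow(x$u), x$residual_norm, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Element deformation gradients, N_e x 4, columns (F11, F12, F21, F22).
element_def_grad <- function(u, mesh, sg = shape_gradients(mesh)) {
  e <- mesh$elements
  u1x <- u[e[, 1L], 1L]; u2x <- u[e[, 2L], 1L]; u3x <- u[e[, 3L], 1L]
  u1y <- u[e[, 1L], 2L]; u2y <- u[e[, 2L], 2L]; u3y <- u[e[, 3L], 2L]
  cbind(1 + u1x * sg$dNx[, 1L] + u2x * sg$dNx[, 2L] + u3x * sg$dNx[, 3L],
            u1x * sg$dNy[, 1L] + u2x * sg$dNy[, 2L] + u3x * sg$dNy[, 3L],
            u1y * sg$dNx[, 1L] + u2y * sg$dNx[, 2L] + u3y * sg$dNx[, 3L],
        1 + u1y * sg$dNy[, 1L] + u2y * sg$dNy[, 2L] + u3y * sg$dNy[, 3L])
}

# Internal-force residual: r[a, i] = sum_e area_e (P_i1 dNa,x + P_i2 dNa,y).
# Returns a length-2*np vector (all ux dofs, then all uy dofs).
assemble_residual <- function(P, mesh, sg) {
  np <- nrow(mesh$nodes)
  e <- mesh$elements
  a <- sg$area
  rx <- numeric(np); ry <- numeric(np)
  for (k in 1:3) {
    cx <- a * (P[, 1L] * sg$dNx[, k] + P[, 2L] * sg$dNy[, k])
    cy <- a * (P[, 3L] * sg$dNx[, k] + P[, 4L] * sg$dNy[, k])
    rx <- rx + rowsum_full(cx, e[, k], np)
    ry <- ry + rowsum_full(cy, e[, k], np)
  }
  c(rx, ry)
}

# Precompute the sparse-assembly index pattern (36 entries per element).
assembly_pattern <- function(mesh) {
  np <- nrow(mesh$nodes)
  e <- mesh$elements
  ne <- nrow(e)
  rows <- integer(36L * ne); cols <- integer(36L * ne)
  slot <- 1L
  for (a in 1:3) for (i in 1:2) for (b in 1:3) for (k in 1:2) {
    idx <- seq.int(slot, by = 36L, length.out = ne)
    rows[idx] <- e[, a] + (i - 1L) * np
    cols[idx] <- e[, b] + (k - 1L) * np
    slot <- slot + 1L
  }
  list(rows = rows, cols = cols, ne = ne, np = np)
}

# Consistent tangent K[(a,i),(b,k)] = sum_e area_e dNa,J C_iJkL dNb,L,
# C = dP/dF with column index 4*(idx(i,J)-1)+idx(k,L).
assemble_tangent <- function(K16, mesh, sg, asm) {
  ne <- asm$ne
  vals <- numeric(36L * ne)
  dN <- list(sg$dNx, sg$dNy)   # dN[[J]][, a]
  a_e <- sg$area
  slot <- 1L
  for (a in 1:3) for (i in 1:2) for (b in 1:3) for (k in 1:2) {
    v <- 0
    for (J in 1:2) for (L in 1:2) {
      p <- 2L * (i - 1L) + J   # idx4(i, J)
      q <- 2L * (k - 1L) + L
      v <- v + dN[[J]][, a] * K16[, 4L * (p - 1L) + q] * dN[[L]][, b]
    }
    idx <- seq.int(slot, by = 36L, length.out = ne)
    vals[idx] <- a_e * v
    slot <- slot + 1L
  }
  Matrix::sparseMatrix(i = asm$rows, j = asm$cols, x = vals,
                       dims = c(2L * asm$np, 2L * asm$np))
}

#' Nodal Green-Lagrange strains from a displacement field
#'
#' Computes the per-element (constant) deformation gradient from the linear
#' shape functions, evaluates the Green-Lagrange strain per element, and
#' averages element strains to nodes with area weights.
#'
#' @param mesh An `elastinv_mesh`.
#' @param u `n_nodes` x 2 matrix of nodal displacements.
#' @return A [strain_field()] at the mesh nodes.
#' @export
strains_from_displacement <- function(mesh, u) {
  stopifnot(nrow(u) == nrow(mesh$nodes), ncol(u) == 2L)
  sg <- shape_gradients(mesh)
  Fm <- element_def_grad(u, mesh, sg)
  ee <- green_lagrange_vec(Fm)
  np <- nrow(mesh$nodes)
  e <- mesh$elements
  wsum <- numeric(np)
  acc <- matrix(0, np, 3L)
  for (k in 1:3) {
    idx <- e[, k]
    wsum <- wsum + as.numeric(rowsum_full(sg$area, idx, np))
    for (c in 1:3)
      acc[, c] <- acc[, c] + as.numeric(rowsum_full(sg$area * ee[, c], idx, np))
  }
  acc <- acc / wsum
  strain_field(mesh$nodes, acc[, 1L], acc[, 2L], acc[, 3L])
}

# rowsum over groups 1..np including empty groups.
rowsum_full <- function(x, idx, np) {
  out <- numeric(np)
  s <- rowsum(x, idx, reorder = TRUE)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Full-field strain container
#'
#' Green-Lagrange strain components at a set of collocation points, the
#' training data of the inverse methods (symmetric-shear convention: a single
#' `exy` value per point).
#'
#' @param points `N` x 2 matrix of coordinates.
#' @param exx,eyy,exy Numeric vectors of strain components.
#' @return An object of class `strain_field`.
#' @export
strain_field <- function(points, exx, eyy, exy) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, length(exx) == nrow(points),
            length(eyy) == nrow(points), length(exy) == nrow(points))
  structure(list(points = points, exx = as.numeric(exx),
                 eyy = as.numeric(eyy), exy = as.numeric(exy)),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("Green-Lagrange strain field at %d points\n", nrow(x$points)))
  cat(sprintf("  exx in [%.4g, %.4g], eyy in [%.4g, %.4g], exy in [%.4g, %.4g]\n",
              min(x$exx), max(x$exx), min(x$eyy), max(x$eyy),
              min(x$exy), max(x$exy)))
  invisible(x)
}

#' Write a strain/displacement field to CSV
#'
#' Columns `x,y,ux,uy,exx,eyy,exy` (displacements zero-filled when absent).
#'
#' @param strains A `strain_field`.
#' @param file Output path.
#' @param u Optional `N` x 2 displacement matrix.
#' @return `file`, invisibly.
#' @export
write_strain_csv <- function(strains, file, u = NULL) {
  n <- nrow(strains$points)
  if (is.null(u)) u <- matrix(0, n, 2L)
  utils::write.csv(
    data.frame(x = strains$points[, 1L], y = strains$points[, 2L],
               ux = u[, 1L], uy = u[, 2L],
               exx = strains$exx, eyy = strains$eyy, exy = strains$exy),
    file, row.names = FALSE)
  invisible(file)
}

#' Read a strain field from CSV
#'
#' Accepts the `x,y,ux,uy,exx,eyy,exy` layout written by [write_strain_csv()]
#' or the minimal `x,y,exx,eyy,exy`.
#'
#' @param file CSV path.
#' @return A list with `strains` (a `strain_field`) and `u` (displacement
#'   matrix or `NULL`).
#' @export
read_strain_csv <- function(file) {
  d <- utils::read.csv(file)
  need <- c("x", "y", "exx", "eyy", "exy")
  if (!all(need %in% names(d)))
    stop("strain CSV must contain columns ", paste(need, collapse = ", "))
  u <- if (all(c("ux", "uy") %in% names(d))) cbind(d$ux, d$uy) else NULL
  list(strains = strain_field(cbind(d$x, d$y), d$exx, d$eyy, d$exy), u = u)
}
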