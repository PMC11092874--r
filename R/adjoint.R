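#' Adjoint inversion configuration
#'
#' Settings for the PDE-constrained baseline: box bounds on the element
#' moduli, the iteration cap, and the strain-misfit tolerance at which the
#' optimization stops.
#'
#' @param bounds Length-2 vector `c(lower, upper)` (default `c(1, 5)`).
#' @param max_iterations Optimizer iteration cap (default 100).
#' @param strain_tolerance Acceptable L2 relative strain error (default
#'   `1e-3`).
#' @param init Initial element modulus field: `"random"` (i.i.d. uniform
#'   within the bounds) or a numeric vector.
#' @param seed Seed for the random initial field.
#' @return An object of class `adjoint_config`.
#' @export
adjoint_config <- function(bounds = c(1, 5), max_iterations = 100L,
                           strain_tolerance = 1e-3, init = "random",
                           seed = 1L) {
  if (bounds[1L] >= bounds[2L]) stop("lower bound must be below upper bound")
  if (strain_tolerance <= 0) stop("strain_tolerance must be > 0")
  structure(list(bounds = bounds, max_iterations = as.integer(max_iterations),
                 strain_tolerance = strain_tolerance, init = init,
                 seed = as.integer(seed)),
            class = "adjoint_config")
}

# Strain-misfit objective and its adjoint gradient at a modulus field E.
# Objective: sum over the three strain components of the L2 relative error
# of the recovered nodal strains against the reference.
adjoint_objective <- function(E, mesh, model, bc, ref, cfg_solver, want_grad) {
  sol <- solve_forward(mesh, E, model, bc, tol = cfg_solver$tol,
                       max_iter = cfg_solver$max_iter,
                       load_steps = cfg_solver$load_steps)
  s <- sol$strains
  comps <- c("exx", "eyy", "exy")
  refnorm <- vapply(comps, function(c) sqrt(sum(ref[[c]]^2)), 0)
  diffs <- lapply(comps, function(c) s[[c]] - ref[[c]])
  names(diffs) <- comps
  dnorm <- vapply(comps, function(c) sqrt(sum(diffs[[c]]^2)), 0)
  J <- sum(dnorm / refnorm)
  if (!want_grad) return(list(J = J))

  np <- nrow(mesh$nodes)
  sg <- shape_gradients(mesh)
  e <- mesh$elements
  Fm <- element_def_grad(sol$u, mesh, sg)
  ct <- pk1_stress_vec(Fm, E, model, want = "tangent")

  # dJ/d(nodal strain component)
  ebar <- lapply(comps, function(c) {
    dn <- sqrt(sum((s[[c]] - ref[[c]])^2))
    if (dn == 0) numeric(np) else (s[[c]] - ref[[c]]) / (dn * refnorm[[c]])
  })
  names(ebar) <- comps

  # nodal strains are area-weighted averages of element strains:
  # eps_node = sum_e w_ne eps_e, w_ne = area_e / sum(area at node)
  wsum <- numeric(np)
  for (k in 1:3) wsum <- wsum + rowsum_full(sg$area, e[, k], np)
  eelbar <- matrix(0, nrow(e), 3L)   # adjoint of element strains
  for (k in 1:3) {
    w_ne <- sg$area / wsum[e[, k]]
    for (c in 1:3)
      eelbar[, c] <- eelbar[, c] + w_ne * ebar[[comps[c]]][e[, k]]
  }

  # element strain -> element F adjoint (eps = (F^T F - I)/2)
  Fbar <- cbind(eelbar[, 1L] * Fm[, 1L] + 0.5 * eelbar[, 3L] * Fm[, 2L],
                eelbar[, 2L] * Fm[, 2L] + 0.5 * eelbar[, 3L] * Fm[, 1L],
                eelbar[, 1L] * Fm[, 3L] + 0.5 * eelbar[, 3L] * Fm[, 4L],
                eelbar[, 2L] * Fm[, 4L] + 0.5 * eelbar[, 3L] * Fm[, 3L])

  # element F -> nodal displacement adjoint: F_iJ = delta + sum_a u_i(a) dN_aJ
  dJdu <- matrix(0, np, 2L)
  for (k in 1:3) {
    cx <- Fbar[, 1L] * sg$dNx[, k] + Fbar[, 2L] * sg$dNy[, k]
    cy <- Fbar[, 3L] * sg$dNx[, k] + Fbar[, 4L] * sg$dNy[, k]
    dJdu[, 1L] <- dJdu[, 1L] + rowsum_full(cx, e[, k], np)
    dJdu[, 2L] <- dJdu[, 2L] + rowsum_full(cy, e[, k], np)
  }

  # adjoint solve: K^T lambda = dJ/du on the free DOFs
  bn <- boundary_nodes(mesh)
  fixed <- c(bn, bn + np)
  free <- setdiff(seq_len(2L * np), fixed)
  asm <- assembly_pattern(mesh)
  K <- assemble_tangent(ct$K, mesh, sg, asm)
  lambda <- numeric(2L * np)
  lambda[free] <- as.numeric(Matrix::solve(Matrix::t(K)[free, free, drop = FALSE],
                                           c(dJdu)[free]))

  # grad_e = -lambda^T dR/dE_e; dR contribution of element e to node a:
  # area_e * dPdE_iJ * dN_aJ
  grad <- numeric(nrow(e))
  lx <- matrix(lambda[seq_len(np)][e], nrow(e), 3L)
  ly <- matrix(lambda[np + seq_len(np)][e], nrow(e), 3L)
  for (k in 1:3) {
    grad <- grad - sg$area *
      (lx[, k] * (ct$PE[, 1L] * sg$dNx[, k] + ct$PE[, 2L] * sg$dNy[, k]) +
       ly[, k] * (ct$PE[, 3L] * sg$dNx[, k] + ct$PE[, 4L] * sg$dNy[, k]))
  }
  list(J = J, grad = grad, u = sol$u, strains = s)
}

#' Adjoint inverse finite element analysis
#'
#' The comparison baseline: minimizes the L2 relative strain misfit (summed
#' over the three components) over the element modulus field, with gradients
#' from one adjoint solve per objective evaluation and a box-constrained
#' quasi-Newton optimizer (L-BFGS-B) honoring `1 <= E <= 5`. Optimization
#' stops at the strain tolerance, the iteration cap, or on forward-solver
#' divergence (the initial-field-sensitive failure mode this baseline is
#' known for).
#'
#' @param mesh An `elastinv_mesh`.
#' @param model A [material_model()].
#' @param bc An [equibiaxial_bc()].
#' @param ref A [strain_field()] at the mesh nodes (the reference data).
#' @param cfg An [adjoint_config()].
#' @param solver_tol,solver_max_iter,solver_load_steps Forward-solver
#'   settings.
#' @return An object of class `adjoint_result`:
#'   \describe{
#'     \item{E}{recovered element moduli.}
#'     \item{objective}{final misfit.}
#'     \item{history}{objective value per accepted outer iteration.}
#'     \item{termination}{`"tolerance"`, `"max_iterations"`, or
#'       `"forward_divergence"`.}
#'     \item{iterations}{optimizer iterations used.}
#'   }
#' @export
invert_adjoint <- function(mesh, model, bc, ref, cfg = adjoint_config(),
                           solver_tol = 1e-9, solver_max_iter = 25L,
                           solver_load_steps = 5L) {
  stopifnot(inherits(mesh, "elastinv_mesh"), inherits(cfg, "adjoint_config"))
  ne <- nrow(mesh$elements)
  if (identical(cfg$init, "random")) {
    old <- get_rng_state()
    set.seed(cfg$seed)
    E0 <- stats::runif(ne, cfg$bounds[1L], cfg$bounds[2L])
    restore_rng_state(old)
  } else {
    E0 <- rep_len(cfg$init, ne)
  }
  cfg_solver <- list(tol = solver_tol, max_iter = solver_max_iter,
                     load_steps = solver_load_steps)

  cache <- new.env(parent = emptyenv())
  eval_obj <- function(E) {
    key <- E
    res <- adjoint_objective(E, mesh, model, bc, ref, cfg_solver, TRUE)
    assign("last", res, envir = cache)
    res
  }
  fn <- function(E) eval_obj(E)$J
  gr <- function(E) get("last", envir = cache)$grad

  history <- numeric(0)
  E <- E0
  termination <- "max_iterations"
  iterations <- 0L
  chunk <- 10L
  first <- tryCatch(eval_obj(E), error = function(e) e)
  if (inherits(first, "error")) {
    return(structure(list(E = E0, objective = NA_real_, history = history,
                          termination = "forward_divergence", iterations = 0L),
                     class = "adjoint_result"))
  }
  history <- first$J
  if (first$J <= cfg$strain_tolerance)
    return(structure(list(E = E0, objective = first$J, history = history,
                          termination = "tolerance", iterations = 0L),
                     class = "adjoint_result"))

  while (iterations < cfg$max_iterations) {
    todo <- min(chunk, cfg$max_iterations - iterations)
    res <- tryCatch(
      stats::optim(E, fn, gr, method = "L-BFGS-B",
                   lower = cfg$bounds[1L], upper = cfg$bounds[2L],
                   control = list(maxit = todo, factr = 10)),
      error = function(e) e)
    if (inherits(res, "error")) {
      termination <- "forward_divergence"
      break
    }
    iterations <- iterations + todo
    E <- res$par
    history <- c(history, res$value)
    if (res$value <= cfg$strain_tolerance) {
      termination <- "tolerance"
      break
    }
    if (res$convergence == 0L && res$value > cfg$strain_tolerance) {
      # optimizer converged to a stationary point above the tolerance
      termination <- "max_iterations"
      break
    }
  }
  obj <- tryCatch(adjoint_objective(E, mesh, model, bc, ref, cfg_solver,
                                    FALSE)$J,
                  error = function(e) NA_real_)
  structure(list(E = E, objective = obj, history = history,
                 termination = termination, iterations = iterations),
            class = "adjoint_result")
}

#' @export
print.adjoint_result <- function(x, ...) {
  cat(sprintf(
    "Adjoint inverse FEA: objective %.4e after %d iterations (%s)\n",
    x$objective, x$iterations, x$termination))
  invisible(x)
}
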