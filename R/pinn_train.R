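#' Loss weights
#'
#' Weights of the composite training objective. Defaults follow the
#' 1 : 100 : 100 convention for the momentum-balance (PDE), constitutive, and
#' strain-data terms. The constitutive weight is ignored for FCNN III-V,
#' which emit no direct stress output.
#'
#' @param w_pde,w_const,w_data Non-negative weights.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(w_pde = 1, w_const = 100, w_data = 100) {
  if (any(c(w_pde, w_const, w_data) < 0)) stop("loss weights must be >= 0")
  structure(list(w_pde = w_pde, w_const = w_const, w_data = w_data),
            class = "loss_weights")
}

#' Momentum-balance residual
#'
#' The residual of `div P = 0` (divergence on the second, reference-frame
#' index) at a set of points. Two modes: from the spatial derivatives of a
#' direct stress output (FCNN I/II), or from the deformation gradient, its
#' spatial derivative, and the modulus field through the constitutive tangent
#' (FCNN III-V).
#'
#' @param dNP For the stress-output mode: named list of vectors `P11_x`,
#'   `P12_y`, `P21_x`, `P22_y` (spatial derivatives of the stress
#'   components).
#' @param F For the constitutive mode: `N` x 4 matrix of deformation-gradient
#'   columns (F11, F12, F21, F22).
#' @param E Modulus vector (constitutive mode).
#' @param dF List of two `N` x 4 matrices `x` and `y`: spatial derivatives of
#'   the `F` columns.
#' @param dE List of vectors `x`, `y`: spatial derivative of the modulus.
#' @param model A [material_model()] (constitutive mode).
#' @return `N` x 2 matrix of residual components.
#' @export
pde_residual <- function(dNP = NULL, F = NULL, E = NULL, dF = NULL, dE = NULL,
                         model = NULL) {
  if (!is.null(dNP)) {
    return(cbind(dNP$P11_x + dNP$P12_y, dNP$P21_x + dNP$P22_y))
  }
  stopifnot(!is.null(F), !is.null(E), !is.null(dF), !is.null(dE),
            !is.null(model))
  ct <- pk1_stress_vec(F, E, model, want = "tangent")
  div_from_tangent(ct$K, ct$PE, dF, dE)
}

# div_i = sum_J sum_q K[, 4 (p-1) + q] dF_q_J + PE[, p] dE_J, p = 2(i-1)+J.
div_from_tangent <- function(K, PE, dF, dE) {
  d1 <- PE[, 1L] * dE$x + PE[, 2L] * dE$y
  d2 <- PE[, 3L] * dE$x + PE[, 4L] * dE$y
  for (q in 1:4) {
    d1 <- d1 + K[, q] * dF$x[, q] + K[, 4L + q] * dF$y[, q]
    d2 <- d2 + K[, 8L + q] * dF$x[, q] + K[, 12L + q] * dF$y[, q]
  }
  cbind(d1, d2)
}

#' Assemble the composite PINN loss from physical fields
#'
#' Field-level reference implementation of the training objective: the mean
#' squared strain-data misfit (Green-Lagrange strains derived from the
#' displacement gradient vs. the reference), the constitutive misfit between
#' a direct stress output and `P(F, E)` (FCNN I/II), and the mean squared
#' momentum residual, combined with the loss weights. Displacements never
#' enter the data term.
#'
#' @param grad_u `N` x 4 matrix of displacement-gradient columns
#'   (`ux_x`, `ux_y`, `uy_x`, `uy_y`).
#' @param E Modulus vector at the points.
#' @param ref A [strain_field()] aligned with the points.
#' @param weights A [loss_weights()].
#' @param model A [material_model()].
#' @param fcnn FCNN variant (`"I"`..`"V"`); decides the constitutive term and
#'   the residual mode.
#' @param NP `N` x 4 direct stress output (FCNN I/II).
#' @param dNP Spatial derivatives of `NP` for the residual (FCNN I/II), as in
#'   [pde_residual()].
#' @param hess_u Named list `ux_xx`, `ux_xy`, `ux_yy`, `uy_xx`, `uy_xy`,
#'   `uy_yy` of second displacement derivatives (FCNN III-V).
#' @param dE List `x`, `y` of modulus spatial derivatives (FCNN III-V).
#' @return List with `total`, `data`, `const`, `pde` loss values.
#' @export
assemble_loss <- function(grad_u, E, ref, weights, model, fcnn,
                          NP = NULL, dNP = NULL, hess_u = NULL, dE = NULL) {
  stopifnot(inherits(ref, "strain_field"), inherits(weights, "loss_weights"))
  N <- nrow(grad_u)
  if (nrow(ref$points) != N)
    stop("alignment error: reference strain points do not match fields")
  F <- cbind(1 + grad_u[, 1L], grad_u[, 2L], grad_u[, 3L], 1 + grad_u[, 4L])
  e <- green_lagrange_vec(F)
  L_data <- mean((e[, 1L] - ref$exx)^2 + (e[, 2L] - ref$eyy)^2 +
                 (e[, 3L] - ref$exy)^2) / 3
  L_const <- 0
  if (fcnn %in% c("I", "II")) {
    stopifnot(!is.null(NP), !is.null(dNP))
    P <- pk1_stress_vec(F, E, model, want = "p")$P
    L_const <- mean((NP - P)^2)
    res <- pde_residual(dNP = dNP)
  } else {
    stopifnot(!is.null(hess_u), !is.null(dE))
    dF <- list(x = cbind(hess_u$ux_xx, hess_u$ux_xy, hess_u$uy_xx, hess_u$uy_xy),
               y = cbind(hess_u$ux_xy, hess_u$ux_yy, hess_u$uy_xy, hess_u$uy_yy))
    res <- pde_residual(F = F, E = E, dF = dF, dE = dE, model = model)
  }
  L_pde <- mean(res^2)
  total <- weights$w_pde * L_pde + weights$w_data * L_data +
    (if (fcnn %in% c("I", "II")) weights$w_const * L_const else 0)
  list(total = total, data = L_data, const = L_const, pde = L_pde)
}

# ---------------------------------------------------------------------------
# Training internals. Channel extraction from engine output: stacked blocks
# of N rows per channel (val, dx, dy[, dxx, dxy, dyy]).

chan <- function(M, c, N) M[((c - 1L) * N + 1L):(c * N), , drop = FALSE]

sigmoid <- function(z) 1 / (1 + exp(-z))

# One forward + loss + seed evaluation. Returns losses, seeds (list of
# stacked matrices per branch, NULL for trunks) and diagnostic fields.
pinn_step <- function(net, theta, ref, model, weights, tf, want_seeds = TRUE) {
  N <- nrow(net$points)
  x <- net$points[, 1L]; y <- net$points[, 2L]
  spec <- net$spec; topo <- net$topo
  nC <- if (net$order == 2L) 6L else 3L
  outs <- mlp_engine_forward(net$engine, theta)

  get <- function(name, c) {
    s <- topo$slots[[name]]
    outs[[s[1L]]][((c - 1L) * N + 1L):(c * N), s[2L]]
  }
  has_np <- spec$fcnn %in% c("I", "II")

  # displacement chain
  sx <- tf$u_std[1L]; sy <- tf$u_std[2L]
  mx <- tf$u_mean[1L]; my <- tf$u_mean[2L]
  if (spec$hard_bc) W <- hard_bc_window(x, y)
  uch <- list()   # u* derivative channels per component
  for (i in 1:2) {
    nm <- c("ux", "uy")[i]
    sgm <- c(sx, sy)[i]; mn <- c(mx, my)[i]
    v <- sgm * get(nm, 1L) + mn
    v_x <- sgm * get(nm, 2L); v_y <- sgm * get(nm, 3L)
    if (net$order == 2L) {
      v_xx <- sgm * get(nm, 4L); v_xy <- sgm * get(nm, 5L)
      v_yy <- sgm * get(nm, 6L)
    }
    if (spec$hard_bc) {
      g_x <- if (i == 1L) 2 * tf$d else 0
      g_y <- if (i == 2L) 2 * tf$d else 0
      u_x <- g_x + W$lx * v + W$l * v_x
      u_y <- g_y + W$ly * v + W$l * v_y
      if (net$order == 2L) {
        u_xx <- W$lxx * v + 2 * W$lx * v_x + W$l * v_xx
        u_xy <- W$lxy * v + W$lx * v_y + W$ly * v_x + W$l * v_xy
        u_yy <- W$lyy * v + 2 * W$ly * v_y + W$l * v_yy
      }
    } else {
      u_x <- v_x; u_y <- v_y
      if (net$order == 2L) { u_xx <- v_xx; u_xy <- v_xy; u_yy <- v_yy }
    }
    uch[[nm]] <- if (net$order == 2L)
      list(v = v, x = u_x, y = u_y, xx = u_xx, xy = u_xy, yy = u_yy)
    else list(v = v, x = u_x, y = u_y)
  }

  # modulus chain
  nE <- get("E", 1L)
  s <- sigmoid(nE)
  Estar <- 1 + 4 * s
  sprime <- s * (1 - s)
  if (net$order == 2L) {
    nE_x <- get("E", 2L); nE_y <- get("E", 3L)
    dE <- list(x = 4 * sprime * nE_x, y = 4 * sprime * nE_y)
  }

  F <- cbind(1 + uch$ux$x, uch$ux$y, uch$uy$x, 1 + uch$uy$y)
  e <- green_lagrange_vec(F)
  dxx <- e[, 1L] - ref$exx; dyy <- e[, 2L] - ref$eyy; dxy <- e[, 3L] - ref$exy
  L_data <- mean(dxx^2 + dyy^2 + dxy^2) / 3

  if (has_np) {
    NP <- cbind(get("P11", 1L), get("P12", 1L), get("P21", 1L), get("P22", 1L))
    ct <- pk1_stress_vec(F, Estar, model, want = "tangent")
    Rc <- NP - ct$P
    L_const <- mean(Rc^2)
    div1 <- get("P11", 2L) + get("P12", 3L)
    div2 <- get("P21", 2L) + get("P22", 3L)
    L_pde <- mean(div1^2 + div2^2) / 2
  } else {
    ct <- pk1_stress_vec(F, Estar, model, want = "tangent")
    dF <- list(x = cbind(uch$ux$xx, uch$ux$xy, uch$uy$xx, uch$uy$xy),
               y = cbind(uch$ux$xy, uch$ux$yy, uch$uy$xy, uch$uy$yy))
    res <- div_from_tangent(ct$K, ct$PE, dF, dE)
    div1 <- res[, 1L]; div2 <- res[, 2L]
    L_pde <- mean(div1^2 + div2^2) / 2
    L_const <- 0
  }
  total <- weights$w_pde * L_pde + weights$w_data * L_data +
    (if (has_np) weights$w_const * L_const else 0)
  losses <- list(total = total, data = L_data, const = L_const, pde = L_pde)

  if (!want_seeds)
    return(list(losses = losses, E = Estar, F = F, u = cbind(uch$ux$v, uch$uy$v)))

  # ---- adjoint seeds -------------------------------------------------------
  zero <- numeric(N)
  # adjoints of u* channels and E chain
  ubar <- list(ux = list(x = zero, y = zero, xx = zero, xy = zero, yy = zero),
               uy = list(x = zero, y = zero, xx = zero, xy = zero, yy = zero))
  Ebar <- zero; dEbar <- list(x = zero, y = zero)

  # data term
  cdx <- weights$w_data * 2 * dxx / (3 * N)
  cdy <- weights$w_data * 2 * dyy / (3 * N)
  cds <- weights$w_data * 2 * dxy / (3 * N)
  Fbar <- cbind(cdx * F[, 1L] + 0.5 * cds * F[, 2L],
                cdy * F[, 2L] + 0.5 * cds * F[, 1L],
                cdx * F[, 3L] + 0.5 * cds * F[, 4L],
                cdy * F[, 4L] + 0.5 * cds * F[, 3L])

  NPbar <- NULL
  if (has_np) {
    rbarc <- weights$w_const * 2 * Rc / (4 * N)         # N x 4
    NPbar_val <- rbarc
    for (q in 1:4) {
      acc <- zero
      for (p in 1:4) acc <- acc + rbarc[, p] * ct$K[, 4L * (p - 1L) + q]
      Fbar[, q] <- Fbar[, q] - acc
    }
    Ebar <- Ebar - (rbarc[, 1L] * ct$PE[, 1L] + rbarc[, 2L] * ct$PE[, 2L] +
                    rbarc[, 3L] * ct$PE[, 3L] + rbarc[, 4L] * ct$PE[, 4L])
    dbar1 <- weights$w_pde * div1 / N
    dbar2 <- weights$w_pde * div2 / N
    NPbar <- list(val = NPbar_val,
                  P11_x = dbar1, P12_y = dbar1, P21_x = dbar2, P22_y = dbar2)
  } else {
    dbar1 <- weights$w_pde * div1 / N
    dbar2 <- weights$w_pde * div2 / N
    # linear-in-(dF, dE) part: exact adjoints via the tangent
    dFbar <- list(x = matrix(0, N, 4L), y = matrix(0, N, 4L))
    for (q in 1:4) {
      dFbar$x[, q] <- dbar1 * ct$K[, q] + dbar2 * ct$K[, 8L + q]
      dFbar$y[, q] <- dbar1 * ct$K[, 4L + q] + dbar2 * ct$K[, 12L + q]
    }
    dEbar$x <- dbar1 * ct$PE[, 1L] + dbar2 * ct$PE[, 3L]
    dEbar$y <- dbar1 * ct$PE[, 2L] + dbar2 * ct$PE[, 4L]
    # nonlinear dependence through K(F, E), PE(F, E): pointwise central
    # differences of the residual w.r.t. the F columns and E (exact to
    # O(h^2) for these smooth laws)
    divfun <- function(Fm, Em) {
      cc <- pk1_stress_vec(Fm, Em, model, want = "tangent")
      div_from_tangent(cc$K, cc$PE, dF, dE)
    }
    for (q in 1:4) {
      h <- 1e-5 * (1 + abs(F[, q]))
      Fp <- F; Fp[, q] <- F[, q] + h
      Fm2 <- F; Fm2[, q] <- F[, q] - h
      rp <- divfun(Fp, Estar); rm <- divfun(Fm2, Estar)
      Fbar[, q] <- Fbar[, q] +
        (dbar1 * (rp[, 1L] - rm[, 1L]) + dbar2 * (rp[, 2L] - rm[, 2L])) / (2 * h)
    }
    hE <- 1e-5 * (1 + abs(Estar))
    rp <- divfun(F, Estar + hE); rm <- divfun(F, Estar - hE)
    Ebar <- Ebar +
      (dbar1 * (rp[, 1L] - rm[, 1L]) + dbar2 * (rp[, 2L] - rm[, 2L])) / (2 * hE)
    # map dFbar to displacement Hessian adjoints
    ubar$ux$xx <- ubar$ux$xx + dFbar$x[, 1L]
    ubar$ux$xy <- ubar$ux$xy + dFbar$y[, 1L] + dFbar$x[, 2L]
    ubar$ux$yy <- ubar$ux$yy + dFbar$y[, 2L]
    ubar$uy$xx <- ubar$uy$xx + dFbar$x[, 3L]
    ubar$uy$xy <- ubar$uy$xy + dFbar$y[, 3L] + dFbar$x[, 4L]
    ubar$uy$yy <- ubar$uy$yy + dFbar$y[, 4L]
  }

  # deformation-gradient adjoints -> u* first-derivative adjoints
  ubar$ux$x <- ubar$ux$x + Fbar[, 1L]
  ubar$ux$y <- ubar$ux$y + Fbar[, 2L]
  ubar$uy$x <- ubar$uy$x + Fbar[, 3L]
  ubar$uy$y <- ubar$uy$y + Fbar[, 4L]

  # assemble raw-output seeds
  seeds <- vector("list", length(topo$branches))
  for (b in seq_along(topo$branches)) {
    if (topo$branches[[b]]$out > 0L)
      seeds[[b]] <- matrix(0, nC * N, topo$branches[[b]]$out)
  }
  put <- function(name, c, val) {
    sl <- topo$slots[[name]]
    idx <- ((c - 1L) * N + 1L):(c * N)
    seeds[[sl[1L]]][idx, sl[2L]] <<- seeds[[sl[1L]]][idx, sl[2L]] + val
  }

  for (i in 1:2) {
    nm <- c("ux", "uy")[i]
    sgm <- c(sx, sy)[i]
    ub <- ubar[[nm]]
    if (spec$hard_bc) {
      vbar <- W$lx * ub$x + W$ly * ub$y
      vbar_x <- W$l * ub$x
      vbar_y <- W$l * ub$y
      if (net$order == 2L) {
        vbar <- vbar + W$lxx * ub$xx + W$lxy * ub$xy + W$lyy * ub$yy
        vbar_x <- vbar_x + 2 * W$lx * ub$xx + W$ly * ub$xy
        vbar_y <- vbar_y + 2 * W$ly * ub$yy + W$lx * ub$xy
        put(nm, 4L, sgm * (W$l * ub$xx))
        put(nm, 5L, sgm * (W$l * ub$xy))
        put(nm, 6L, sgm * (W$l * ub$yy))
      }
      put(nm, 1L, sgm * vbar)
      put(nm, 2L, sgm * vbar_x)
      put(nm, 3L, sgm * vbar_y)
    } else {
      put(nm, 2L, sgm * ub$x)
      put(nm, 3L, sgm * ub$y)
      if (net$order == 2L) {
        put(nm, 4L, sgm * ub$xx)
        put(nm, 5L, sgm * ub$xy)
        put(nm, 6L, sgm * ub$yy)
      }
    }
  }

  # modulus seeds
  nE_seed <- 4 * sprime * Ebar
  if (net$order == 2L) {
    nE_seed <- nE_seed +
      4 * sprime * (1 - 2 * s) * (nE_x * dEbar$x + nE_y * dEbar$y)
    put("E", 2L, 4 * sprime * dEbar$x)
    put("E", 3L, 4 * sprime * dEbar$y)
  }
  put("E", 1L, nE_seed)

  if (has_np) {
    put("P11", 1L, NPbar$val[, 1L]); put("P12", 1L, NPbar$val[, 2L])
    put("P21", 1L, NPbar$val[, 3L]); put("P22", 1L, NPbar$val[, 4L])
    put("P11", 2L, NPbar$P11_x); put("P12", 3L, NPbar$P12_y)
    put("P21", 2L, NPbar$P21_x); put("P22", 3L, NPbar$P22_y)
  }

  list(losses = losses, seeds = seeds, E = Estar, F = F,
       u = cbind(uch$ux$v, uch$uy$v))
}

#' Train a PINN to recover the modulus field
#'
#' Full-batch Adam optimization of the composite loss at fixed collocation
#' points (the finite element nodes of the data-generating mesh). Reference
#' Green-Lagrange strains drive the data term; displacements never enter it.
#'
#' @param spec An [architecture_spec()].
#' @param model A [material_model()].
#' @param data A [strain_field()]: the reference strains at the collocation
#'   points.
#' @param bc The [equibiaxial_bc()] of the experiment (used by the hard
#'   boundary constraint and the default displacement scale).
#' @param weights A [loss_weights()].
#' @param iters Number of Adam iterations.
#' @param lr Initial learning rate (default `1e-3`).
#' @param lr_decay Optional inverse-time decay constant: the effective rate
#'   at iteration `t` is `lr / (1 + t / lr_decay)`. The default `Inf` keeps
#'   the rate constant: on the desk-scale problems the late global-scale
#'   settling of the modulus needs full-size steps, and decay was measured to
#'   slow it substantially.
#' @param u_ref Optional reference displacement matrix (`N` x 2) whose
#'   mean/std normalize the displacement outputs; defaults to mean 0, std
#'   `d` per component.
#' @param truth Optional list for error tracking: `mesh` and element moduli
#'   `E` (the known synthetic ground truth); the recovered modulus is then
#'   compared at element centroids every `log_every` iterations.
#' @param log_every Logging stride for the training history (default 1000).
#' @param precision `"single"` (default) or `"double"`.
#' @return An object of class `pinn_fit`: the trained network, `history`
#'   (data frame of loss components and, when truth is supplied, the modulus
#'   L2 relative error), and the output transforms.
#' @export
train_pinn <- function(spec, model, data, bc = equibiaxial_bc(0.2),
                       weights = loss_weights(), iters = 20000L, lr = 1e-3,
                       lr_decay = Inf, u_ref = NULL, truth = NULL,
                       log_every = 1000L, precision = "single") {
  stopifnot(inherits(spec, "architecture_spec"),
            inherits(model, "material_model"),
            inherits(data, "strain_field"))
  points <- data$points
  if (is.null(u_ref)) {
    u_mean <- c(0, 0); u_std <- rep(max(abs(bc$d), 0.01), 2L)
  } else {
    u_mean <- colMeans(u_ref)
    u_std <- pmax(apply(u_ref, 2L, stats::sd), 1e-6)
  }
  tf <- output_transforms(u_mean = u_mean, u_std = u_std, d = bc$d)
  net <- build_network(spec, points, precision = precision)
  theta <- net$theta

  cent_truth <- NULL
  if (!is.null(truth)) {
    cent <- element_centroids(truth$mesh)
    cent_net <- build_network(spec, cent, precision = precision)
    cent_truth <- truth$E
  }

  # Adam state
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- list()
  log_row <- function(it, losses) {
    err <- NA_real_
    if (!is.null(cent_truth)) {
      Ec <- predict_raw_modulus(cent_net, theta)
      err <- l2_relative_error(Ec, cent_truth)
    }
    hist[[length(hist) + 1L]] <<- data.frame(
      iter = it, total = losses$total, data = losses$data,
      const = losses$const, pde = losses$pde, e_l2_rel = err)
  }

  if (iters > 0) {
    for (it in seq_len(iters)) {
      st <- pinn_step(net, theta, data, model, weights, tf, want_seeds = TRUE)
      if (!is.finite(st$losses$total))
        stop("training diverged: non-finite loss at iteration ", it)
      g <- mlp_engine_backward(net$engine, st$seeds)
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      mhat <- m / (1 - b1^it)
      vhat <- v / (1 - b2^it)
      lr_t <- lr / (1 + it / lr_decay)
      theta <- theta - lr_t * mhat / (sqrt(vhat) + eps)
      if (it %% log_every == 0L || it == iters) log_row(it, st$losses)
    }
  }
  net$theta <- theta
  history <- if (length(hist)) do.call(rbind, hist)
             else data.frame(iter = integer(), total = numeric(),
                             data = numeric(), const = numeric(),
                             pde = numeric(), e_l2_rel = numeric())
  structure(list(net = net, spec = spec, model = model, weights = weights,
                 transforms = tf, history = history, iters = iters, lr = lr,
                 lr_decay = lr_decay),
            class = "pinn_fit")
}

#' @export
print.pinn_fit <- function(x, ...) {
  cat(sprintf("Trained PINN %s%s (%d iterations)\n",
              x$spec$fcnn, x$spec$variant, x$iters))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final losses: total %.3e (data %.3e, const %.3e, pde %.3e)\n",
                last$total, last$data, last$const, last$pde))
    if (is.finite(last$e_l2_rel))
      cat(sprintf("  modulus L2 relative error: %.3f%%\n", 100 * last$e_l2_rel))
  }
  invisible(x)
}

# Raw modulus prediction at the collocation points of a (possibly separate)
# engine network.
predict_raw_modulus <- function(net, theta) {
  outs <- mlp_engine_forward(net$engine, theta)
  s <- net$topo$slots$E
  N <- nrow(net$points)
  modulus_transform(outs[[s[1L]]][1:N, s[2L]])
}

#' Evaluate a trained PINN
#'
#' Computes the recovered displacement, modulus, and (for FCNN I/II) stress
#' fields at arbitrary points.
#'
#' @param object A `pinn_fit`.
#' @param points `M` x 2 matrix of evaluation coordinates (defaults to the
#'   training collocation points).
#' @param ... Unused.
#' @return List with `ux`, `uy`, `E` and, when the architecture emits stress,
#'   an `M` x 4 matrix `P`.
#' @export
predict.pinn_fit <- function(object, points = NULL, ...) {
  net <- object$net
  if (is.null(points)) points <- net$points
  pnet <- if (identical(dim(points), dim(net$points)) &&
              all(points == net$points)) net
          else build_network(object$spec, points, precision = net$precision)
  N <- nrow(points)
  outs <- mlp_engine_forward(pnet$engine, net$theta)
  g <- function(name) {
    s <- pnet$topo$slots[[name]]
    outs[[s[1L]]][1:N, s[2L]]
  }
  tfd <- apply_output_transforms(
    list(ux = g("ux"), uy = g("uy"), E = g("E")),
    points[, 1L], points[, 2L], object$transforms, object$spec$hard_bc)
  out <- tfd
  if (object$spec$fcnn %in% c("I", "II"))
    out$P <- cbind(g("P11"), g("P12"), g("P21"), g("P22"))
  out
}

#' Element centroids
#'
#' @param mesh An `elastinv_mesh`.
#' @return `n_elements` x 2 matrix of centroid coordinates.
#' @export
element_centroids <- function(mesh) {
  e <- mesh$elements
  cbind((mesh$nodes[e[, 1L], 1L] + mesh$nodes[e[, 2L], 1L] +
           mesh$nodes[e[, 3L], 1L]) / 3,
        (mesh$nodes[e[, 1L], 2L] + mesh$nodes[e[, 2L], 2L] +
           mesh$nodes[e[, 3L], 2L]) / 3)
}

#' Recovered modulus at element centroids
#'
#' Convenience accessor: evaluates the trained modulus map at the element
#' centroids of a mesh, the natural comparison points against an element-wise
#' ground truth.
#'
#' @param fit A `pinn_fit`.
#' @param mesh An `elastinv_mesh`.
#' @return Numeric vector of recovered moduli, one per element.
#' @export
recovered_modulus <- function(fit, mesh) {
  predict.pinn_fit(fit, element_centroids(mesh))$E
}
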