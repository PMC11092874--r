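# Shared fixtures: small meshes, random admissible deformation states, and a
# tiny forward problem, all built in code at test time.

small_mesh <- function(n = 4L) make_crossed_mesh(n)

# Random displacement gradients with well-separated positive det(I + G).
random_grad_u <- function(n, sd = 0.15, min_det = 0.2) {
  out <- vector("list", n)
  k <- 0L
  while (k < n) {
    g <- matrix(stats::rnorm(4, sd = sd), 2, 2)
    if (det(diag(2) + g) > min_det) {
      k <- k + 1L
      out[[k]] <- g
    }
  }
  out
}

all_models <- function() {
  list(nh_strain = material_model("neo_hookean_plane_strain", nu = 0.3),
       nh_stress = material_model("neo_hookean_plane_stress", nu = 0.45),
       mr = material_model("mooney_rivlin", mu2 = 0.2),
       gent = material_model("gent", Jm = 10))
}

# Forward solution of a homogeneous body on a small mesh (exact affine state).
homogeneous_problem <- function(n = 6L, E = 2.5, d = 0.2,
                                model = material_model("neo_hookean_plane_strain")) {
  mesh <- make_crossed_mesh(n)
  sol <- solve_forward(mesh, rep(E, nrow(mesh$elements)), model,
                       equibiaxial_bc(d))
  list(mesh = mesh, sol = sol, model = model)
}

# Central finite difference of Psi with respect to F at one state.
fd_stress <- function(grad_u, modulus, model, h = 1e-6) {
  P <- matrix(0, 2, 2)
  for (a in 1:2) for (b in 1:2) {
    gp <- grad_u; gp[a, b] <- gp[a, b] + h
    gm <- grad_u; gm[a, b] <- gm[a, b] - h
    P[a, b] <- (pk1_stress(deformation_gradient(gp), modulus, model)$Psi -
                pk1_stress(deformation_gradient(gm), modulus, model)$Psi) / (2 * h)
  }
  P
}
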