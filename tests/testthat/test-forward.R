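test_that("homogeneous equibiaxial stretch is reproduced exactly (patch test)", {
  for (nm in c("nh_strain", "mr", "gent")) {
    model <- all_models()[[nm]]
    hp <- homogeneous_problem(n = 5, E = 2, d = 0.2, model = model)
    s <- hp$sol$strains
    expect_lt(max(abs(s$exx - 0.48)), 1e-8)
    expect_lt(max(abs(s$eyy - 0.48)), 1e-8)
    expect_lt(max(abs(s$exy)), 1e-9)
    # boundary nodes carry the prescribed displacement exactly
    bn <- boundary_nodes(hp$mesh)
    g <- elastinv:::bc_displacement(equibiaxial_bc(0.2), hp$mesh$nodes[bn, ])
    expect_equal(hp$sol$u[bn, ], g, tolerance = 1e-14)
  }
})

test_that("zero boundary displacement gives the trivial equilibrium", {
  mesh <- small_mesh(4)
  model <- material_model("neo_hookean_plane_strain")
  sol <- solve_forward(mesh, rep(2, nrow(mesh$elements)), model,
                       equibiaxial_bc(0))
  expect_lt(max(abs(sol$u)), 1e-12)
  expect_lt(max(abs(sol$strains$exx), abs(sol$strains$eyy),
                abs(sol$strains$exy)), 1e-12)
})

test_that("strain recovery is exact for affine fields and kills rigid rotations", {
  mesh <- small_mesh(5)
  xy <- mesh$nodes
  # affine stretch
  u <- cbind(0.2 * (2 * xy[, 1] - 1), 0.2 * (2 * xy[, 2] - 1))
  s <- strains_from_displacement(mesh, u)
  expect_lt(max(abs(s$exx - 0.48)), 1e-13)
  expect_lt(max(abs(s$eyy - 0.48)), 1e-13)
  # rigid rotation by 10 degrees
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ur <- t(R %*% t(xy)) - xy
  sr <- strains_from_displacement(mesh, ur)
  expect_lt(max(abs(sr$exx), abs(sr$eyy), abs(sr$exy)), 1e-12)
})

test_that("strain recovery error halves when the mesh is refined", {
  # quadratic displacement field: u = (x^2, x y) -> strain error O(h)
  err_at <- function(n) {
    mesh <- make_crossed_mesh(n)
    xy <- mesh$nodes
    u <- cbind(0.1 * xy[, 1]^2, 0.1 * xy[, 1] * xy[, 2])
    s <- strains_from_displacement(mesh, u)
    # analytic Green-Lagrange strain of the field
    F11 <- 1 + 0.2 * xy[, 1]; F12 <- rep(0, nrow(xy))
    F21 <- 0.1 * xy[, 2];     F22 <- 1 + 0.1 * xy[, 1]
    exx <- 0.5 * (F11^2 + F21^2 - 1)
    interior <- xy[, 1] > 0.1 & xy[, 1] < 0.9 & xy[, 2] > 0.1 & xy[, 2] < 0.9
    sqrt(mean((s$exx[interior] - exx[interior])^2))
  }
  e8 <- err_at(8); e16 <- err_at(16)
  expect_lt(e16, 0.7 * e8)
})

test_that("piecewise modulus solution converges under mesh refinement", {
  # fine-mesh oracle; the comparison excludes a band around the material
  # interface, where nodal strain averaging of the discontinuous field
  # dominates the error
  model <- material_model("neo_hookean_plane_strain", nu = 0.3)
  solve_piecewise <- function(n) {
    mesh <- make_crossed_mesh(n)
    cent <- element_centroids(mesh)
    E <- ifelse(cent[, 1] < 0.5, 1, 4)
    list(mesh = mesh, sol = solve_forward(mesh, E, model, equibiaxial_bc(0.1)))
  }
  fine <- solve_piecewise(64)
  key <- function(xy) paste(round(xy[, 1], 10), round(xy[, 2], 10))
  errs <- sapply(c(16, 32), function(n) {
    coarse <- solve_piecewise(n)
    # every coarse node is a fine-mesh node; match by coordinates
    idx <- match(key(coarse$mesh$nodes), key(fine$mesh$nodes))
    expect_false(anyNA(idx))
    away <- abs(coarse$mesh$nodes[, 1] - 0.5) > 0.1
    sapply(c("exx", "eyy", "exy"), function(c)
      l2_relative_error(coarse$sol$strains[[c]][away],
                        fine$sol$strains[[c]][idx][away]))
  })
  # n = 32 agrees with the fine oracle to < 1% in every component and the
  # error contracts under refinement
  expect_true(all(errs[, 2] < 0.01))
  expect_true(all(errs[, 2] < 0.5 * errs[, 1]))
})

test_that("discrete reaction forces balance globally", {
  mesh <- small_mesh(6)
  set.seed(1)
  E <- runif(nrow(mesh$elements), 1, 4)
  model <- material_model("neo_hookean_plane_strain")
  sol <- solve_forward(mesh, E, model, equibiaxial_bc(0.2))
  sg <- elastinv:::shape_gradients(mesh)
  Fm <- elastinv:::element_def_grad(sol$u, mesh, sg)
  P <- elastinv:::pk1_stress_vec(Fm, E, model)$P
  r <- elastinv:::assemble_residual(P, mesh, sg)
  np <- nrow(mesh$nodes)
  # interior residual vanishes (equilibrium), boundary reactions sum to zero
  expect_lt(max(abs(sum(r[seq_len(np)])), abs(sum(r[np + seq_len(np)]))), 1e-10)
})

test_that("mirrored domain gives the mirrored solution", {
  model <- material_model("neo_hookean_plane_strain")
  mesh <- small_mesh(4)
  set.seed(2)
  f <- runif(nrow(mesh$nodes))
  E <- element_modulus(f, mesh)
  sol <- solve_forward(mesh, E, model, equibiaxial_bc(0.15))
  # mirror the intensity field about x = 1/2; mesh maps onto itself
  xy <- mesh$nodes
  key <- paste(round(1 - xy[, 1], 10), round(xy[, 2], 10))
  idx <- match(key, paste(round(xy[, 1], 10), round(xy[, 2], 10)))
  fm <- f[idx]
  Em <- element_modulus(fm, mesh)
  solm <- solve_forward(mesh, Em, model, equibiaxial_bc(0.15))
  # ux mirrors with a sign flip, strains exx mirror directly
  expect_equal(solm$u[idx, 1], -sol$u[, 1], tolerance = 1e-9)
  expect_equal(solm$strains$exx[idx], sol$strains$exx, tolerance = 1e-9)
})

test_that("solver validates its inputs", {
  mesh <- small_mesh(2)
  model <- material_model("neo_hookean_plane_strain")
  expect_error(solve_forward(mesh, rep(-1, nrow(mesh$elements)), model),
               "> 0")
  expect_error(solve_forward(mesh, rep(1, 3), model), "per element")
  expect_error(equibiaxial_bc(-0.6), "domain collapse")
})

test_that("strain CSV round-trips", {
  hp <- homogeneous_problem(n = 3)
  td <- withr::local_tempdir()
  p <- file.path(td, "strains.csv")
  write_strain_csv(hp$sol$strains, p, u = hp$sol$u)
  back <- read_strain_csv(p)
  expect_equal(back$strains$exx, hp$sol$strains$exx, tolerance = 1e-12)
  expect_equal(back$u, unname(hp$sol$u), tolerance = 1e-12,
               ignore_attr = TRUE)
})
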