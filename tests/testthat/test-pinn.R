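test_that("Fourier features follow the sine-mode pattern", {
  expect_equal(fourier_features(0, 0), matrix(0, 1, 12))
  f55 <- fourier_features(0.5, 0.5)
  expect_equal(as.numeric(f55),
               c(0.5, 0.5, 1, 0, -1, 0, 1, 1, 0, -1, 0, 1), tolerance = 1e-14)
  fb <- fourier_features(1, 0.37)
  expect_equal(as.numeric(fb)[3:7], rep(0, 5), tolerance = 1e-14)
})

test_that("architecture codes parse and invalid codes are rejected", {
  s <- architecture_spec("IIB")
  expect_identical(s$fcnn, "II")
  expect_false(s$fourier); expect_false(s$hard_bc)
  s2 <- architecture_spec("IVC")
  expect_identical(s2$fcnn, "IV")
  expect_true(s2$fourier); expect_true(s2$hard_bc)
  s3 <- architecture_spec("IA")
  expect_true(s3$hard_bc); expect_false(s3$fourier)
  expect_error(architecture_spec("VIE"), "invalid architecture code")
  expect_error(architecture_spec("IIX"), "invalid architecture code")
})

test_that("network output arities match their topology", {
  pts <- cbind(runif(5), runif(5))
  # FCNN V: 3 outputs from one net
  netV <- build_network(architecture_spec("VB"), pts, precision = "double")
  outs <- elastinv:::mlp_engine_forward(netV$engine, netV$theta)
  expect_identical(length(outs), 1L)
  expect_identical(ncol(outs[[1]]), 3L)
  # FCNN II: net2 emits modulus + 4 stress components
  netII <- build_network(architecture_spec("IIB"), pts, precision = "double")
  outs2 <- elastinv:::mlp_engine_forward(netII$engine, netII$theta)
  expect_identical(ncol(outs2[[2]]), 5L)
})

test_that("parameter counts agree with direct enumeration", {
  # FCNN IV: three independent 5x25 nets, 2 inputs, 1 output each
  by_formula <- 3 * (2 * 25 + 25 + 4 * (25 * 25 + 25) + 25 * 1 + 1)
  expect_identical(count_parameters("IV", 2L), as.integer(by_formula))
  expect_identical(by_formula, 8103)
  # engine agrees with the R-side count for every topology and input width
  for (fc in c("I", "II", "III", "IV", "V")) for (ind in c(2L, 12L)) {
    spec <- architecture_spec(fcnn = fc,
                              variant = if (ind == 2L) "B" else "D")
    net <- build_network(spec, cbind(0.5, 0.5), precision = "double")
    expect_identical(elastinv:::mlp_engine_n_params(net$engine),
                     count_parameters(fc, ind))
    expect_identical(length(net$theta), as.integer(count_parameters(fc, ind)))
  }
})

test_that("modulus transform is bounded, monotone, and centered at 3", {
  expect_equal(modulus_transform(0), 3)
  expect_equal(modulus_transform(50), 5, tolerance = 1e-12)
  expect_equal(modulus_transform(-50), 1, tolerance = 1e-12)
  # strictly inside (1, 5) over the numerically representable regime (the
  # sigmoid saturates to the closed bounds in double precision beyond
  # |n| ~ 37); never outside [1, 5] anywhere
  set.seed(1)
  n <- sort(c(runif(10000, -30, 30), rnorm(10000, sd = 50)))
  E <- modulus_transform(n)
  expect_true(all(E >= 1 & E <= 5))
  expect_true(all(E[abs(n) <= 30] > 1 & E[abs(n) <= 30] < 5))
  expect_true(all(diff(E) >= 0))
})

test_that("hard boundary constraint reproduces the prescribed displacement exactly", {
  tf <- output_transforms(u_mean = c(0.3, -0.2), u_std = c(2, 2), d = 0.2)
  set.seed(2)
  # 1000 random boundary points
  t <- runif(1000)
  side <- sample(4, 1000, replace = TRUE)
  x <- ifelse(side == 1, 0, ifelse(side == 2, 1, t))
  y <- ifelse(side == 3, 0, ifelse(side == 4, 1, t))
  raw <- list(ux = rnorm(1000, sd = 5), uy = rnorm(1000, sd = 5),
              E = rnorm(1000))
  out <- apply_output_transforms(raw, x, y, tf, hard_bc = TRUE)
  expect_equal(out$ux, 0.2 * (2 * x - 1), tolerance = 1e-14)
  expect_equal(out$uy, 0.2 * (2 * y - 1), tolerance = 1e-14)
  # spot value from the transform definition
  o <- apply_output_transforms(list(ux = 1, uy = 1, E = 0), 1, 0.3, tf,
                               hard_bc = TRUE)
  expect_equal(o$ux, 0.2)
  expect_equal(o$E, 3)
})

test_that("assembled losses vanish for truth-consistent fields", {
  mesh <- small_mesh(4)
  model <- material_model("neo_hookean_plane_strain", nu = 0.3)
  bc <- equibiaxial_bc(0.2)
  E <- rep(2.4, nrow(mesh$elements))
  sol <- solve_forward(mesh, E, model, bc)
  xy <- mesh$nodes
  np <- nrow(xy)
  # analytic homogeneous state: grad u constant, F = 1.4 I
  grad_u <- cbind(rep(0.4, np), 0, 0, rep(0.4, np))
  F <- cbind(1.4, 0, 0, 1.4)[rep(1, np), ]
  Ev <- rep(2.4, np)
  P <- elastinv:::pk1_stress_vec(F, Ev, model)$P
  dNP <- list(P11_x = numeric(np), P12_y = numeric(np),
              P21_x = numeric(np), P22_y = numeric(np))
  L <- assemble_loss(grad_u, Ev, sol$strains, loss_weights(), model, "II",
                     NP = P, dNP = dNP)
  expect_lt(L$data, 1e-8)
  expect_lt(L$const, 1e-20)
  expect_equal(L$pde, 0)
  # data term depends only on the displacement gradient, not on E
  L2 <- assemble_loss(grad_u, Ev * 1.7,
                      sol$strains, loss_weights(), model, "II",
                      NP = P, dNP = dNP)
  expect_equal(L2$data, L$data)
  # doubling the data weight doubles only the data contribution
  Lw <- assemble_loss(grad_u, Ev, sol$strains,
                      loss_weights(w_data = 200), model, "II",
                      NP = P, dNP = dNP)
  expect_equal(Lw$total - Lw$const * 100,
               2 * (L$total - L$const * 100), tolerance = 1e-12)
})

test_that("momentum residual is zero for constant stress and matches an FD oracle", {
  np <- 20
  dNP0 <- list(P11_x = numeric(np), P12_y = numeric(np),
               P21_x = numeric(np), P22_y = numeric(np))
  expect_equal(pde_residual(dNP = dNP0), matrix(0, np, 2),
               ignore_attr = TRUE)
  # manufactured field: u = (a x^2 + b x y, c y^2), E = 2 + sin(pi x) sin(pi y)
  model <- material_model("neo_hookean_plane_strain", nu = 0.3)
  a <- 0.05; b <- 0.03; cc <- 0.04
  ufun <- function(x, y) c(a * x^2 + b * x * y, cc * y^2)
  Efun <- function(x, y) 2 + sin(pi * x) * sin(pi * y)
  Pfun <- function(x, y) {
    F <- cbind(1 + 2 * a * x + b * y, b * x, 0, 1 + 2 * cc * y)
    elastinv:::pk1_stress_vec(F, Efun(x, y), model)$P
  }
  set.seed(3)
  x <- runif(8, 0.2, 0.8); y <- runif(8, 0.2, 0.8)
  Fm <- cbind(1 + 2 * a * x + b * y, b * x, rep(0, 8), 1 + 2 * cc * y)
  dF <- list(x = cbind(rep(2 * a, 8), rep(b, 8), 0, 0),
             y = cbind(rep(b, 8), rep(0, 8), 0, rep(2 * cc, 8)))
  sE <- pi * cos(pi * x) * sin(pi * y)
  dE <- list(x = sE, y = pi * sin(pi * x) * cos(pi * y))
  res <- pde_residual(F = Fm, E = Efun(x, y), dF = dF, dE = dE, model = model)
  # FD oracle: divergence of P(x, y) by central differences
  h <- 1e-6
  for (i in seq_along(x)) {
    dPx <- (Pfun(x[i] + h, y[i]) - Pfun(x[i] - h, y[i])) / (2 * h)
    dPy <- (Pfun(x[i], y[i] + h) - Pfun(x[i], y[i] - h)) / (2 * h)
    oracle <- c(dPx[1, 1] + dPy[1, 2], dPx[1, 3] + dPy[1, 4])
    expect_equal(unname(res[i, ]), oracle, tolerance = 1e-5)
  }
})

test_that("training gradients agree with finite differences of the total loss", {
  # double-precision engine; Richardson-extrapolated central differences
  mesh <- small_mesh(3)
  model <- material_model("neo_hookean_plane_strain", nu = 0.3)
  sol <- solve_forward(mesh, rep(2, nrow(mesh$elements)), model,
                       equibiaxial_bc(0.1))
  tf <- output_transforms(u_mean = c(0, 0), u_std = c(0.1, 0.1), d = 0.1)
  w <- loss_weights()
  for (code in c("IIB", "IA", "IVD", "IIIC")) {
    spec <- architecture_spec(code, seed = 4)
    net <- build_network(spec, sol$strains$points, precision = "double")
    st <- elastinv:::pinn_step(net, net$theta, sol$strains, model, w, tf,
                               want_seeds = TRUE)
    g <- elastinv:::mlp_engine_backward(net$engine, st$seeds)
    lossf <- function(th)
      elastinv:::pinn_step(net, th, sol$strains, model, w, tf,
                           want_seeds = FALSE)$losses$total
    set.seed(10)
    for (i in sample(length(net$theta), 8)) {
      fd <- vapply(c(1e-4, 1e-5), function(h) {
        tp <- net$theta; tp[i] <- tp[i] + h
        tm <- net$theta; tm[i] <- tm[i] - h
        (lossf(tp) - lossf(tm)) / (2 * h)
      }, 0)
      rich <- (100 * fd[2] - fd[1]) / 99
      expect_lt(abs(g[i] - rich) / max(abs(rich), abs(g[i]), 1e-6), 1e-4)
    }
  }
})

test_that("zero-iteration training returns the initialized transform state", {
  mesh <- small_mesh(3)
  model <- material_model("neo_hookean_plane_strain")
  sol <- solve_forward(mesh, rep(2, nrow(mesh$elements)), model,
                       equibiaxial_bc(0.2))
  fit <- train_pinn(architecture_spec("VB", seed = 1), model, sol$strains,
                    iters = 0L)
  expect_identical(nrow(fit$history), 0L)
  pred <- predict(fit)
  expect_true(all(pred$E > 1 & pred$E < 5))
  net0 <- build_network(architecture_spec("VB", seed = 1), sol$strains$points)
  expect_identical(fit$net$theta, net0$theta)
})

test_that("training is deterministic under a fixed seed", {
  mesh <- small_mesh(3)
  model <- material_model("neo_hookean_plane_strain")
  sol <- solve_forward(mesh, rep(2, nrow(mesh$elements)), model,
                       equibiaxial_bc(0.2))
  run <- function() {
    fit <- train_pinn(architecture_spec("IIB", seed = 5), model, sol$strains,
                      iters = 60L, log_every = 30L)
    fit$history$total
  }
  expect_identical(run(), run())
})

test_that("every architecture variant trains without error", {
  mesh <- small_mesh(2)
  model <- material_model("neo_hookean_plane_strain")
  sol <- solve_forward(mesh, rep(2, nrow(mesh$elements)), model,
                       equibiaxial_bc(0.2))
  for (fc in c("I", "II", "III", "IV", "V")) for (v in c("A", "B", "C", "D")) {
    fit <- train_pinn(architecture_spec(fcnn = fc, variant = v, seed = 1),
                      model, sol$strains, iters = 5L, log_every = 5L)
    expect_true(is.finite(fit$history$total[1]))
  }
})

test_that("constitutive-term architectures run with the weight disabled", {
  mesh <- small_mesh(2)
  model <- material_model("neo_hookean_plane_strain")
  sol <- solve_forward(mesh, rep(2, nrow(mesh$elements)), model,
                       equibiaxial_bc(0.2))
  fit <- train_pinn(architecture_spec("IIB", seed = 1), model, sol$strains,
                    weights = loss_weights(w_const = 0), iters = 20L,
                    log_every = 20L)
  expect_true(is.finite(fit$history$total[1]))
  expect_equal(fit$history$total[1],
               with(fit$history, 1 * pde[1] + 100 * data[1]),
               tolerance = 1e-10)
})
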