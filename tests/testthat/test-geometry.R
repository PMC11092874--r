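test_that("crossed mesh has the expected node and element counts", {
  for (n in c(1L, 2L, 3L, 7L, 16L, 50L)) {
    m <- make_crossed_mesh(n)
    expect_identical(nrow(m$elements), as.integer(4 * n^2))
    expect_identical(nrow(m$nodes), as.integer((n + 1)^2 + n^2))
  }
  expect_error(make_crossed_mesh(0), "invalid resolution")
  expect_error(make_crossed_mesh(2.5), "invalid resolution")
})

test_that("all elements are counterclockwise and tile the unit square", {
  for (n in c(1L, 4L, 11L)) {
    m <- make_crossed_mesh(n)
    a <- element_areas(m)
    expect_true(all(a > 0))
    expect_lt(abs(sum(a) - 1), 1e-12)
    expect_true(all(m$nodes >= 0 & m$nodes <= 1))
  }
})

test_that("boundary nodes lie exactly on the boundary", {
  m <- make_crossed_mesh(5)
  bn <- boundary_nodes(m)
  expect_identical(length(bn), 4L * 5L)  # 4n boundary vertices
  xy <- m$nodes[bn, ]
  on_b <- xy[, 1] %in% c(0, 1) | xy[, 2] %in% c(0, 1)
  expect_true(all(on_b))
})

test_that("GRF draws are reproducible and perfectly correlated in the long-length limit", {
  m <- small_mesh(4)
  s <- grf_spec(correlation_length = 0.1, seed = 42)
  f1 <- sample_grf(m, s)
  f2 <- sample_grf(m, s)
  expect_identical(f1, f2)
  expect_identical(length(f1), nrow(m$nodes))
  # l >> domain: all nodal values identical per draw (spread ~ r/l per pair)
  flong <- sample_grf(m, grf_spec(correlation_length = 1e4, seed = 7))
  expect_lt(diff(range(flong)), 1e-3)
})

test_that("GRF ensemble statistics match the squared-exponential kernel", {
  # two fixed points at distance r = 0.1: empirical covariance ~ exp(-1/2)
  m <- small_mesh(10)  # grid spacing 0.1
  idx <- c(1L, 2L)     # (0,0) and (0.1, 0)
  expect_equal(sqrt(sum((m$nodes[idx[1], ] - m$nodes[idx[2], ])^2)), 0.1)
  draws <- sample_grf(m, grf_spec(correlation_length = 0.1, seed = 3),
                      n_draws = 2000L)
  v <- draws[idx, ]
  emp_cov <- mean(v[1, ] * v[2, ])
  # std error of the product-moment estimate
  se <- stats::sd(v[1, ] * v[2, ]) / sqrt(ncol(draws))
  expect_lt(abs(emp_cov - exp(-0.5)), 3 * se)
  # marginal mean within 3 sigma/sqrt(N), variance within 5%
  one <- draws[5L, ]
  expect_lt(abs(mean(one)), 3 / sqrt(length(one)))
  expect_lt(abs(stats::var(one) - 1), 0.05 * 1 + 3 * se)
})

test_that("element modulus follows the sum rule and its bounds", {
  m <- small_mesh(3)
  np <- nrow(m$nodes)
  expect_equal(element_modulus(rep(0, np), m), rep(1, nrow(m$elements)))
  expect_equal(element_modulus(rep(1, np), m), rep(4, nrow(m$elements)))
  # direct substitution on one element
  f <- numeric(np)
  e1 <- m$elements[1L, ]
  f[e1] <- c(0.1, 0.2, 0.3)
  expect_equal(element_modulus(f, m)[1L], 1.6)
  # average convention
  expect_equal(element_modulus(rep(1, np), m, convention = "average"),
               rep(2, nrow(m$elements)))
  expect_error(element_modulus(rep(0, np - 1L), m), "does not match")
  expect_error(element_modulus(rep(2, np), m), "\\[0, 1\\]")
})

test_that("element modulus is monotone in every nodal intensity", {
  set.seed(5)
  m <- small_mesh(3)
  f <- runif(nrow(m$nodes))
  E0 <- element_modulus(f, m)
  for (i in sample(length(f), 10)) {
    f2 <- f
    f2[i] <- min(1, f2[i] + 0.2)
    expect_true(all(element_modulus(f2, m) >= E0 - 1e-14))
  }
})

test_that("image mapping reproduces a linear intensity ramp", {
  W <- 64L
  img <- matrix(rep((seq_len(W) - 0.5) / W, each = W), W, W)  # I(u,v) = u
  m <- make_crossed_mesh(8)
  f <- image_to_nodal_field(img, m)
  interior <- m$nodes[, 1] > 0.05 & m$nodes[, 1] < 0.95
  expect_lt(max(abs(f[interior] - m$nodes[interior, 1])), 0.02)
})

test_that("min-max normalization puts checkerboard pixel centers at 0 and 1", {
  img <- matrix(c(0, 255, 255, 0), 2, 2)
  m <- make_crossed_mesh(2)  # cell centers coincide with pixel centers
  f <- image_to_nodal_field(img, m)
  centers <- which(seq_len(nrow(m$nodes)) > 9L)  # the 4 cell-center nodes
  expect_true(all(f[centers] %in% c(0, 1)))
  expect_error(image_to_nodal_field(matrix(3, 4, 4), m),
               "degenerate normalization")
})

test_that("separable bicubic evaluation matches a direct per-cell oracle", {
  # oracle: direct 4x4 double sum of the Keys kernel, written independently
  keys_w <- function(x) {
    a <- -0.5; ax <- abs(x)
    if (ax <= 1) (a + 2) * ax^3 - (a + 3) * ax^2 + 1
    else if (ax < 2) a * ax^3 - 5 * a * ax^2 + 8 * a * ax - 4 * a
    else 0
  }
  oracle <- function(img, px, py) {
    H <- nrow(img); W <- ncol(img)
    gx <- px * W + 0.5; gy <- py * H + 0.5
    c0 <- floor(gx); r0 <- floor(gy)
    val <- 0
    for (dr in -1:2) for (dc in -1:2) {
      rr <- min(max(r0 + dr, 1), H); cc <- min(max(c0 + dc, 1), W)
      val <- val + keys_w(gy - (r0 + dr)) * keys_w(gx - (c0 + dc)) * img[rr, cc]
    }
    val
  }
  set.seed(8)
  img <- matrix(runif(64 * 64), 64, 64)
  px <- runif(10, 0.05, 0.95); py <- runif(10, 0.05, 0.95)
  mine <- elastinv:::bicubic_eval(img, px, py)
  ref <- vapply(seq_along(px), function(i) oracle(img, px[i], py[i]), 0)
  expect_lt(max(abs(mine - ref)), 1e-6)
})

test_that("mesh export writes readable VTU and text listings", {
  m <- small_mesh(2)
  td <- withr::local_tempdir()
  vtu <- file.path(td, "mesh.vtu")
  write_vtu(m, vtu, point_data = list(f = seq_len(nrow(m$nodes))),
            cell_data = list(E = seq_len(nrow(m$elements))))
  expect_true(file.exists(vtu))
  doc <- readLines(vtu)
  expect_true(any(grepl("UnstructuredGrid", doc)))
  files <- write_mesh_text(m, file.path(td, "mesh"))
  expect_identical(nrow(utils::read.table(files[1], header = TRUE)),
                   nrow(m$nodes))
  expect_identical(nrow(utils::read.table(files[2], header = TRUE)),
                   nrow(m$elements))
})
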