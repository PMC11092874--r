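#' L2 relative error
#'
#' `||pred - truth||_2 / ||truth||_2`, the primary accuracy metric for
#' recovered modulus and strain fields.
#'
#' @param pred,truth Numeric vectors of equal length.
#' @return Scalar relative error.
#' @export
l2_relative_error <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  nt <- sqrt(sum(truth^2))
  if (nt == 0) stop("undefined metric: truth has zero norm")
  sqrt(sum((pred - truth)^2)) / nt
}

#' Pointwise absolute error
#'
#' @param pred,truth Numeric vectors of equal length.
#' @return List with `error` (|pred - truth| per point) and `max`.
#' @export
pointwise_abs_error <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  e <- abs(pred - truth)
  list(error = e, max = max(e))
}

#' Inject white Gaussian noise into a strain field
#'
#' Adds independent zero-mean Gaussian noise to each strain component with a
#' component-wise relative amplitude: the noise standard deviation for
#' component `c` is `level * sd(c)`. `level = 0.05` corresponds to "5% noise".
#'
#' @param strains A [strain_field()].
#' @param level Noise fraction `p >= 0`.
#' @param seed Integer seed; fixed seed reproduces the same noise.
#' @return A new `strain_field` with noisy components.
#' @export
add_strain_noise <- function(strains, level, seed = 1L) {
  stopifnot(inherits(strains, "strain_field"))
  if (level < 0) stop("noise level must be >= 0")
  if (level == 0) return(strains)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  n <- nrow(strains$points)
  noisy <- lapply(c("exx", "eyy", "exy"), function(c) {
    strains[[c]] + stats::rnorm(n, sd = level * stats::sd(strains[[c]]))
  })
  strain_field(strains$points, noisy[[1L]], noisy[[2L]], noisy[[3L]])
}

#' Delentropy of a grayscale image
#'
#' An image-complexity score: half the Shannon entropy of the joint histogram
#' of per-pixel gradient pairs. Gradients are estimated by convolution with
#' the 3x3 central-difference kernel `[[-1,0,1],[-1,0,1],[-1,0,1]]` (x) and
#' its transpose (y), trimming the one-pixel boundary. The joint (dx, dy)
#' histogram is normalized to sum to one before the entropy sum
#' `DE = -1/2 sum p log2 p`.
#'
#' @param image Numeric matrix, at least 3x3 (rows = y, columns = x).
#' @param bins Number of histogram bins per gradient axis (default 256).
#' @return An object of class `delentropy_result` with fields `DE` (bits),
#'   `deldensity` (the bins x bins probability matrix), `dx_edges`,
#'   `dy_edges`.
#' @export
delentropy <- function(image, bins = 256L) {
  stopifnot(is.matrix(image))
  if (nrow(image) < 3L || ncol(image) < 3L)
    stop("image must be at least 3x3 for the gradient kernel")
  gr <- image_gradients(image)
  dx <- gr$dx; dy <- gr$dy
  rx <- range(dx); ry <- range(dy)
  # widen degenerate ranges so constant-gradient images land in one bin
  if (rx[2] - rx[1] <= 0) rx <- rx + c(-0.5, 0.5)
  if (ry[2] - ry[1] <= 0) ry <- ry + c(-0.5, 0.5)
  xe <- seq(rx[1], rx[2], length.out = bins + 1L)
  ye <- seq(ry[1], ry[2], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(dx, xe, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(dy, ye, rightmost.closed = TRUE), 1L), bins)
  tab <- table(factor(ix, levels = seq_len(bins)),
               factor(iy, levels = seq_len(bins)))
  p <- as.numeric(tab) / sum(tab)
  nz <- p > 0
  DE <- -0.5 * sum(p[nz] * log2(p[nz]))
  structure(list(DE = DE, deldensity = matrix(p, bins, bins),
                 dx_edges = xe, dy_edges = ye),
            class = "delentropy_result")
}

#' @export
print.delentropy_result <- function(x, ...) {
  cat(sprintf("Delentropy: %.4f bits (%d occupied bins)\n",
              x$DE, sum(x$deldensity > 0)))
  invisible(x)
}

# "Valid" convolution of the image with the central-difference kernels.
# Kernel [[-1,0,1],[-1,0,1],[-1,0,1]] applied along x (columns), its
# transpose along y (rows); correlation convention (no kernel flip), one-pixel
# boundary trimmed.
image_gradients <- function(image) {
  H <- nrow(image); W <- ncol(image)
  rows <- 2:(H - 1L); cols <- 2:(W - 1L)
  right <- image[rows - 1L, cols + 1L] + image[rows, cols + 1L] + image[rows + 1L, cols + 1L]
  left  <- image[rows - 1L, cols - 1L] + image[rows, cols - 1L] + image[rows + 1L, cols - 1L]
  down  <- image[rows + 1L, cols - 1L] + image[rows + 1L, cols] + image[rows + 1L, cols + 1L]
  up    <- image[rows - 1L, cols - 1L] + image[rows - 1L, cols] + image[rows - 1L, cols + 1L]
  list(dx = right - left, dy = down - up)
}

#' Rasterize a nodal field to a regular grid
#'
#' Samples a piecewise-linear nodal field of a crossed mesh on a uniform
#' pixel grid (barycentric interpolation), e.g. to compute the [delentropy()]
#' of a modulus or intensity map.
#'
#' @param mesh An `elastinv_mesh`.
#' @param values Per-node numeric vector.
#' @param resolution Grid size (pixels per side, default 128).
#' @return `resolution` x `resolution` numeric matrix (rows = y from bottom).
#' @export
rasterize_nodal_field <- function(mesh, values, resolution = 128L) {
  stopifnot(length(values) == nrow(mesh$nodes))
  n <- mesh$n
  px <- (seq_len(resolution) - 0.5) / resolution
  P <- cbind(rep(px, times = resolution), rep(px, each = resolution))
  # locate the cell, then which of its 4 triangles contains the point
  ci <- pmin(floor(P[, 1L] * n), n - 1L)
  cj <- pmin(floor(P[, 2L] * n), n - 1L)
  lx <- P[, 1L] * n - ci; ly <- P[, 2L] * n - cj   # local in [0,1]
  # triangles: south (ly <= lx, ly <= 1-lx), east (lx >= ...), etc.
  tri <- integer(nrow(P))
  tri[ly <= pmin(lx, 1 - lx)] <- 0L                       # south
  tri[lx >= pmax(ly, 1 - ly)] <- 1L                       # east
  tri[ly >= pmax(lx, 1 - lx)] <- 2L                       # north
  tri[lx <= pmin(ly, 1 - ly)] <- 3L                       # west
  eidx <- 4L * (cj * n + ci) + tri + 1L
  e <- mesh$elements[eidx, , drop = FALSE]
  x1 <- mesh$nodes[e[, 1L], 1L]; y1 <- mesh$nodes[e[, 1L], 2L]
  x2 <- mesh$nodes[e[, 2L], 1L]; y2 <- mesh$nodes[e[, 2L], 2L]
  x3 <- mesh$nodes[e[, 3L], 1L]; y3 <- mesh$nodes[e[, 3L], 2L]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  l2 <- ((P[, 1L] - x1) * (y3 - y1) - (P[, 2L] - y1) * (x3 - x1)) / det
  l3 <- ((P[, 2L] - y1) * (x2 - x1) - (P[, 1L] - x1) * (y2 - y1)) / det
  l1 <- 1 - l2 - l3
  v <- l1 * values[e[, 1L]] + l2 * values[e[, 2L]] + l3 * values[e[, 3L]]
  matrix(v, resolution, resolution, byrow = TRUE)
}
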