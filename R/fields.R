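#' Gaussian random field specification
#'
#' Squared-exponential (radial basis) covariance
#' \eqn{k(r) = \sigma^2 \exp(-r^2 / (2 l^2))}. The default correlation length
#' `l = 0.1` generates the heterogeneous stiffness patterns used for the fully
#' synthetic example.
#'
#' @param correlation_length Correlation length `l` (> 0, dimensionless).
#' @param variance Marginal variance `sigma^2` (> 0).
#' @param seed Integer seed; every draw is reproducible under a fixed seed.
#' @return An object of class `grf_spec`.
#' @export
grf_spec <- function(correlation_length = 0.1, variance = 1, seed = 1L) {
  if (correlation_length <= 0) stop("correlation_length must be > 0")
  if (variance <= 0) stop("variance must be > 0")
  structure(list(correlation_length = correlation_length,
                 variance = variance, seed = as.integer(seed)),
            class = "grf_spec")
}

#' Sample a mean-zero Gaussian random field at mesh nodes
#'
#' Draws one realization of a mean-zero Gaussian process with
#' squared-exponential covariance evaluated at the node coordinates, via a
#' Cholesky factorization of the dense covariance matrix (with an escalating
#' diagonal jitter for numerical positive definiteness).
#'
#' @param mesh An `elastinv_mesh`.
#' @param spec A `grf_spec`.
#' @param n_draws Number of independent realizations (default 1).
#' @return A numeric vector of nodal values (one per node), or a matrix with
#'   `n_draws` columns when `n_draws > 1`.
#' @export
sample_grf <- function(mesh, spec, n_draws = 1L) {
  stopifnot(inherits(mesh, "elastinv_mesh"), inherits(spec, "grf_spec"))
  L <- grf_chol(mesh$nodes, spec$correlation_length, spec$variance)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  z <- matrix(stats::rnorm(nrow(mesh$nodes) * n_draws), nrow(mesh$nodes))
  f <- L %*% z
  if (n_draws == 1L) drop(f) else f
}

# Lower-triangular Cholesky factor of the squared-exponential covariance,
# with jitter escalation; errors out if the matrix stays indefinite.
grf_chol <- function(xy, l, s2) {
  d2 <- as.matrix(stats::dist(xy))^2
  K <- s2 * exp(-d2 / (2 * l^2))
  jitter <- 1e-10 * s2
  for (k in 1:8) {
    ok <- tryCatch({ R <- chol(K + diag(jitter, nrow(K))); TRUE },
                   error = function(e) FALSE)
    if (ok) return(t(R))
    jitter <- jitter * 10
  }
  stop("numerical conditioning: covariance matrix not positive definite ",
       "after jitter escalation")
}

#' Min-max normalization to [0, 1]
#'
#' @param x Numeric vector.
#' @return `(x - min) / (max - min)`.
#' @export
minmax_normalize <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0)
    stop("degenerate normalization: field is constant (max equals min)")
  (x - r[1]) / (r[2] - r[1])
}

#' Map a grayscale image onto mesh nodes
#'
#' Crops a rectangular region of the image, rescales it to the unit square,
#' min-max normalizes the intensities to `[0, 1]`, and evaluates a bicubic
#' interpolant (Keys convolution kernel, a = -0.5, pixel centers at
#' `(i - 0.5) / n_pixels`) at the node coordinates. Output values are clipped
#' to `[0, 1]`.
#'
#' @param image Numeric matrix of intensities; rows index the image y
#'   direction (top to bottom), columns the x direction. See
#'   [read_gray_image()] for PNG/TIFF input.
#' @param mesh An `elastinv_mesh`.
#' @param crop Optional `c(x0, x1, y0, y1)` in pixel units (1-based, inclusive)
#'   selecting columns `x0:x1` and rows `y0:y1`; default is the whole image.
#' @return Numeric vector of nodal intensities in `[0, 1]`.
#' @export
image_to_nodal_field <- function(image, mesh, crop = NULL) {
  stopifnot(is.matrix(image), nrow(image) >= 1, ncol(image) >= 1)
  if (!is.null(crop)) {
    stopifnot(length(crop) == 4)
    if (crop[1] < 1 || crop[2] > ncol(image) || crop[3] < 1 ||
        crop[4] > nrow(image) || crop[1] > crop[2] || crop[3] > crop[4])
      stop("crop rectangle outside image bounds")
    image <- image[crop[3]:crop[4], crop[1]:crop[2], drop = FALSE]
  }
  r <- range(image)
  if (r[2] - r[1] <= 0)
    stop("degenerate normalization: image is constant (max equals min)")
  img <- (image - r[1]) / (r[2] - r[1])
  # image row 1 is the top: flip so that v = 0 is the bottom of the unit square
  img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  v <- bicubic_eval(img, mesh$nodes[, 1L], mesh$nodes[, 2L])
  pmin(pmax(v, 0), 1)
}

#' Read a grayscale PNG or TIFF image
#'
#' Loads an 8- or 16-bit image and collapses color channels (if present) by
#' averaging. Requires the `png` or `tiff` package.
#'
#' @param path Image file path (`.png`, `.tif`, `.tiff`).
#' @return Numeric matrix of intensities in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = { requireNamespace("png"); png::readPNG(path) },
    tif = ,
    tiff = { requireNamespace("tiff"); tiff::readTIFF(path) },
    stop("unsupported image format: ", ext))
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                       c(1, 2), mean)
  a
}

# Keys bicubic convolution kernel, a = -0.5 (the classic imaging "cubic").
cubic_kernel_weights <- function(t) {
  # weights for samples at offsets -1, 0, 1, 2 given fractional position t in [0,1)
  a <- -0.5
  w <- function(x) {
    ax <- abs(x)
    ifelse(ax <= 1, (a + 2) * ax^3 - (a + 3) * ax^2 + 1,
           ifelse(ax < 2, a * ax^3 - 5 * a * ax^2 + 8 * a * ax - 4 * a, 0))
  }
  cbind(w(t + 1), w(t), w(t - 1), w(t - 2))
}

# Evaluate the separable bicubic convolution interpolant of a matrix img
# (rows = y from bottom, cols = x) at unit-square points (px, py).
# Pixel (row r, col c) has center ((c-0.5)/W, (r-0.5)/H); edge pixels are
# replicated outside the grid.
bicubic_eval <- function(img, px, py) {
  H <- nrow(img); W <- ncol(img)
  gx <- px * W + 0.5   # continuous column coordinate (pixel centers at integers)
  gy <- py * H + 0.5
  c0 <- floor(gx); r0 <- floor(gy)
  tx <- gx - c0; ty <- gy - r0
  wx <- cubic_kernel_weights(tx)
  wy <- cubic_kernel_weights(ty)
  clampc <- function(i) pmin(pmax(i, 1L), W)
  clampr <- function(i) pmin(pmax(i, 1L), H)
  out <- numeric(length(px))
  for (dr in 0:3) {
    rows <- clampr(as.integer(r0) - 1L + dr)
    acc <- numeric(length(px))
    for (dc in 0:3) {
      cols <- clampc(as.integer(c0) - 1L + dc)
      acc <- acc + wx[, dc + 1L] * img[cbind(rows, cols)]
    }
    out <- out + wy[, dr + 1L] * acc
  }
  out
}

#' Element-wise modulus from a nodal intensity field
#'
#' Converts a nodal intensity field `f` in `[0, 1]` to one elastic modulus per
#' element. The default rule is the sum of the three vertex intensities plus
#' one, `E_ele = f(x1) + f(x2) + f(x3) + 1`, giving moduli in `[1, 4]`; the
#' `"average"` convention uses the mean of the vertex intensities instead
#' (range `[1, 2]`).
#'
#' @param field Numeric vector of nodal intensities in `[0, 1]`.
#' @param mesh An `elastinv_mesh`.
#' @param convention `"sum"` (default) or `"average"`.
#' @return Numeric vector of element moduli.
#' @export
element_modulus <- function(field, mesh, convention = c("sum", "average")) {
  convention <- match.arg(convention)
  if (length(field) != nrow(mesh$nodes))
    stop("field length (", length(field), ") does not match node count (",
         nrow(mesh$nodes), ")")
  if (any(field < -1e-12) || any(field > 1 + 1e-12))
    stop("field values must lie in [0, 1]; min-max normalize first")
  e <- mesh$elements
  s <- field[e[, 1L]] + field[e[, 2L]] + field[e[, 3L]]
  if (convention == "sum") s + 1 else s / 3 + 1
}

#' Normalize an element modulus field to span its admissible range
#'
#' Affinely rescales a modulus field so that its minimum and maximum equal
#' `lower` and `upper` (default `[1, 4]`, the range of the sum rule). The
#' bounded sigmoid output transform of the inverse network identifies the
#' modulus only up to a global scale factor unless the true field touches the
#' modulus floor; at fine resolution the intensity extremes are attained
#' within single elements and the sum rule spans `[1, 4]` on its own, while a
#' coarse mesh leaves a draw-dependent gap. This normalization makes the
#' floor-touching identifiability condition hold by construction at every
#' resolution.
#'
#' @param E Numeric vector of element moduli.
#' @param lower,upper Target range.
#' @return Rescaled modulus vector with `min = lower`, `max = upper`.
#' @export
normalize_modulus_range <- function(E, lower = 1, upper = 4) {
  r <- range(E)
  if (r[2] - r[1] <= 0)
    stop("degenerate normalization: modulus field is constant")
  lower + (upper - lower) * (E - r[1]) / (r[2] - r[1])
}

# Save/restore the global RNG state so seeded draws do not disturb the
# caller's random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
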