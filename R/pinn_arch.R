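#' @keywords internal
#' @aliases elastinv-package
#' @useDynLib elastinv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

#' PINN architecture specification
#'
#' One of the twenty network variants: a fully connected topology
#' (FCNN `"I"` to `"V"`) combined with a letter variant encoding the input
#' features and boundary treatment: `A` = standard inputs + hard boundary
#' constraint, `B` = standard inputs, free boundary, `C` = Fourier features +
#' hard constraint, `D` = Fourier features, free boundary. FCNN I and II emit
#' direct stress outputs and train with a constitutive-relation loss; FCNN
#' III-V derive stress from displacement and modulus only.
#'
#' @param code Architecture code such as `"IIB"` or `"IVC"` (FCNN numeral
#'   then variant letter); alternatively pass `fcnn` and `variant`.
#' @param fcnn,variant Explicit FCNN (`"I"`..`"V"`) and variant (`"A"`..`"D"`).
#' @param seed Integer seed for parameter initialization and training.
#' @return An object of class `architecture_spec` with fields `fcnn`,
#'   `variant`, `fourier`, `hard_bc`, `activation`, `seed`.
#' @examples
#' architecture_spec("IIB")
#' @export
architecture_spec <- function(code = NULL, fcnn = NULL, variant = NULL,
                              seed = 1L) {
  if (!is.null(code)) {
    m <- regmatches(code, regexec("^(I{1,3}|IV|V)([A-D])$", code))[[1L]]
    if (length(m) != 3L)
      stop("invalid architecture code '", code,
           "': expected FCNN numeral I-V followed by variant letter A-D")
    fcnn <- m[2L]; variant <- m[3L]
  }
  if (!fcnn %in% c("I", "II", "III", "IV", "V"))
    stop("fcnn must be one of I, II, III, IV, V")
  if (!variant %in% c("A", "B", "C", "D"))
    stop("variant must be one of A, B, C, D")
  structure(list(fcnn = fcnn, variant = variant,
                 fourier = variant %in% c("C", "D"),
                 hard_bc = variant %in% c("A", "C"),
                 activation = "swish", seed = as.integer(seed)),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("PINN architecture %s%s: %s inputs, %s boundary, Swish, seed %d\n",
              x$fcnn, x$variant,
              if (x$fourier) "Fourier-feature (12)" else "coordinate (2)",
              if (x$hard_bc) "hard-constrained" else "free", x$seed))
  invisible(x)
}

#' Branch topology of an FCNN variant
#'
#' Returns the multi-branch layer layout and the mapping from named outputs
#' (`ux`, `uy`, `E`, and `P11`, `P12`, `P21`, `P22` for FCNN I/II) to branch
#' output columns. Branch `parent = 0` reads the input features; otherwise the
#' branch reads the final hidden activation of its parent (a shared trunk).
#'
#' Topologies: FCNN I: a shared 2x50 displacement trunk feeding two 2x50
#' single-output branches, plus an independent 5x75 network emitting the
#' modulus and the four stress components. FCNN II: two independent 5x75
#' networks, one for displacement, one for modulus + stress. FCNN III: a
#' shared 2x25 trunk feeding three 3x25 single-output branches (ux, uy, E).
#' FCNN IV: three independent 5x25 single-output networks. FCNN V: one 5x50
#' network with three outputs.
#'
#' @param fcnn `"I"`..`"V"`.
#' @return List with `branches` (list of `parent`/`widths`/`out`) and `slots`
#'   (named list of `c(branch, column)`).
#' @export
fcnn_topology <- function(fcnn) {
  h <- function(w, k) rep(w, k)
  switch(fcnn,
    I = list(
      branches = list(
        list(parent = 0L, widths = h(50, 2), out = 0L),
        list(parent = 1L, widths = h(50, 2), out = 1L),
        list(parent = 1L, widths = h(50, 2), out = 1L),
        list(parent = 0L, widths = h(75, 5), out = 5L)),
      slots = list(ux = c(2L, 1L), uy = c(3L, 1L), E = c(4L, 1L),
                   P11 = c(4L, 2L), P12 = c(4L, 3L), P21 = c(4L, 4L),
                   P22 = c(4L, 5L))),
    II = list(
      branches = list(
        list(parent = 0L, widths = h(75, 5), out = 2L),
        list(parent = 0L, widths = h(75, 5), out = 5L)),
      slots = list(ux = c(1L, 1L), uy = c(1L, 2L), E = c(2L, 1L),
                   P11 = c(2L, 2L), P12 = c(2L, 3L), P21 = c(2L, 4L),
                   P22 = c(2L, 5L))),
    III = list(
      branches = list(
        list(parent = 0L, widths = h(25, 2), out = 0L),
        list(parent = 1L, widths = h(25, 3), out = 1L),
        list(parent = 1L, widths = h(25, 3), out = 1L),
        list(parent = 1L, widths = h(25, 3), out = 1L)),
      slots = list(ux = c(2L, 1L), uy = c(3L, 1L), E = c(4L, 1L))),
    IV = list(
      branches = list(
        list(parent = 0L, widths = h(25, 5), out = 1L),
        list(parent = 0L, widths = h(25, 5), out = 1L),
        list(parent = 0L, widths = h(25, 5), out = 1L)),
      slots = list(ux = c(1L, 1L), uy = c(2L, 1L), E = c(3L, 1L))),
    V = list(
      branches = list(
        list(parent = 0L, widths = h(50, 5), out = 3L)),
      slots = list(ux = c(1L, 1L), uy = c(1L, 2L), E = c(1L, 3L))),
    stop("unknown FCNN variant: ", fcnn))
}

#' Fourier feature map
#'
#' Maps a coordinate pair to the 12-vector
#' `[x, y, sin(pi x), ..., sin(5 pi x), sin(pi y), ..., sin(5 pi y)]`:
#' the raw coordinates are retained alongside five sine modes per input
#' variable.
#'
#' @param x,y Coordinate vectors of equal length.
#' @return Matrix with `length(x)` rows and 12 columns.
#' @examples
#' fourier_features(0.5, 0.5)
#' @export
fourier_features <- function(x, y) {
  k <- outer(x, pi * (1:5))
  m <- outer(y, pi * (1:5))
  cbind(x, y, sin(k), sin(m), deparse.level = 0)
}

# Feature matrices with spatial derivatives, stacked channel-wise
# ([val; dx; dy] or [val; dx; dy; dxx; dxy; dyy]) for the network engine.
feature_stack <- function(x, y, fourier, order) {
  n <- length(x)
  zero <- matrix(0, n, 1L)
  one <- matrix(1, n, 1L)
  if (!fourier) {
    val <- cbind(x, y, deparse.level = 0)
    dx <- cbind(one, zero); dy <- cbind(zero, one)
    d2 <- cbind(zero, zero)
    chans <- if (order == 2) list(val, dx, dy, d2, d2, d2)
             else list(val, dx, dy)
  } else {
    i5 <- pi * (1:5)
    kx <- outer(x, i5); ky <- outer(y, i5)
    zx <- matrix(0, n, 5L)
    val <- cbind(x, y, sin(kx), sin(ky), deparse.level = 0)
    dx <- cbind(one, zero, sweep(cos(kx), 2, i5, `*`), zx)
    dy <- cbind(zero, one, zx, sweep(cos(ky), 2, i5, `*`))
    if (order == 2) {
      dxx <- cbind(zero, zero, -sweep(sin(kx), 2, i5^2, `*`), zx)
      dyy <- cbind(zero, zero, zx, -sweep(sin(ky), 2, i5^2, `*`))
      dxy <- cbind(zero, zero, zx, zx)
      chans <- list(val, dx, dy, dxx, dxy, dyy)
    } else chans <- list(val, dx, dy)
  }
  do.call(rbind, chans)
}

#' Build a PINN network
#'
#' Instantiates the network of an [architecture_spec()] at a fixed set of
#' collocation points: Glorot-uniform initial parameters under the spec's
#' seed, the feature map (coordinates or Fourier features) with its spatial
#' derivatives, and the compiled forward/backward engine.
#'
#' @param spec An `architecture_spec`.
#' @param points `N` x 2 matrix of collocation coordinates.
#' @param precision `"single"` (training default) or `"double"` (used by
#'   derivative verification).
#' @return An object of class `pinn_network` with the initialized parameter
#'   vector in `$theta`.
#' @export
build_network <- function(spec, points, precision = c("single", "double")) {
  stopifnot(inherits(spec, "architecture_spec"))
  precision <- match.arg(precision)
  topo <- fcnn_topology(spec$fcnn)
  order <- if (needs_second_derivatives(spec$fcnn)) 2L else 1L
  in_dim <- if (spec$fourier) 12L else 2L
  theta <- init_glorot(topo, in_dim, spec$seed)
  net <- list(spec = spec, topo = topo, order = order, in_dim = in_dim,
              points = as.matrix(points), precision = precision,
              theta = theta)
  net$engine <- make_engine(net, points, precision)
  class(net) <- "pinn_network"
  net
}

needs_second_derivatives <- function(fcnn) fcnn %in% c("III", "IV", "V")

make_engine <- function(net, points, precision) {
  feats <- feature_stack(points[, 1L], points[, 2L],
                         net$spec$fourier, net$order)
  mlp_engine_new(
    parents = vapply(net$topo$branches, function(b) b$parent, 1L) - 1L,
    widths = lapply(net$topo$branches, function(b) as.integer(b$widths)),
    outs = vapply(net$topo$branches, function(b) as.integer(b$out), 1L),
    feats_stacked = feats, n_points = nrow(points), order = net$order,
    single_precision = precision == "single")
}

#' @export
print.pinn_network <- function(x, ...) {
  cat(sprintf("PINN network %s%s: %d branches, %d parameters, %d collocation points (%s precision)\n",
              x$spec$fcnn, x$spec$variant, length(x$topo$branches),
              length(x$theta), nrow(x$points), x$precision))
  invisible(x)
}

#' Number of trainable parameters of an FCNN topology
#'
#' Counts weights and biases by direct enumeration of the branch layers.
#'
#' @param fcnn `"I"`..`"V"`.
#' @param in_dim Input width (2 standard, 12 Fourier).
#' @return Integer parameter count.
#' @export
count_parameters <- function(fcnn, in_dim = 2L) {
  topo <- fcnn_topology(fcnn)
  total <- 0L
  for (b in topo$branches) {
    prev <- if (b$parent == 0L) in_dim
            else utils::tail(topo$branches[[b$parent]]$widths, 1L)
    for (w in b$widths) { total <- total + prev * w + w; prev <- w }
    if (b$out > 0L) total <- total + prev * b$out + b$out
  }
  as.integer(total)
}

# Glorot-uniform initialization, packed in engine order (per branch, per
# layer: W column-major then b).
init_glorot <- function(topo, in_dim, seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  theta <- numeric(0)
  for (b in topo$branches) {
    prev <- if (b$parent == 0L) in_dim
            else utils::tail(topo$branches[[b$parent]]$widths, 1L)
    sizes <- c(b$widths, if (b$out > 0L) b$out)
    for (w in sizes) {
      lim <- sqrt(6 / (prev + w))
      theta <- c(theta, stats::runif(w * prev, -lim, lim), numeric(w))
      prev <- w
    }
  }
  theta
}

#' Output transforms
#'
#' Maps raw network outputs to physical fields. The displacement transform is
#' `u_i* = N_i sd_i + mean_i` (free boundary) or
#' `u_i* = g_i + l(x, y) (N_i sd_i + mean_i)` (hard constraint), with window
#' `l = 16 x (1 - x) y (1 - y)` vanishing on the boundary and particular
#' solution `g = (d (2x - 1), d (2y - 1))` carrying the prescribed boundary
#' displacement. The modulus transform is the bounded sigmoid map
#' `E* = 4 / (1 + exp(-N_E)) + 1`, confining the modulus to (1, 5).
#'
#' @param u_mean,u_std Length-2 normalization statistics of the displacement
#'   components (defaults `(0, 0)` mean and `(d, d)` std when no reference
#'   displacements are supplied to [train_pinn()]).
#' @param d Boundary displacement per side (defines `g`).
#' @return An object of class `output_transforms`.
#' @export
output_transforms <- function(u_mean = c(0, 0), u_std = c(0.2, 0.2), d = 0.2) {
  structure(list(u_mean = u_mean, u_std = u_std, d = d),
            class = "output_transforms")
}

#' Modulus transform
#'
#' `E* = 4 / (1 + exp(-n)) + 1`: a sigmoid bound confining the recovered
#' modulus to the physically admissible open interval (1, 5).
#'
#' @param n Raw network modulus output.
#' @return Transformed modulus values.
#' @export
modulus_transform <- function(n) 4 / (1 + exp(-n)) + 1

# Window function and derivatives for the hard boundary constraint.
hard_bc_window <- function(x, y) {
  list(l = 16 * x * (1 - x) * y * (1 - y),
       lx = 16 * (1 - 2 * x) * y * (1 - y),
       ly = 16 * x * (1 - x) * (1 - 2 * y),
       lxx = -32 * y * (1 - y),
       lxy = 16 * (1 - 2 * x) * (1 - 2 * y),
       lyy = -32 * x * (1 - x))
}

#' Apply output transforms to raw network outputs
#'
#' Reference implementation of the transform layer at individual points
#' (training uses the same formulas on whole channel matrices). Returns the
#' physical displacement and modulus for given raw outputs.
#'
#' @param raw Named list with `ux`, `uy`, `E` (raw network outputs,
#'   vectors over points).
#' @param x,y Coordinates of the points.
#' @param transforms An [output_transforms()].
#' @param hard_bc Apply the hard boundary constraint window?
#' @return List with `ux`, `uy` (physical displacements) and `E` (modulus in
#'   (1, 5)).
#' @export
apply_output_transforms <- function(raw, x, y, transforms, hard_bc = FALSE) {
  stopifnot(inherits(transforms, "output_transforms"))
  vx <- raw$ux * transforms$u_std[1L] + transforms$u_mean[1L]
  vy <- raw$uy * transforms$u_std[2L] + transforms$u_mean[2L]
  if (hard_bc) {
    l <- hard_bc_window(x, y)$l
    d <- transforms$d
    ux <- d * (2 * x - 1) + l * vx
    uy <- d * (2 * y - 1) + l * vy
  } else {
    ux <- vx; uy <- vy
  }
  list(ux = ux, uy = uy, E = modulus_transform(raw$E))
}
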