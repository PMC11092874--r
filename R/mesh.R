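#' Crossed triangulation of the unit square
#'
#' Builds the structured mesh used throughout the package: an `n` x `n` grid of
#' square cells, each split into four triangles by both diagonals, with one
#' extra node at every cell center. For resolution `n` the mesh has
#' `(n+1)^2 + n^2` nodes and `4 n^2` elements; `n = 50` gives the 5,101-node,
#' 10,000-element discretization on which the reference strain data are
#' generated.
#'
#' Node ordering is deterministic: the `(n+1)^2` grid vertices come first in
#' row-major order (x fastest), followed by the `n^2` cell-center nodes, also
#' row-major. Elements are listed cell by cell (row-major), four per cell
#' (south, east, north, west triangle), each with counterclockwise vertex
#' order.
#'
#' @param n Number of cells per side (positive integer).
#' @return An object of class `elastinv_mesh` with components:
#'   \describe{
#'     \item{nodes}{numeric matrix, `n_nodes` x 2, node coordinates in `[0,1]^2`.}
#'     \item{elements}{integer matrix, `n_elements` x 3, 1-based vertex indices,
#'       counterclockwise.}
#'     \item{n}{the resolution.}
#'   }
#' @examples
#' m <- make_crossed_mesh(50)
#' nrow(m$elements)  # 10000
#' nrow(m$nodes)     # 5101
#' @export
make_crossed_mesh <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("invalid resolution: n must be a positive integer")
  n <- as.integer(n)
  g <- seq(0, 1, length.out = n + 1L)
  grid <- cbind(rep(g, times = n + 1L), rep(g, each = n + 1L))
  cc <- (seq_len(n) - 0.5) / n
  centers <- cbind(rep(cc, times = n), rep(cc, each = n))
  nodes <- rbind(grid, centers)

  i <- rep(0:(n - 1L), times = n)          # cell column, row-major
  j <- rep(0:(n - 1L), each = n)           # cell row
  v00 <- j * (n + 1L) + i + 1L
  v10 <- v00 + 1L
  v01 <- v00 + (n + 1L)
  v11 <- v01 + 1L
  cen <- (n + 1L)^2 + j * n + i + 1L
  # south, east, north, west triangles per cell, all counterclockwise;
  # cell k (row-major) contributes elements 4k-3 .. 4k
  elements <- matrix(c(rbind(v00, v10, cen, v10, v11, cen,
                             v11, v01, cen, v01, v00, cen)),
                     ncol = 3L, byrow = TRUE)
  storage.mode(elements) <- "integer"
  structure(list(nodes = nodes, elements = elements, n = n),
            class = "elastinv_mesh")
}

#' @export
print.elastinv_mesh <- function(x, ...) {
  cat(sprintf("Crossed unit-square mesh: n = %d (%d nodes, %d elements)\n",
              x$n, nrow(x$nodes), nrow(x$elements)))
  invisible(x)
}

#' Signed element areas
#'
#' @param mesh An `elastinv_mesh`.
#' @return Numeric vector of signed areas (positive for counterclockwise
#'   elements), one per element.
#' @export
element_areas <- function(mesh) {
  e <- mesh$elements
  x <- matrix(mesh$nodes[e, 1L], ncol = 3L)
  y <- matrix(mesh$nodes[e, 2L], ncol = 3L)
  0.5 * ((x[, 2L] - x[, 1L]) * (y[, 3L] - y[, 1L]) -
         (x[, 3L] - x[, 1L]) * (y[, 2L] - y[, 1L]))
}

#' Boundary node indices
#'
#' Nodes lying on the boundary of the unit square. Only grid vertices can be
#' boundary nodes in a crossed mesh.
#'
#' @param mesh An `elastinv_mesh`.
#' @return Integer vector of 1-based node indices.
#' @export
boundary_nodes <- function(mesh) {
  xy <- mesh$nodes
  tol <- 1e-12
  which(xy[, 1L] < tol | xy[, 1L] > 1 - tol |
        xy[, 2L] < tol | xy[, 2L] > 1 - tol)
}

#' Per-element shape-function gradients
#'
#' Constant gradients of the three linear (P1) shape functions on every
#' element, plus element areas. Used by the forward solver, the strain
#' recovery, and the adjoint baseline.
#'
#' @param mesh An `elastinv_mesh`.
#' @return List with `dNx`, `dNy` (`n_elements` x 3 matrices: the x- and
#'   y-derivative of shape function a on each element) and `area`.
#' @keywords internal
shape_gradients <- function(mesh) {
  e <- mesh$elements
  x <- matrix(mesh$nodes[e, 1L], ncol = 3L)
  y <- matrix(mesh$nodes[e, 2L], ncol = 3L)
  det <- (x[, 2L] - x[, 1L]) * (y[, 3L] - y[, 1L]) -
         (x[, 3L] - x[, 1L]) * (y[, 2L] - y[, 1L])
  # grad N_a = (y_b - y_c, x_c - x_b) / det  for (a,b,c) cyclic
  dNx <- cbind(y[, 2L] - y[, 3L], y[, 3L] - y[, 1L], y[, 1L] - y[, 2L]) / det
  dNy <- cbind(x[, 3L] - x[, 2L], x[, 1L] - x[, 3L], x[, 2L] - x[, 1L]) / det
  list(dNx = dNx, dNy = dNy, area = 0.5 * det)
}

#' Export a mesh (and optional fields) to VTU
#'
#' Writes an XML VTK unstructured-grid file (ASCII) for visualization in
#' ParaView or similar tools.
#'
#' @param mesh An `elastinv_mesh`.
#' @param file Output path.
#' @param point_data Named list of per-node numeric vectors (optional).
#' @param cell_data Named list of per-element numeric vectors (optional).
#' @return `file`, invisibly.
#' @export
write_vtu <- function(mesh, file, point_data = list(), cell_data = list()) {
  np <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', np, ne)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(mesh$nodes[, 1L], mesh$nodes[, 2L], 0), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(mesh$elements[, 1L] - 1L, mesh$elements[, 2L] - 1L,
                   mesh$elements[, 3L] - 1L), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(ne) * 3L), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("5", ne), con)
  w('        </DataArray>')
  w('      </Cells>')
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(as.character(point_data[[nm]]), con)
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  if (length(cell_data)) {
    w('      <CellData>')
    for (nm in names(cell_data)) {
      w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(as.character(cell_data[[nm]]), con)
      w('        </DataArray>')
    }
    w('      </CellData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(file)
}

#' Export a mesh as plain-text node/element listings
#'
#' Writes `<stem>.nodes.txt` (`id x y`, one row per node) and
#' `<stem>.elements.txt` (`id v1 v2 v3`, 1-based vertex indices).
#'
#' @param mesh An `elastinv_mesh`.
#' @param stem Output path stem.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_mesh_text <- function(mesh, stem) {
  nf <- paste0(stem, ".nodes.txt")
  ef <- paste0(stem, ".elements.txt")
  utils::write.table(
    data.frame(id = seq_len(nrow(mesh$nodes)), x = mesh$nodes[, 1L],
               y = mesh$nodes[, 2L]),
    nf, row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(id = seq_len(nrow(mesh$elements)), v1 = mesh$elements[, 1L],
               v2 = mesh$elements[, 2L], v3 = mesh$elements[, 3L]),
    ef, row.names = FALSE, quote = FALSE)
  invisible(c(nf, ef))
}
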