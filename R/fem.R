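#' Assemble the finite-element mass matrix
#'
#' \eqn{M_{jk} = \int_\Omega \phi_j \phi_k \, ds} for the piecewise linear
#' hat basis. The local block on a triangle of area \eqn{A} is
#' \eqn{(A/12)\,[2\,1\,1; 1\,2\,1; 1\,1\,2]}. M is symmetric positive
#' definite and its entries sum to the mesh area (partition of unity).
#'
#' @param mesh a `tri_mesh`.
#' @return sparse symmetric K x K matrix.
#' @export
assemble_mass <- function(mesh) {
  tri <- mesh$triangles
  area2 <- .signed_area2(mesh$nodes, tri)
  if (any(area2 <= 0)) stop("degenerate (non-positive area) triangle in mesh")
  area <- area2 / 2
  loc <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3, 3) / 12
  idx <- expand.grid(a = 1:3, b = 1:3)
  ii <- as.vector(tri[, idx$a])
  jj <- as.vector(tri[, idx$b])
  xx <- as.vector(outer(area, loc[cbind(idx$a, idx$b)]))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = rep(nrow(mesh$nodes), 2))
  Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
}

#' Assemble the finite-element stiffness matrix
#'
#' \eqn{A_{jk} = \int_\Omega \nabla\phi_j \cdot \nabla\phi_k \, ds}. On each
#' triangle the hat-function gradients are constant, so the local block is
#' the Gram matrix of the (scaled) edge normals times the triangle area.
#' A is symmetric positive semidefinite and annihilates constants
#' (\eqn{A\,1 = 0}).
#'
#' @param mesh a `tri_mesh`.
#' @return sparse symmetric K x K matrix.
#' @export
assemble_stiffness <- function(mesh) {
  tri <- mesh$triangles
  nodes <- mesh$nodes
  area2 <- .signed_area2(nodes, tri)
  if (any(area2 <= 0)) stop("degenerate (non-positive area) triangle in mesh")
  area <- area2 / 2
  # gradient of hat at vertex v: rot90 of opposite edge / (2A)
  gx <- gy <- matrix(0, nrow(tri), 3)
  for (v in 1:3) {
    o1 <- tri[, v %% 3 + 1]; o2 <- tri[, (v + 1) %% 3 + 1]
    gx[, v] <- (nodes[o1, 2] - nodes[o2, 2]) / area2
    gy[, v] <- (nodes[o2, 1] - nodes[o1, 1]) / area2
  }
  idx <- expand.grid(a = 1:3, b = 1:3)
  ii <- as.vector(tri[, idx$a])
  jj <- as.vector(tri[, idx$b])
  xx <- as.vector(vapply(seq_len(nrow(idx)), function(k) {
    a <- idx$a[k]; b <- idx$b[k]
    area * (gx[, a] * gx[, b] + gy[, a] * gy[, b])
  }, numeric(nrow(tri))))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = rep(nrow(nodes), 2))
  Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
}

#' Assemble the Laplacian curvature penalty matrix
#'
#' Discretizes the thin-plate-style roughness penalty
#' \eqn{\int_\Omega (\Delta f)^2 ds} for linear elements by the mixed
#' (auxiliary-variable) formulation \eqn{P = A M^{-1} A}, where M is the
#' mass matrix and A the stiffness matrix. Computed via a sparse Cholesky
#' solve of M (never an explicit inverse). With `lumped = TRUE` the
#' diagonal (row-sum lumped) mass matrix is used instead, which keeps P
#' sparse at a small accuracy cost.
#'
#' @param mass mass matrix (SPD).
#' @param stiffness stiffness matrix (symmetric PSD), same dimension.
#' @param lumped use the lumped (diagonal) mass matrix.
#' @return symmetric PSD K x K penalty matrix with \eqn{P\,1 = 0}.
#' @export
assemble_penalty <- function(mass, stiffness, lumped = FALSE) {
  if (!all(dim(mass) == dim(stiffness))) stop("non-conforming dimensions")
  if (lumped) {
    m <- Matrix::rowSums(mass)
    if (any(m <= 0)) stop("singular lumped mass matrix")
    P <- stiffness %*% (stiffness / m)
  } else {
    X <- tryCatch(Matrix::solve(mass, stiffness),
                  error = function(e) stop("singular mass matrix: ",
                                           conditionMessage(e)))
    P <- stiffness %*% X
  }
  P <- (P + Matrix::t(P)) / 2
  Matrix::forceSymmetric(P)
}

#' Build the full basis system for a spot set
#'
#' Convenience constructor: Delaunay mesh with nodes at the spots, then the
#' mass, stiffness, and curvature-penalty matrices. The basis count K
#' equals the number of spots, and the basis evaluated at the spots is the
#' identity, so the zero-smoothing limit interpolates the data.
#'
#' @param spots a [spot_set()] (or coordinate matrix).
#' @param lumped passed to [assemble_penalty()].
#' @return object of class `basis_system` with elements `mesh`, `K`,
#'   `mass`, `stiffness`, `penalty`.
#' @export
basis_system <- function(spots, lumped = FALSE) {
  mesh <- if (inherits(spots, "tri_mesh")) spots else build_mesh(spots)
  M <- assemble_mass(mesh)
  A <- assemble_stiffness(mesh)
  P <- assemble_penalty(M, A, lumped = lumped)
  structure(list(mesh = mesh, K = nrow(mesh$nodes),
                 mass = M, stiffness = A, penalty = P),
            class = "basis_system")
}

#' @export
print.basis_system <- function(x, ...) {
  cat("basis_system: K =", x$K, "piecewise linear bases on",
      nrow(x$mesh$triangles), "triangles\n")
  invisible(x)
}
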