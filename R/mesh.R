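#' Construct a set of spatial spots
#'
#' Bundles 2D spot coordinates with unique spot identifiers. Spots are the
#' measurement units of spatial transcriptomics platforms; each spot
#' \eqn{s_j = (s_{j1}, s_{j2})^T} carries an expression vector across genes.
#'
#' @param coords numeric matrix or data frame with n rows and 2 columns
#'   (x, y), in the platform's spatial units.
#' @param spot_ids character vector of unique identifiers, one per row.
#'   Defaults to `"spot_1" ... "spot_n"`.
#' @param dedup_tol coordinates are considered duplicated when equal after
#'   rounding to this resolution (platform coordinates are discrete).
#' @return an object of class `spot_set` with elements `coords` (n x 2
#'   matrix with columns `x`, `y`) and `spot_ids`.
#' @export
spot_set <- function(coords, spot_ids = NULL, dedup_tol = 1e-9) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have exactly 2 columns (x, y)")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  n <- nrow(coords)
  if (n < 3L) stop("at least 3 spots are required")
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(n))
  spot_ids <- as.character(spot_ids)
  if (length(spot_ids) != n) stop("spot_ids length must match number of rows")
  if (anyDuplicated(spot_ids)) {
    stop("duplicate spot_ids: ",
         paste(utils::head(unique(spot_ids[duplicated(spot_ids)]), 5L),
               collapse = ", "))
  }
  key <- paste(round(coords[, 1] / dedup_tol), round(coords[, 2] / dedup_tol))
  if (anyDuplicated(key)) {
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    stop("duplicate coordinates for spots: ",
         paste(utils::head(spot_ids[dup], 10L), collapse = ", "))
  }
  colnames(coords) <- c("x", "y")
  rownames(coords) <- spot_ids
  structure(list(coords = coords, spot_ids = spot_ids), class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat("spot_set:", nrow(x$coords), "spots; bounding box [",
      format(min(x$coords[, 1])), ",", format(max(x$coords[, 1])), "] x [",
      format(min(x$coords[, 2])), ",", format(max(x$coords[, 2])), "]\n")
  invisible(x)
}

# circumcenter and squared circumradius of triangles given by index rows
# of `tri` into `pts`; returns list(cx, cy, r2, degenerate)
.circumcircles <- function(pts, tri) {
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  list(cx = ux, cy = uy, r2 = r2, degenerate = !is.finite(ux) | !is.finite(uy))
}

# twice the signed area of triangles (positive = counterclockwise)
.signed_area2 <- function(pts, tri) {
  (pts[tri[, 2], 1] - pts[tri[, 1], 1]) * (pts[tri[, 3], 2] - pts[tri[, 1], 2]) -
  (pts[tri[, 3], 1] - pts[tri[, 1], 1]) * (pts[tri[, 2], 2] - pts[tri[, 1], 2])
}

#' Delaunay triangulation of a spot set
#'
#' Triangulates the convex hull of the spots with mesh nodes placed exactly
#' at the spot coordinates (in input order), via the incremental
#' Bowyer-Watson algorithm. A strict in-circle test is used, so exactly
#' cocircular configurations (e.g. regular lattices) resolve to one of the
#' valid tie-break triangulations deterministically.
#'
#' @param spots a [spot_set()].
#' @return object of class `tri_mesh` with `nodes` (V x 2, V = n, rows equal
#'   to the spot coordinates), `triangles` (T x 3 integer, counterclockwise),
#'   and `boundary_edges` (B x 2 integer; edges on the convex hull).
#' @export
build_mesh <- function(spots) {
  if (!inherits(spots, "spot_set")) spots <- spot_set(spots)
  pts <- spots$coords
  n <- nrow(pts)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))$d
  if (sv[2] <= 1e-12 * max(sv[1], 1)) {
    stop("all spots are collinear; a 2D triangulation is not possible")
  }
  # super-triangle well outside the data
  rng <- apply(pts, 2, range)
  diam <- max(rng[2, ] - rng[1, ], 1e-12)
  m <- 100 * diam
  super <- rbind(c(ctr[1] - 2 * m, ctr[2] - m),
                 c(ctr[1] + 2 * m, ctr[2] - m),
                 c(ctr[1],         ctr[2] + 2 * m))
  allp <- rbind(super, pts)
  tri <- matrix(c(1L, 2L, 3L), nrow = 1)
  cc <- .circumcircles(allp, tri)
  ccm <- cbind(cc$cx, cc$cy, cc$r2)
  for (ip in seq_len(n)) {
    p <- allp[ip + 3L, ]
    d2 <- (p[1] - ccm[, 1])^2 + (p[2] - ccm[, 2])^2
    bad <- which(d2 < ccm[, 3] * (1 - 1e-7))   # strict: cocircular excluded
    if (length(bad) == 0L) {
      # numerically on the circle of every candidate; take nearest triangle
      bad <- which.min(d2 / pmax(ccm[, 3], 1e-300))
    }
    # cavity boundary: edges of bad triangles occurring exactly once
    bt <- tri[bad, , drop = FALSE]
    e <- rbind(bt[, c(1, 2), drop = FALSE],
               bt[, c(2, 3), drop = FALSE],
               bt[, c(3, 1), drop = FALSE])
    ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    keep <- !(ek %in% ek[duplicated(ek)])
    be <- e[keep, , drop = FALSE]
    newt <- cbind(be, ip + 3L)
    # enforce positive orientation of the new triangles
    s2 <- .signed_area2(allp, newt)
    flip <- s2 < 0
    if (any(flip)) newt[flip, 1:2] <- newt[flip, 2:1]
    tri <- rbind(tri[-bad, , drop = FALSE], newt)
    ncc <- .circumcircles(allp, newt)
    ccm <- rbind(ccm[-bad, , drop = FALSE], cbind(ncc$cx, ncc$cy, ncc$r2))
  }
  real <- rowSums(tri <= 3L) == 0L
  tri <- tri[real, , drop = FALSE] - 3L
  if (nrow(tri) == 0L) stop("triangulation failed: no interior triangles")
  # drop degenerate slivers, orient counterclockwise, canonical ordering
  s2 <- .signed_area2(pts, tri)
  tri <- tri[abs(s2) > 1e-12 * diam^2, , drop = FALSE]
  s2 <- .signed_area2(pts, tri)
  flip <- s2 < 0
  if (any(flip)) tri[flip, 2:3] <- tri[flip, 3:2]
  rot <- apply(tri, 1, which.min)
  tri <- t(vapply(seq_len(nrow(tri)), function(i) {
    v <- tri[i, ]
    if (rot[i] == 2L) v <- v[c(2, 3, 1)] else if (rot[i] == 3L) v <- v[c(3, 1, 2)]
    v
  }, integer(3)))
  tri <- tri[order(tri[, 1], tri[, 2], tri[, 3]), , drop = FALSE]
  storage.mode(tri) <- "integer"
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  bnd <- e[!(ek %in% ek[duplicated(ek)]), , drop = FALSE]
  bnd <- bnd[order(bnd[, 1], bnd[, 2]), , drop = FALSE]
  storage.mode(bnd) <- "integer"
  structure(list(nodes = pts, triangles = tri, boundary_edges = bnd,
                 spot_ids = spots$spot_ids),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("tri_mesh:", nrow(x$nodes), "nodes,", nrow(x$triangles), "triangles,",
      nrow(x$boundary_edges), "boundary edges\n")
  invisible(x)
}

#' Evaluate the piecewise linear basis at arbitrary points
#'
#' Each mesh node carries one hat function: 1 at the node, 0 at all other
#' nodes, linear on each triangle. The returned row for a point holds the
#' barycentric weights of its containing triangle, so rows are nonnegative
#' and sum to one, and evaluation at node j yields the unit indicator row.
#'
#' @param mesh a [build_mesh()] result (or a `basis_system`).
#' @param points m x 2 numeric matrix of evaluation locations.
#' @param tol points outside the hull by more than this (in barycentric
#'   units) raise an error; closer points are snapped onto the hull.
#' @return sparse m x K matrix (`Matrix::dgCMatrix`), K = number of nodes.
#' @export
evaluate_basis <- function(mesh, points, tol = 1e-8) {
  if (inherits(mesh, "basis_system")) mesh <- mesh$mesh
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must have 2 columns")
  nodes <- mesh$nodes; tri <- mesh$triangles
  m <- nrow(points); K <- nrow(nodes)
  assigned <- rep(FALSE, m)
  ii <- jj <- integer(0); xx <- numeric(0)
  bary_tol <- tol
  for (t in seq_len(nrow(tri))) {
    if (all(assigned)) break
    v <- tri[t, ]
    a <- nodes[v[1], ]; b <- nodes[v[2], ]; c <- nodes[v[3], ]
    det <- (b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])
    idx <- which(!assigned)
    px <- points[idx, 1] - a[1]; py <- points[idx, 2] - a[2]
    w2 <- (px * (c[2] - a[2]) - py * (c[1] - a[1])) / det
    w3 <- (py * (b[1] - a[1]) - px * (b[2] - a[2])) / det
    w1 <- 1 - w2 - w3
    inside <- w1 >= -bary_tol & w2 >= -bary_tol & w3 >= -bary_tol
    if (!any(inside)) next
    hit <- idx[inside]
    w <- cbind(w1[inside], w2[inside], w3[inside])
    w[w < 0] <- 0
    w <- w / rowSums(w)
    ii <- c(ii, rep(hit, 3L))
    jj <- c(jj, rep(v, each = length(hit)))
    xx <- c(xx, as.vector(w))
    assigned[hit] <- TRUE
  }
  if (!all(assigned)) {
    stop("points outside the mesh beyond tolerance: indices ",
         paste(utils::head(which(!assigned), 10L), collapse = ", "))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, K))
}

#' Export a mesh as an OFF-style text file
#'
#' Writes a plain-text dump (`OFF`, node count / triangle count, node
#' coordinates, then triangles as `3 i j k` with 0-based indices) for
#' inspection in standard mesh viewers.
#'
#' @param mesh a `tri_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(mesh$nodes), nrow(mesh$triangles), 0), con)
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], 0), con)
  writeLines(paste(3, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
  invisible(path)
}
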