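#' Linear finite-element Laplace-Beltrami matrices
#'
#' Assembles the cotangent-weighted stiffness matrix and the consistent
#' linear-FEM mass matrix of a triangle mesh. Stiffness rows sum to zero
#' (constants are in the null space); mass entries sum to the total surface
#' area (partition of unity). Both are returned as sparse symmetric
#' matrices.
#'
#' @param mesh A `laminar_mesh`, connected and free of degenerate triangles.
#' @param lumped If `TRUE`, return the diagonally lumped mass matrix
#'   (barycentric vertex areas) instead of the consistent one.
#' @return List with `stiffness` and `mass` (`Matrix::dsCMatrix`).
#' @export
build_fem_matrices <- function(mesh, lumped = FALSE) {
  v <- mesh$vertices
  tr <- mesh$triangles
  areas <- triangle_areas(mesh)
  if (any(areas <= .Machine$double.eps)) {
    stop_geometry(sprintf("degenerate triangle(s) with zero area: %s",
                          paste(which(areas <= .Machine$double.eps)[1:3], collapse = ", ")))
  }
  n <- nrow(v)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  # Cotangent at the vertex opposite each edge; one pass per corner.
  for (c0 in 1:3) {
    a <- tr[, c0]
    b <- tr[, (c0 %% 3) + 1L]
    cc <- tr[, ((c0 + 1L) %% 3) + 1L]
    e1 <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    e2 <- v[cc, , drop = FALSE] - v[a, , drop = FALSE]
    dot <- rowSums(e1 * e2)
    cotan <- dot / (2 * areas)          # |e1 x e2| = 2 * area
    if (any(!is.finite(cotan))) stop_geometry("cotangent overflow on a degenerate triangle")
    w <- cotan / 2
    ii <- c(ii, b, cc, b, cc)
    jj <- c(jj, cc, b, b, cc)
    xx <- c(xx, -w, -w, w, w)
  }
  stiffness <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  stiffness <- Matrix::forceSymmetric((stiffness + Matrix::t(stiffness)) / 2)
  if (lumped) {
    mass <- Matrix::Diagonal(n, x = vertex_areas(mesh))
  } else {
    mi <- c(tr[, 1], tr[, 2], tr[, 3], tr[, 1], tr[, 2], tr[, 1], tr[, 3],
            tr[, 2], tr[, 3])
    mj <- c(tr[, 1], tr[, 2], tr[, 3], tr[, 2], tr[, 1], tr[, 3], tr[, 1],
            tr[, 3], tr[, 2])
    mx <- c(rep(areas / 6, 3), rep(areas / 12, 6))
    mass <- Matrix::forceSymmetric(
      Matrix::sparseMatrix(i = mi, j = mj, x = mx, dims = c(n, n)))
  }
  list(stiffness = stiffness, mass = mass)
}

#' Geometric eigenmodes of a cortical mesh
#'
#' Solves the generalized symmetric eigenproblem `K v = lambda M v` for the
#' linear-FEM Laplace-Beltrami operator and returns the `k` smallest
#' eigenpairs, sorted ascending and mass-orthonormalized
#' (`t(V) %*% M %*% V = I`). Mode 1 is spatially constant with eigenvalue
#' ~0; modes 2+ order spatial patterns from coarse to fine. The problem is
#' reduced to standard form through a Cholesky factor of the mass matrix and
#' solved densely with LAPACK, which is exact and fast at the mesh sizes
#' used here (a few thousand vertices).
#'
#' Each eigenvector's sign is fixed by requiring the loading of largest
#' absolute value to be positive (ties broken by lowest vertex index), so
#' repeated runs return identical loadings.
#'
#' @param mesh A `laminar_mesh`.
#' @param k Number of modes (>= 4, much smaller than the vertex count).
#' @param lumped Use the lumped mass matrix (default consistent).
#' @return An object of class `laminar_modes`: `evals` (length k,
#'   ascending), `modes` (`N x k`), `k`, `lumped`.
#' @export
compute_eigenmodes <- function(mesh, k = 10L, lumped = FALSE) {
  k <- as.integer(k)
  n <- nrow(mesh$vertices)
  if (k < 4L) stop_contract("`k` must be at least 4")
  if (k >= n) stop_contract("`k` must be much smaller than the vertex count")
  fem <- build_fem_matrices(mesh, lumped = lumped)
  K <- as.matrix(fem$stiffness)
  M <- as.matrix(fem$mass)
  R <- tryCatch(chol(M), error = function(e) {
    stop_geometry("mass matrix is not positive definite; mesh may be degenerate")
  })
  # A = R^-T K R^-1 via two triangular solves.
  A <- backsolve(R, t(backsolve(R, t(K), transpose = TRUE)), transpose = TRUE)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  sel <- seq(n, n - k + 1L)            # eigen() returns descending order
  evals <- pmax(e$values[sel], 0)
  modes <- backsolve(R, e$vectors[, sel, drop = FALSE])
  for (j in seq_len(k)) {
    i_max <- which.max(abs(modes[, j]))
    if (modes[i_max, j] < 0) modes[, j] <- -modes[, j]
  }
  structure(list(evals = evals, modes = modes, k = k, lumped = lumped,
                 n_vertices = n),
            class = "laminar_modes")
}

#' @export
print.laminar_modes <- function(x, ...) {
  cat(sprintf("<laminar_modes> %d modes on %d vertices; eigenvalues %.3g .. %.3g\n",
              x$k, x$n_vertices, x$evals[1], x$evals[x$k]))
  invisible(x)
}

#' Broadcast a parcel effect map to vertices
#'
#' Every vertex receives its parcel's statistic; vertices of excluded (or
#' otherwise absent) parcels are `NA`.
#'
#' @param effects Effect-map tibble with `parcel_id` and a statistic column.
#' @param labels Per-vertex parcel ids.
#' @param column Statistic column to broadcast (default `"statistic"`).
#' @return Numeric per-vertex vector with `NA` at missing parcels.
#' @export
upsample_parcel_map <- function(effects, labels, column = "statistic") {
  if (anyNA(labels)) stop_contract("unlabeled vertices present")
  idx <- match(as.character(labels), as.character(effects$parcel_id))
  effects[[column]][idx]
}
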