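#' Construct a triangle surface mesh
#'
#' A mesh is a list with an `N x 3` numeric vertex matrix (world mm) and an
#' `M x 3` integer triangle matrix holding 1-based vertex indices. Matched
#' pial/white meshes (see [cortical_ribbon()]) share vertex indexing.
#'
#' @param vertices Numeric matrix, `N x 3`, vertex coordinates in mm.
#' @param triangles Integer matrix, `M x 3`, 1-based vertex indices.
#' @return An object of class `laminar_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3L)
  if (ncol(vertices) != 3L) stop_contract("`vertices` must have 3 columns")
  if (any(triangles < 1L) || any(triangles > nrow(vertices))) {
    stop_contract("triangle indices must lie in [1, N]")
  }
  storage.mode(vertices) <- "double"
  structure(list(vertices = vertices, triangles = triangles),
            class = "laminar_mesh")
}

#' @export
print.laminar_mesh <- function(x, ...) {
  cat(sprintf("<laminar_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Pair matched pial and white meshes into a cortical ribbon
#'
#' Vertex correspondence is implicit: vertex `i` of the pial mesh matches
#' vertex `i` of the white mesh, and both meshes must share one triangle list.
#'
#' @param pial,white `laminar_mesh` objects with identical topology.
#' @return An object of class `laminar_ribbon` with elements `pial`, `white`.
#' @export
cortical_ribbon <- function(pial, white) {
  if (!inherits(pial, "laminar_mesh") || !inherits(white, "laminar_mesh")) {
    stop_contract("`pial` and `white` must be laminar_mesh objects")
  }
  if (nrow(pial$vertices) != nrow(white$vertices)) {
    stop_contract("pial and white meshes have different vertex counts")
  }
  if (!identical(pial$triangles, white$triangles)) {
    stop_contract("pial and white meshes have different triangle lists")
  }
  structure(list(pial = pial, white = white), class = "laminar_ribbon")
}

#' @export
print.laminar_ribbon <- function(x, ...) {
  cat(sprintf("<laminar_ribbon> %d matched vertices, %d triangles\n",
              nrow(x$pial$vertices), nrow(x$pial$triangles)))
  invisible(x)
}

# Per-triangle areas via the cross product; degenerate triangles are allowed
# here and caught by consumers that cannot tolerate them.
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  e1 <- v[tr[, 2L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  e2 <- v[tr[, 3L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Barycentric vertex areas
#'
#' Each vertex receives one third of the area of every incident triangle, so
#' vertex areas sum exactly to the total surface area. This is the standard
#' lumped-area surrogate for local surface expansion used by the
#' equivolumetric construction.
#'
#' @param mesh A `laminar_mesh`.
#' @return Numeric vector of per-vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  ta <- triangle_areas(mesh)
  n <- nrow(mesh$vertices)
  acc <- rep(0, n)
  for (j in 1:3) {
    contrib <- rowsum(ta, group = mesh$triangles[, j], reorder = FALSE)
    idx <- as.integer(rownames(contrib))
    acc[idx] <- acc[idx] + contrib[, 1L]
  }
  if (any(acc == 0)) {
    stop_contract(sprintf("mesh has %d isolated vertices with no incident triangle",
                          sum(acc == 0)))
  }
  acc / 3
}

# Signed enclosed volume of a closed mesh (divergence theorem).
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 1L], , drop = FALSE]
  b <- v[tr[, 2L], , drop = FALSE]
  c_ <- v[tr[, 3L], , drop = FALSE]
  det <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
         a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
         a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  sum(det) / 6
}

#' Geodesic icosphere
#'
#' Repeated 4-to-1 subdivision of a regular icosahedron projected to the unit
#' sphere, giving `10 * 4^subdivision + 2` vertices with outward-winding
#' triangles. The unit icosphere doubles as the spherical projection of every
#' phantom surface derived from it.
#'
#' @param subdivision Non-negative integer subdivision level.
#' @param radius Sphere radius (default 1).
#' @return A `laminar_mesh`.
#' @export
icosphere <- function(subdivision = 4L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  verts <- verts / sqrt(rowSums(verts^2))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivision)) {
    nv <- nrow(verts)
    ea <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
    key <- pmin(ea[, 1], ea[, 2]) * (nv + 1) + pmax(ea[, 1], ea[, 2])
    uk <- unique(key)
    mid_id <- match(key, uk) + nv
    first <- match(uk, key)
    mids <- (verts[ea[first, 1], , drop = FALSE] +
             verts[ea[first, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    verts <- rbind(verts, mids)
    nf <- nrow(faces)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2 * nf + seq_len(nf)]
    faces <- rbind(
      cbind(faces[, 1], m12, m31),
      cbind(faces[, 2], m23, m12),
      cbind(faces[, 3], m31, m23),
      cbind(m12, m23, m31))
  }
  surface_mesh(verts * radius, faces)
}
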