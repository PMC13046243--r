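#' Equivolumetric distance fraction
#'
#' Converts a local volume fraction `alpha` into the fractional Euclidean
#' distance `rho` between two boundary surfaces whose local areas are
#' `area_in` (the side the fraction is measured from) and `area_out`,
#' assuming the local area varies linearly with distance across the ribbon.
#' Solving `V(rho) = alpha * V(1)` for `A(rho) = A_in + rho (A_out - A_in)`
#' gives
#' \deqn{\rho = \frac{-A_{in} + \sqrt{\alpha A_{out}^2 + (1-\alpha) A_{in}^2}}
#'                   {A_{out} - A_{in}}}
#' with the flat-sheet limit `rho = alpha` when the two areas coincide. This
#' is the curvature compensation that keeps the volume between consecutive
#' intracortical surfaces constant in gyri and sulci alike.
#'
#' @param alpha Volume fraction(s) in \[0, 1\], measured from the `area_in` side.
#' @param area_in,area_out Positive local areas (mm^2) of the two boundaries.
#'   All three arguments are recycled to a common length.
#' @return Distance fraction(s) `rho` in \[0, 1\] from the `area_in` side.
#' @export
equivolume_fraction <- function(alpha, area_in, area_out) {
  n <- max(length(alpha), length(area_in), length(area_out))
  alpha <- rep_len(alpha, n)
  a_in <- rep_len(area_in, n)
  a_out <- rep_len(area_out, n)
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1)) {
    stop_domain("`alpha` must lie in [0, 1]")
  }
  if (any(a_in <= 0) || any(a_out <= 0)) {
    stop_domain("boundary areas must be strictly positive")
  }
  rho <- numeric(n)
  # Near-equal areas: the closed form cancels catastrophically; use the
  # exact flat-sheet limit instead.
  flat <- abs(a_out - a_in) < 1e-9 * pmax(a_in, a_out)
  rho[flat] <- alpha[flat]
  if (any(!flat)) {
    ai <- a_in[!flat]; ao <- a_out[!flat]; al <- alpha[!flat]
    rho[!flat] <- (-ai + sqrt(al * ao^2 + (1 - al) * ai^2)) / (ao - ai)
  }
  pmin(pmax(rho, 0), 1)
}

#' Build equivolumetric intracortical depth surfaces
#'
#' Places `n_depths` surfaces between the pial and white boundaries of a
#' ribbon so that each pair of consecutive surfaces encloses an equal
#' fraction of the local cortical volume. Local curvature is summarized by
#' the pial/white vertex-area ratio: for each vertex, the distance fraction
#' is [equivolume_fraction()] with `area_in` the white-side vertex area and
#' `area_out` the pial-side vertex area, and the vertex is placed at
#' `white + rho * (pial - white)`.
#'
#' Depth index 1 is the pial surface and index `n_depths` the white surface
#' (so a larger profile center of gravity means signal balance toward deeper
#' cortex). The default volume-fraction grid spans \[0, 1\] inclusive of both
#' boundaries; `offset` shrinks it to an interior grid
#' `[offset, 1 - offset]` for users who want to avoid boundary partial
#' voluming.
#'
#' @param ribbon A `laminar_ribbon`.
#' @param n_depths Number of depth surfaces (default 12).
#' @param offset Boundary offset fraction in \[0, 0.5), default 0.
#' @return A `laminar_depth_stack`: list with `coords` (`N x 3 x n_depths`
#'   array, ordered pial to white), `alpha` (volume fraction from the pial
#'   side per depth), `triangles`, and `n_depths`.
#' @export
build_depth_surfaces <- function(ribbon, n_depths = 12L, offset = 0) {
  if (!inherits(ribbon, "laminar_ribbon")) {
    stop_contract("`ribbon` must be a laminar_ribbon")
  }
  n_depths <- as.integer(n_depths)
  if (n_depths < 2L) stop_contract("`n_depths` must be at least 2")
  if (offset < 0 || offset >= 0.5) stop_contract("`offset` must lie in [0, 0.5)")
  a_pial <- vertex_areas(ribbon$pial)
  a_white <- vertex_areas(ribbon$white)
  alpha <- seq(offset, 1 - offset, length.out = n_depths)  # from pial side
  n <- nrow(ribbon$pial$vertices)
  coords <- array(NA_real_, dim = c(n, 3L, n_depths))
  pv <- ribbon$pial$vertices
  wv <- ribbon$white$vertices
  for (d in seq_len(n_depths)) {
    # Fraction 1 - alpha measured from the white side, per the closed form.
    rho <- equivolume_fraction(1 - alpha[d], a_white, a_pial)
    coords[, , d] <- wv + rho * (pv - wv)
  }
  structure(
    list(coords = coords, alpha = alpha, triangles = ribbon$pial$triangles,
         n_depths = n_depths),
    class = "laminar_depth_stack")
}

#' @export
print.laminar_depth_stack <- function(x, ...) {
  cat(sprintf("<laminar_depth_stack> %d vertices x %d depths (1 = pial, %d = white)\n",
              dim(x$coords)[1L], x$n_depths, x$n_depths))
  invisible(x)
}

#' Extract one depth surface from a stack as a mesh
#'
#' @param stack A `laminar_depth_stack`.
#' @param depth Depth index (1 = pial).
#' @return A `laminar_mesh`.
#' @export
depth_surface <- function(stack, depth) {
  if (depth < 1L || depth > stack$n_depths) stop_contract("depth index out of range")
  surface_mesh(stack$coords[, , depth], stack$triangles)
}
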