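#' Construct an intensity volume
#'
#' A 3D numeric array together with a 4x4 affine mapping 0-based voxel
#' indices (voxel centers at integer coordinates) to world mm, the dominant
#' neuroimaging convention.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 numeric voxel-to-world transform.
#' @return An object of class `laminar_volume`.
#' @export
laminar_volume <- function(data, affine) {
  if (length(dim(data)) != 3L) stop_contract("`data` must be a 3D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop_contract("`affine` must be 4x4")
  det_a <- det(affine[1:3, 1:3])
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps) {
    stop_format("volume affine is singular")
  }
  structure(list(data = data, affine = affine), class = "laminar_volume")
}

#' @export
print.laminar_volume <- function(x, ...) {
  cat(sprintf("<laminar_volume> %s voxels\n", paste(dim(x$data), collapse = " x ")))
  invisible(x)
}

#' Trilinear interpolation of a volume at world coordinates
#'
#' Each point is mapped to continuous 0-based voxel coordinates through the
#' inverse affine and interpolated as the weighted average of its eight
#' neighboring voxels. Points outside the valid interpolation domain (the
#' box spanned by the outermost voxel centers) are flagged invalid and
#' returned as `NA`, never extrapolated or clamped.
#'
#' @param volume A `laminar_volume`.
#' @param points Numeric `K x 3` matrix of world-mm coordinates.
#' @return A list with `values` (length-K numeric, `NA` where invalid) and
#'   `valid` (logical length K).
#' @export
trilinear_sample <- function(volume, points) {
  if (!inherits(volume, "laminar_volume")) stop_contract("`volume` must be a laminar_volume")
  points <- matrix(as.numeric(points), ncol = 3L)
  if (any(!is.finite(points))) stop_contract("sampling points must be finite")
  dm <- dim(volume$data)
  inv <- solve(volume$affine)
  vox <- cbind(points, 1) %*% t(inv)            # continuous 0-based indices
  cc <- vox[, 1:3, drop = FALSE]
  dm_hi <- matrix(dm - 1, nrow(cc), 3L, byrow = TRUE)
  # points within rounding error of the boundary faces count as inside
  tol <- 1e-9
  valid <- rowSums(cc >= -tol & cc <= dm_hi + tol) == 3L
  cc <- pmin(pmax(cc, 0), dm_hi)
  i0 <- floor(cc)
  fr <- cc - i0
  # Points landing exactly on the far voxel-center face belong to the last
  # interior cell with fraction 1 (no extrapolation involved).
  on_edge <- i0 >= dm_hi
  i0[on_edge] <- i0[on_edge] - 1
  fr[on_edge] <- fr[on_edge] + 1
  i0 <- pmax(i0, 0)  # guard only for invalid rows; they are masked anyway
  i0[i0 > dm_hi - 1] <- 0
  values <- rep(NA_real_, nrow(points))
  if (any(valid)) {
    ii <- i0[valid, , drop = FALSE]
    ff <- fr[valid, , drop = FALSE]
    lin <- function(dx, dy, dz) {
      1L + (ii[, 1] + dx) + dm[1] * ((ii[, 2] + dy) + dm[2] * (ii[, 3] + dz))
    }
    v <- volume$data
    wx0 <- 1 - ff[, 1]; wy0 <- 1 - ff[, 2]; wz0 <- 1 - ff[, 3]
    values[valid] <-
      v[lin(0, 0, 0)] * wx0 * wy0 * wz0 + v[lin(1, 0, 0)] * ff[, 1] * wy0 * wz0 +
      v[lin(0, 1, 0)] * wx0 * ff[, 2] * wz0 + v[lin(0, 0, 1)] * wx0 * wy0 * ff[, 3] +
      v[lin(1, 1, 0)] * ff[, 1] * ff[, 2] * wz0 + v[lin(1, 0, 1)] * ff[, 1] * wy0 * ff[, 3] +
      v[lin(0, 1, 1)] * wx0 * ff[, 2] * ff[, 3] + v[lin(1, 1, 1)] * ff[, 1] * ff[, 2] * ff[, 3]
  }
  valid <- valid & is.finite(values)
  values[!valid] <- NA_real_
  list(values = values, valid = valid)
}

#' Sample depth profiles at every vertex of a depth-surface stack
#'
#' Row `v`, column `d` of the result is the trilinear sample of the volume at
#' vertex `v` of depth surface `d` (1 = pial). A vertex is masked out if any
#' of its depth samples falls outside the volume.
#'
#' @param volume A `laminar_volume`.
#' @param stack A `laminar_depth_stack` in the same world space.
#' @return A `laminar_profiles` object: `N x n_depths` matrix with attributes
#'   `mask` (logical, masked-in vertices) and `alpha`.
#' @export
sample_profiles <- function(volume, stack) {
  if (!inherits(stack, "laminar_depth_stack")) {
    stop_contract("`stack` must be a laminar_depth_stack")
  }
  n <- dim(stack$coords)[1L]
  d <- stack$n_depths
  pts <- matrix(aperm(stack$coords, c(1L, 3L, 2L)), ncol = 3L)  # (vertex, depth) rows
  s <- trilinear_sample(volume, pts)
  intens <- matrix(s$values, nrow = n, ncol = d)
  mask <- rowSums(matrix(s$valid, nrow = n, ncol = d)) == d
  structure(intens, mask = mask, alpha = stack$alpha,
            class = c("laminar_profiles", "matrix", "array"))
}

#' @export
print.laminar_profiles <- function(x, ...) {
  cat(sprintf("<laminar_profiles> %d vertices x %d depths (%d masked in)\n",
              nrow(x), ncol(x), sum(attr(x, "mask"))))
  invisible(x)
}
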