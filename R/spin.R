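#' Draw a uniform random 3D rotation
#'
#' QR orthonormalization of a standard Gaussian matrix with sign and
#' determinant corrections, which yields a rotation distributed uniformly
#' (Haar) over SO(3). Consumes the current RNG state; seed the session (or
#' use the `seed` arguments of the spin tests) for reproducibility.
#'
#' @return A 3x3 rotation matrix (orthogonal, determinant +1).
#' @export
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qrd)
  # Fix the sign ambiguity of QR so Q is Haar-distributed.
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

#' Spin permutation test of spatial correspondence
#'
#' Tests the Pearson correlation between two vertex-wise maps against a
#' spatial-autocorrelation-preserving null: `map_a`'s vertex positions are
#' rotated on the spherical projection by uniformly random rotations, values
#' are reassigned to each original vertex from its nearest rotated vertex
#' (exact nearest neighbour), and the correlation against the unrotated
#' `map_b` is recomputed. Vertices where either map is missing are dropped
#' pairwise, per permutation; a rotated assignment drawing on a
#' missing-source vertex propagates the missing value. The two-tailed
#' permutation p-value is
#' `(1 + #\{|r_null| >= |r_obs|\}) / (1 + n_perm)`.
#'
#' @param map_a,map_b Numeric per-vertex maps (`NA` = missing); `map_a` is
#'   the rotated map.
#' @param sphere `N x 3` unit-norm spherical projection aligned with the
#'   maps' vertex indexing (e.g. `phantom$sphere`).
#' @param n_perm Number of rotations (default 10000).
#' @param seed Integer seed.
#' @return An object of class `laminar_spin`: `r_obs`, `p_spin`, `null_r`,
#'   `n_perm`, `seed`.
#' @export
spin_correlation_test <- function(map_a, map_b, sphere, n_perm = 10000L, seed = 1L) {
  sphere <- as.matrix(sphere)
  n <- nrow(sphere)
  if (length(map_a) != n || length(map_b) != n) {
    stop_contract("maps and sphere must share vertex indexing")
  }
  norms <- sqrt(rowSums(sphere^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop_contract("sphere coordinates must be unit-norm")
  }
  ok <- !is.na(map_a) & !is.na(map_b)
  if (sum(ok) < 3L) stop_contract("fewer than 3 jointly valid vertices")
  if (stats::sd(map_a[ok]) == 0 || stats::sd(map_b[ok]) == 0) {
    stop_contract("correlation undefined: a map is constant over valid vertices")
  }
  r_obs <- stats::cor(map_a[ok], map_b[ok])
  null_r <- numeric(n_perm)
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      R <- random_rotation()
      rot <- sphere %*% t(R)
      # For each original vertex, the nearest rotated source vertex
      # (max dot product on the unit sphere).
      nn <- max.col(tcrossprod(sphere, rot), ties.method = "first")
      a_perm <- map_a[nn]
      ok_b <- !is.na(a_perm) & !is.na(map_b)
      null_r[b] <- if (sum(ok_b) >= 3L &&
                       stats::sd(a_perm[ok_b]) > 0 && stats::sd(map_b[ok_b]) > 0) {
        stats::cor(a_perm[ok_b], map_b[ok_b])
      } else NA_real_
    }
  })
  exceed <- sum(abs(null_r) >= abs(r_obs), na.rm = TRUE)
  structure(
    list(r_obs = r_obs, p_spin = (1 + exceed) / (1 + n_perm),
         null_r = null_r, n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "laminar_spin")
}

#' @export
print.laminar_spin <- function(x, ...) {
  cat(sprintf("<laminar_spin> r = %.3f, p_spin = %.4g (%d permutations)\n",
              x$r_obs, x$p_spin, x$n_perm))
  invisible(x)
}

#' @export
tidy.laminar_spin <- function(x, ...) {
  tibble::tibble(estimate = x$r_obs, p.value = x$p_spin, n_perm = x$n_perm,
                 seed = x$seed)
}

#' @export
glance.laminar_spin <- function(x, ...) tidy(x)

#' Variance in an effect map explained by eigenmode subsets
#'
#' Regresses a vertex-wise effect map on the loadings of each requested
#' eigenmode subset (plus intercept) over jointly valid vertices and
#' reports R^2. Nested subsets necessarily satisfy monotone R^2.
#'
#' @param effect_map Numeric per-vertex map (`NA` = missing).
#' @param basis A `laminar_modes` object.
#' @param subsets List of integer mode-index vectors (default the
#'   univariate and combined subsets of modes 2-4).
#' @return Tibble with `subset` (label), `modes` (list column), `r.squared`,
#'   `n_vertices`.
#' @export
eigenmode_variance_explained <- function(effect_map, basis,
                                         subsets = list(2L, 3L, 4L, c(2L, 3L),
                                                        c(2L, 4L), c(3L, 4L),
                                                        2:4)) {
  if (!inherits(basis, "laminar_modes")) stop_contract("`basis` must be laminar_modes")
  if (length(effect_map) != basis$n_vertices) {
    stop_contract("effect map and eigenmode basis differ in vertex count")
  }
  ok <- !is.na(effect_map)
  if (sum(ok) < 3L) stop_contract("fewer than 3 valid vertices")
  purrr::map_dfr(subsets, function(s) {
    s <- as.integer(s)
    if (length(s) == 0L) stop_contract("empty mode subset")
    if (any(s < 1L) || any(s > basis$k)) stop_contract("mode index out of range")
    X <- cbind(`(Intercept)` = 1, basis$modes[ok, s, drop = FALSE])
    colnames(X) <- c("(Intercept)", paste0("mode", s))
    fit <- fit_ols(X, effect_map[ok])
    tibble::tibble(subset = paste(s, collapse = "+"), modes = list(s),
                   r.squared = fit$r2, n_vertices = sum(ok))
  })
}
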