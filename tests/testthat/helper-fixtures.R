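# Fixtures built in code; no binary files.

# Regular tetrahedron with unit edge length.
make_tetrahedron <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / (2 * sqrt(2))
  tr <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  surface_mesh(v, tr)
}

# Ribbon of two concentric icospheres (pial outside).
make_sphere_ribbon <- function(r_white = 2, r_pial = 3, subdivision = 3L) {
  base <- icosphere(subdivision)
  cortical_ribbon(
    pial = surface_mesh(base$vertices * r_pial, base$triangles),
    white = surface_mesh(base$vertices * r_white, base$triangles))
}

# Flat n x n unit-spaced sheet at height z, triangulated with a diagonal split.
make_flat_sheet <- function(n = 5L, z = 0) {
  g <- expand.grid(x = seq_len(n) - 1, y = seq_len(n) - 1)
  v <- cbind(g$x, g$y, z)
  id <- function(i, j) (j - 1L) * n + i
  tris <- list()
  for (j in seq_len(n - 1L)) for (i in seq_len(n - 1L)) {
    tris[[length(tris) + 1L]] <- c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
    tris[[length(tris) + 1L]] <- c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
  }
  surface_mesh(v, do.call(rbind, tris))
}

# Identity-affine volume filled by a function of 0-based voxel indices.
make_index_volume <- function(dim3, f, affine = NULL) {
  g <- expand.grid(i = seq_len(dim3[1]) - 1, j = seq_len(dim3[2]) - 1,
                   k = seq_len(dim3[3]) - 1)
  laminar_volume(array(f(g$i, g$j, g$k), dim = dim3),
                 affine %||% diag(4))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Small phantom study shared by pipeline-level tests.
make_small_study <- function(n = 20L, seed = 5L, subdivision = 2L,
                             n_parcels = 8L, noise_sd = 0.05) {
  geom <- simulate_phantom_geometry(subdivision = subdivision,
                                    n_parcels = n_parcels, seed = seed)
  spec <- default_effect_spec(noise_sd = noise_sd)
  cohort <- simulate_cohort(n, seed = seed + 1L)
  stack <- build_depth_surfaces(geom$ribbon)
  list(geom = geom, spec = spec, cohort = cohort, stack = stack)
}

# Run the sampling + moments stages for every subject of a study.
study_moments <- function(study, seed_base = 1000L) {
  out <- vector("list", nrow(study$cohort))
  for (i in seq_len(nrow(study$cohort))) {
    vol <- simulate_subject_volume(study$geom, study$cohort[i, ], study$spec,
                                   seed = seed_base + i)
    pm <- parcel_mean_profiles(sample_profiles(vol, study$stack),
                               study$geom$labels)
    mom <- profile_moments(as.matrix(pm[, grep("^depth_", names(pm))]))
    out[[i]] <- tibble::tibble(subject_id = study$cohort$subject_id[i],
                               parcel_id = pm$parcel_id,
                               mu1 = mom$mu1, mu2 = mom$mu2)
  }
  dplyr::bind_rows(out)
}
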