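#' Define the generative depth-effect specification for phantom volumes
#'
#' An effect spec gives, for each named parcel group, a 12-entry baseline
#' depth template (the expected myelin-sensitive profile of a term-born
#' neonate at birth, pial to white) plus per-depth linear slopes on
#' gestational age, postnatal age, sex, and an optional GA x PNA
#' interaction. The expected intensity of a voxel at fractional depth `f`
#' for a subject with covariates `(ga, pna, sex)` is the linear
#' interpolation at `f` of
#' `baseline + s_ga (ga - ga_ref) + s_pna (pna - pna_ref) + s_sex sex +
#'  s_int (ga - ga_ref)(pna - pna_ref)`.
#' Construction fails if any template can become non-positive anywhere over
#' the configured covariate ranges (the expected profile must stay a valid
#' intensity).
#'
#' @param groups Named list; each element a list with numeric length-12
#'   vectors `baseline`, and optionally `slope_ga`, `slope_pna`, `slope_sex`,
#'   `interaction` (defaulting to zeros).
#' @param noise_sd Gaussian voxel noise SD inside the ribbon (intensity units).
#' @param csf_value,wm_value Background intensities outside the pial surface
#'   and beneath the white surface.
#' @param ga_range,pna_range Covariate ranges the spec is validated over.
#' @param ga_ref,pna_ref Reference covariate values (defaults: term birth,
#'   scan at birth).
#' @return An object of class `laminar_effect_spec`.
#' @export
effect_spec <- function(groups, noise_sd = 0.05, csf_value = 0.3, wm_value = 1.8,
                        ga_range = c(23, 42.3), pna_range = c(0, 7),
                        ga_ref = 40, pna_ref = 0) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == "")) {
    stop_parameter("`groups` must be a named list")
  }
  groups <- lapply(groups, function(g) {
    fill <- function(x) {
      x <- x %||% rep(0, 12)
      if (length(x) == 1L) x <- rep(x, 12)
      if (length(x) != 12L) stop_parameter("effect templates must have exactly 12 entries")
      as.numeric(x)
    }
    g$baseline <- fill(g$baseline)
    if (any(g$baseline < 0)) stop_parameter("baseline template must be non-negative")
    g$slope_ga <- fill(g$slope_ga); g$slope_pna <- fill(g$slope_pna)
    g$slope_sex <- fill(g$slope_sex); g$interaction <- fill(g$interaction)
    g
  })
  spec <- structure(
    list(groups = groups, noise_sd = noise_sd, csf_value = csf_value,
         wm_value = wm_value, ga_range = ga_range, pna_range = pna_range,
         ga_ref = ga_ref, pna_ref = pna_ref),
    class = "laminar_effect_spec")
  # Bilinear in (ga, pna) at fixed sex, so positivity over the box is
  # decided at its corners.
  for (gname in names(groups)) {
    for (ga in ga_range) for (pna in pna_range) for (sex in c(0, 1)) {
      tmpl <- evaluate_template(spec, gname, ga, pna, sex)
      if (any(tmpl < 0) || sum(tmpl) <= 0) {
        stop_parameter(sprintf(
          "group \"%s\": expected intensity non-positive at GA=%.1f, PNA=%.1f, sex=%d",
          gname, ga, pna, sex))
      }
    }
  }
  spec
}

#' Default three-group effect specification
#'
#' Groups: `deep_ga` carries a positive GA slope confined to the deep
#' depths (9-12), `superficial_pna` a positive PNA slope confined to the
#' superficial depths (1-4), and `null` no age effect. `swap_depths`
#' exchanges the deep/superficial placement, which flips the sign of the
#' induced center-of-gravity effect.
#'
#' The default background intensities continue the baseline template across
#' the pial (CSF side) and white boundaries, so that measured pipeline error
#' reflects sampling and surface placement rather than boundary
#' partial-volume steps; pass contrasting `csf_value`/`wm_value` to emulate
#' sharp tissue boundaries instead.
#'
#' @param slope Per-week effect size at affected depths (default 0.012).
#' @param noise_sd Voxel noise SD (default 0.05).
#' @param swap_depths Plant the GA effect superficially and the PNA effect
#'   deep instead.
#' @param csf_value,wm_value Background intensities (defaults continue the
#'   baseline template: 1.0 and 1.6).
#' @param ... Passed to [effect_spec()].
#' @return A `laminar_effect_spec`.
#' @export
default_effect_spec <- function(slope = 0.012, noise_sd = 0.05,
                                swap_depths = FALSE, csf_value = 1.0,
                                wm_value = 1.6, ...) {
  baseline <- seq(1.0, 1.6, length.out = 12)
  deep <- c(rep(0, 8), rep(1, 4))
  superficial <- c(rep(1, 4), rep(0, 8))
  ga_profile <- if (swap_depths) superficial else deep
  pna_profile <- if (swap_depths) deep else superficial
  effect_spec(
    groups = list(
      deep_ga = list(baseline = baseline, slope_ga = slope * ga_profile),
      superficial_pna = list(baseline = baseline, slope_pna = slope * pna_profile),
      null = list(baseline = baseline)),
    noise_sd = noise_sd, csf_value = csf_value, wm_value = wm_value, ...)
}

# Noiseless 12-depth expected profile for one group and one subject.
evaluate_template <- function(spec, group, ga, pna, sex) {
  g <- spec$groups[[group]]
  if (is.null(g)) stop_parameter(sprintf("unknown parcel group \"%s\"", group))
  dga <- ga - spec$ga_ref
  dpna <- pna - spec$pna_ref
  g$baseline + g$slope_ga * dga + g$slope_pna * dpna + g$slope_sex * sex +
    g$interaction * dga * dpna
}

#' Analytic ground-truth moments of the noiseless expected profile
#'
#' Evaluates the group's 12-depth expected profile at the subject's
#' covariates and returns its central moments in closed form — the
#' reference that pipeline recovery is measured against.
#'
#' @param spec A `laminar_effect_spec`.
#' @param covariates A one-row data frame with `ga_weeks`, `pna_weeks`, `sex`.
#' @param parcel_group Group name in `spec$groups`.
#' @return A one-row tibble with `mu1`, `mu2`.
#' @export
expected_moments <- function(spec, covariates, parcel_group) {
  tmpl <- evaluate_template(spec, parcel_group, covariates$ga_weeks[1],
                            covariates$pna_weeks[1], covariates$sex[1])
  if (any(tmpl < 0) || sum(tmpl) <= 0) {
    stop_domain("expected profile is non-positive; spec invalid at these covariates")
  }
  profile_moments(tmpl)
}

# ---- phantom geometry ------------------------------------------------------

# Low-order angular harmonic basis (l = 2 quadratic forms of the unit
# direction), used for smooth deterministic radius/thickness perturbations.
angular_basis <- function(u) {
  cbind(u[, 1] * u[, 2], u[, 2] * u[, 3], u[, 1] * u[, 3],
        u[, 1]^2 - u[, 2]^2, 3 * u[, 3]^2 - 1)
}

# Smooth field on the sphere: coef-weighted basis, normalized so its max
# absolute value over a fixed dense direction set equals 1.
angular_field <- function(u, coef, norm_const) {
  as.vector(angular_basis(u) %*% coef) / norm_const
}

#' Simulate phantom cortical-ribbon geometry
#'
#' Builds a closed synthetic "cortex": the white surface is an icosphere
#' whose radius is modulated by a smooth random angular field, the pial
#' surface lies strictly outside it along each vertex ray at a smoothly
#' varying cortical thickness, and parcels are the spherical Voronoi cells
#' of random seed directions (hence contiguous). The base icosphere supplies
#' the per-vertex spherical projection used by spin tests. Because radius
#' and thickness are closed-form functions of direction, every voxel of the
#' sampling grid has an analytically known fractional cortical depth, which
#' is cached on the returned object together with voxel parcel labels.
#'
#' @param subdivision Icosphere subdivision level (>= 2; default 4 gives
#'   2562 vertices).
#' @param n_parcels Number of parcels (>= 2, default 33).
#' @param radius Mean white-surface radius in mm (default 12).
#' @param thickness Mean cortical thickness in mm (default 2).
#' @param radius_amp,thickness_amp Relative amplitudes of the smooth radius
#'   and thickness modulation (defaults 0.08 and 0.15).
#' @param voxel_size Sampling-grid resolution in mm (default 0.5).
#' @param seed Integer seed.
#' @return An object of class `laminar_phantom` with elements `ribbon`,
#'   `sphere` (unit-norm per-vertex projection), `labels` (per-vertex parcel
#'   id), `n_parcels`, `grid` (dim, affine, voxel cache), `params`.
#' @export
simulate_phantom_geometry <- function(subdivision = 4L, n_parcels = 33L,
                                      radius = 12, thickness = 2,
                                      radius_amp = 0.08, thickness_amp = 0.15,
                                      voxel_size = 0.5, seed = 1L) {
  if (subdivision < 2L) stop_parameter("`subdivision` must be at least 2")
  if (n_parcels < 2L) stop_parameter("`n_parcels` must be at least 2")
  if (thickness <= 0 || radius <= 0) stop_geometry("radius and thickness must be positive")
  if (thickness_amp >= 1) {
    stop_geometry("thickness amplitude >= 1 yields non-positive thickness")
  }
  base <- icosphere(subdivision)
  u <- base$vertices
  dense <- icosphere(3L)$vertices  # fixed normalization set for field scaling
  withr::with_seed(seed, {
    coef_w <- stats::rnorm(5L)
    coef_t <- stats::rnorm(5L)
    norm_w <- max(abs(angular_basis(dense) %*% coef_w))
    norm_t <- max(abs(angular_basis(dense) %*% coef_t))
    seeds_ok <- FALSE
    for (try in 1:50) {
      pseed <- matrix(stats::rnorm(3L * n_parcels), ncol = 3L)
      pseed <- pseed / sqrt(rowSums(pseed^2))
      labels <- max.col(u %*% t(pseed), ties.method = "first")
      if (length(unique(labels)) == n_parcels) { seeds_ok <- TRUE; break }
    }
  })
  if (!seeds_ok) {
    stop_parameter("could not place non-empty parcels; lower `n_parcels` or raise `subdivision`")
  }
  r_white_fun <- function(uu) radius * (1 + radius_amp * angular_field(uu, coef_w, norm_w))
  thick_fun <- function(uu) thickness * (1 + thickness_amp * angular_field(uu, coef_t, norm_t))
  r_w <- r_white_fun(u)
  th <- thick_fun(u)
  if (any(th <= 0) || any(r_w <= 0)) stop_geometry("perturbation produced non-positive geometry")
  white <- surface_mesh(u * r_w, base$triangles)
  pial <- surface_mesh(u * (r_w + th), base$triangles)

  # Sampling grid: odd-dimensioned, centered on the origin, RAS-aligned.
  max_r <- max(r_white_fun(dense) + thick_fun(dense)) + 2 * voxel_size
  half <- ceiling(max_r / voxel_size)
  dim3 <- rep(2L * half + 1L, 3L)
  affine <- diag(c(voxel_size, voxel_size, voxel_size, 1))
  affine[1:3, 4] <- -half * voxel_size
  ax <- (seq_len(dim3[1]) - 1L - half) * voxel_size
  coords <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  r <- sqrt(rowSums(coords^2))
  uu <- coords / pmax(r, .Machine$double.eps)
  rw_v <- r_white_fun(uu)
  th_v <- thick_fun(uu)
  f <- (rw_v + th_v - r) / th_v          # fractional depth from pial
  region <- integer(nrow(coords))        # 0 = CSF, 1 = ribbon, 2 = white
  region[f >= 0 & f <= 1] <- 1L
  region[f > 1] <- 2L
  ribbon_idx <- which(region == 1L)
  vox_labels <- max.col(uu[ribbon_idx, , drop = FALSE] %*% t(pseed),
                        ties.method = "first")
  structure(
    list(ribbon = cortical_ribbon(pial, white), sphere = u,
         labels = labels, n_parcels = as.integer(n_parcels),
         parcel_seeds = pseed,
         grid = list(dim = dim3, affine = affine, region = region,
                     ribbon_idx = ribbon_idx, depth_frac = f[ribbon_idx],
                     vox_labels = vox_labels),
         params = list(subdivision = subdivision, radius = radius,
                       thickness = thickness, radius_amp = radius_amp,
                       thickness_amp = thickness_amp, voxel_size = voxel_size,
                       seed = seed)),
    class = "laminar_phantom")
}

#' @export
print.laminar_phantom <- function(x, ...) {
  cat(sprintf("<laminar_phantom> %d vertices, %d parcels, %s grid @ %.2g mm\n",
              nrow(x$sphere), x$n_parcels,
              paste(x$grid$dim, collapse = "x"), x$params$voxel_size))
  invisible(x)
}

#' Mean parcel thickness of a phantom
#'
#' Per-vertex pial-white radial distance averaged within each parcel.
#'
#' @param geom A `laminar_phantom`.
#' @return Tibble with `parcel_id`, `thickness_mm`.
#' @export
parcel_thickness <- function(geom) {
  d <- sqrt(rowSums((geom$ribbon$pial$vertices - geom$ribbon$white$vertices)^2))
  tibble::tibble(
    parcel_id = sort(unique(geom$labels)),
    thickness_mm = as.vector(rowsum(d, geom$labels) / as.vector(table(geom$labels))))
}

#' Default parcel-to-group assignment of a phantom
#'
#' Assigns parcels to effect-spec groups in contiguous azimuthal sectors
#' (parcels ranked by the azimuth of their seed directions and split into
#' near-equal blocks), so planted effects form spatially coherent territories
#' the way regional developmental effects cluster on the real cortex. This
#' also keeps most parcel borders — where a vertex's trilinear support mixes
#' neighbouring parcels' intensities — inside a single group.
#'
#' @param geom A `laminar_phantom`.
#' @param group_names Character vector of effect-spec group names.
#' @return Character vector of length `geom$n_parcels` mapping parcel id to
#'   group name.
#' @export
parcel_groups <- function(geom, group_names) {
  az <- atan2(geom$parcel_seeds[, 2], geom$parcel_seeds[, 1])
  blocks <- ceiling(rank(az, ties.method = "first") *
                      length(group_names) / geom$n_parcels)
  group_names[blocks]
}

#' Simulate one subject's phantom volume
#'
#' Fills the phantom grid: voxels inside the ribbon receive the parcel
#' group's expected depth template linearly interpolated at the voxel's
#' analytic fractional depth, plus Gaussian noise of SD `spec$noise_sd`;
#' voxels outside the pial surface receive `spec$csf_value` and voxels
#' beneath the white surface `spec$wm_value`.
#'
#' @param geom A `laminar_phantom`.
#' @param covariates One cohort row (needs `ga_weeks`, `pna_weeks`, `sex`).
#' @param spec A `laminar_effect_spec`.
#' @param seed Integer seed; identical arguments give bit-identical volumes.
#' @param parcel_group Optional character vector mapping parcel id to group
#'   name; defaults to round-robin assignment over `names(spec$groups)`.
#' @return A `laminar_volume`.
#' @export
simulate_subject_volume <- function(geom, covariates, spec, seed,
                                    parcel_group = NULL) {
  if (!inherits(geom, "laminar_phantom")) stop_contract("`geom` must be a laminar_phantom")
  if (!inherits(spec, "laminar_effect_spec")) stop_contract("`spec` must be a laminar_effect_spec")
  ga <- covariates$ga_weeks[1]; pna <- covariates$pna_weeks[1]; sex <- covariates$sex[1]
  if (ga < spec$ga_range[1] || ga > spec$ga_range[2] ||
      pna < spec$pna_range[1] || pna > spec$pna_range[2]) {
    stop_parameter("covariates outside the spec's validated range")
  }
  parcel_group <- parcel_group %||% parcel_groups(geom, names(spec$groups))
  if (length(parcel_group) != geom$n_parcels) {
    stop_parameter("`parcel_group` must map every parcel")
  }
  gnames <- names(spec$groups)
  tm <- vapply(gnames, function(g) evaluate_template(spec, g, ga, pna, sex),
               numeric(12L))          # 12 x n_groups
  gr <- geom$grid
  vox_group <- match(parcel_group[gr$vox_labels], gnames)
  pos <- 1 + gr$depth_frac * 11       # depth coordinate, 1 = pial .. 12 = white
  lo <- pmin(floor(pos), 11)
  w <- pos - lo
  base_idx <- lo + 12L * (vox_group - 1L)
  values <- tm[base_idx] * (1 - w) + tm[base_idx + 1L] * w
  if (spec$noise_sd > 0) {
    withr::with_seed(seed, {
      values <- values + stats::rnorm(length(values), sd = spec$noise_sd)
    })
  }
  vol <- numeric(prod(gr$dim))
  vol[gr$region == 0L] <- spec$csf_value
  vol[gr$region == 2L] <- spec$wm_value
  vol[gr$ribbon_idx] <- values
  laminar_volume(array(vol, dim = gr$dim), gr$affine)
}
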