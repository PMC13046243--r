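#' Default pipeline configuration
#'
#' Returns the configuration list understood by [run_pipeline()], with a
#' simulation block describing a phantom study. Exactly one of `simulate`
#' or `inputs` may be present in a config. All randomness flows from
#' `seed` through fixed per-stage substreams, so a config plus seed fully
#' determines every numeric output.
#'
#' @param n Number of simulated subjects.
#' @param seed Master seed.
#' @param out Output directory.
#' @param subdivision,n_parcels,voxel_size Phantom geometry settings.
#' @param n_depths Number of equivolumetric depth surfaces (default 12).
#' @param k_modes Number of geometric eigenmodes (default 10).
#' @param n_perm Spin permutations per test (default 1000).
#' @param alpha BH-FDR level per moment (default 0.025).
#' @param noise_sd Phantom voxel noise SD.
#' @param interaction Also fit the GA x PNA interaction model.
#' @return A config list.
#' @export
pipeline_config <- function(n = 40L, seed = 7L, out = tempfile("neolaminar_run_"),
                            subdivision = 3L, n_parcels = 33L, voxel_size = 0.5,
                            n_depths = 12L, k_modes = 10L, n_perm = 1000L,
                            alpha = 0.025, noise_sd = 0.05, interaction = FALSE) {
  list(
    seed = as.integer(seed), out = out, n_depths = as.integer(n_depths),
    k_modes = as.integer(k_modes), n_perm = as.integer(n_perm), alpha = alpha,
    interaction = isTRUE(interaction),
    simulate = list(n = as.integer(n), subdivision = as.integer(subdivision),
                    n_parcels = as.integer(n_parcels), voxel_size = voxel_size,
                    noise_sd = noise_sd))
}

#' Run the full depth-profiling pipeline
#'
#' Executes, in order: cohort + phantom simulation (or ingestion of real
#' surfaces/volumes), equivolumetric depth-surface construction, per-subject
#' volume sampling, parcel-level central moments, parcel-wise developmental
#' models (PMA + sex; GA + PNA + sex; optionally the GA x PNA interaction),
#' geometric eigenmodes of the midthickness mesh, spin permutation tests of
#' each effect map against modes 2-4, and eigenmode variance decomposition.
#' Every artifact is written under `config$out` and listed in
#' `manifest.json`; rerunning with the same config and seed reproduces the
#' numeric outputs byte for byte.
#'
#' @param config A list from [pipeline_config()] (or a compatible list with
#'   an `inputs` block of file paths instead of `simulate`).
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs) {
    stop_contract("config must contain exactly one of `simulate` or `inputs`")
  }
  out <- config$out %||% stop_contract("config lacks an output directory")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  n_depths <- config$n_depths %||% 12L
  alpha <- config$alpha %||% 0.025
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message("[neolaminar] ", msg)
  }
  artifacts <- character(0)
  emit <- function(writer, obj, name) {
    path <- file.path(out, name)
    writer(obj, path)
    artifacts <<- c(artifacts, name)
    path
  }

  stage_seeds <- list(cohort = derive_seed(seed, 1L), geometry = derive_seed(seed, 2L),
                      volumes = derive_seed(seed, 3L), spin = derive_seed(seed, 4L))

  if (has_sim) {
    sim <- config$simulate
    note("simulate: cohort n=%d", sim$n)
    cohort <- simulate_cohort(sim$n, seed = stage_seeds$cohort)
    geom <- simulate_phantom_geometry(
      subdivision = sim$subdivision %||% 3L, n_parcels = sim$n_parcels %||% 33L,
      voxel_size = sim$voxel_size %||% 0.5, seed = stage_seeds$geometry)
    spec <- default_effect_spec(noise_sd = sim$noise_sd %||% 0.05)
    labels <- geom$labels
    sphere <- geom$sphere
    ribbon <- geom$ribbon
    excluded <- integer(0)
  } else {
    inp <- config$inputs
    note("inputs: reading surfaces and cohort")
    cohort <- read_cohort(inp$cohort)
    ribbon <- cortical_ribbon(read_surface(inp$pial), read_surface(inp$white))
    sphere <- read_surface(inp$sphere)$vertices
    sphere <- sphere / sqrt(rowSums(sphere^2))
    labels <- read_labels(inp$labels)
    excluded <- inp$excluded_ids %||% integer(0)
    geom <- NULL; spec <- NULL
  }
  emit(write_cohort, cohort, "cohort.csv")
  emit(write_surface, ribbon$pial, "pial.surf.gii")
  emit(write_surface, ribbon$white, "white.surf.gii")
  emit(function(x, p) write_labels(x, p), labels, "parcels.label.gii")

  note("surfaces: %d equivolumetric depths", n_depths)
  stack <- build_depth_surfaces(ribbon, n_depths = n_depths)

  note("sampling: %d subjects", nrow(cohort))
  moments <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    vol <- if (has_sim) {
      simulate_subject_volume(geom, cohort[i, ], spec,
                              seed = derive_seed(stage_seeds$volumes, i))
    } else {
      read_volume(config$inputs$volumes[[cohort$subject_id[i]]])
    }
    prof <- sample_profiles(vol, stack)
    pm <- parcel_mean_profiles(prof, labels, excluded_ids = excluded)
    mom <- profile_moments(as.matrix(pm[, grep("^depth_", names(pm))]))
    moments[[i]] <- tibble::tibble(subject_id = cohort$subject_id[i],
                                   parcel_id = pm$parcel_id,
                                   n_vertices = pm$n_vertices,
                                   mu1 = mom$mu1, mu2 = mom$mu2)
  }
  moments <- dplyr::bind_rows(moments)
  emit(function(x, p) readr::write_csv(x, p), moments, "parcel_moments.csv")

  note("models: parcel-wise developmental fits")
  model_sets <- list(pma = c("pma", "sex"), ga = c("ga", "pna", "sex"),
                     pna = c("ga", "pna", "sex"))
  effects <- list()
  for (resp in c("mu1", "mu2")) {
    for (term in names(model_sets)) {
      em <- parcelwise_effects(moments, cohort, predictors = model_sets[[term]],
                               term = term, response = resp, alpha = alpha)
      effects[[paste(term, resp, sep = "_")]] <- em
      emit(function(x, p) readr::write_csv(x, p), em,
           sprintf("effects_%s_%s.csv", term, resp))
    }
    if (isTRUE(config$interaction)) {
      em <- interaction_effects(moments, cohort, response = resp, alpha = alpha)
      effects[[paste("ga_pna", resp, sep = "_")]] <- em
      emit(function(x, p) readr::write_csv(x, p), em,
           sprintf("effects_interaction_%s.csv", resp))
    }
  }

  note("model comparison: global mean moments")
  global_mu <- moments |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(mu1 = mean(.data$mu1), mu2 = mean(.data$mu2)) |>
    (\(d) d[match(cohort$subject_id, d$subject_id), ])()
  candidate_specs <- list(c("sex"), c("ga", "sex"), c("pna", "sex"),
                          c("ga", "pna", "sex"))
  comparison <- dplyr::bind_rows(
    dplyr::mutate(compare_models(global_mu$mu1, cohort, candidate_specs)$models,
                  response = "mu1"),
    dplyr::mutate(compare_models(global_mu$mu2, cohort, candidate_specs)$models,
                  response = "mu2"))
  emit(function(x, p) readr::write_csv(x, p), comparison, "model_comparison.csv")

  note("eigenmodes: k=%d on midthickness mesh", config$k_modes %||% 10L)
  mid <- surface_mesh((ribbon$pial$vertices + ribbon$white$vertices) / 2,
                      ribbon$pial$triangles)
  basis <- compute_eigenmodes(mid, k = config$k_modes %||% 10L)
  emit(function(x, p) readr::write_csv(x, p),
       tibble::tibble(mode = seq_along(basis$evals), eigenvalue = basis$evals),
       "eigenvalues.csv")
  emit(function(x, p) write_metric(x, p), basis$modes, "modes.func.gii")

  note("spin tests: effect maps vs modes 2-4 (%d permutations)",
       config$n_perm %||% 1000L)
  spin_rows <- list()
  vex_rows <- list()
  spin_i <- 0L
  for (nm in names(effects)) {
    tmap <- upsample_parcel_map(effects[[nm]], labels)
    if (stats::sd(tmap, na.rm = TRUE) == 0) next
    for (mode in 2:4) {
      spin_i <- spin_i + 1L
      sr <- spin_correlation_test(tmap, basis$modes[, mode], sphere,
                                  n_perm = config$n_perm %||% 1000L,
                                  seed = derive_seed(stage_seeds$spin, spin_i))
      spin_rows[[length(spin_rows) + 1L]] <-
        tibble::tibble(effect = nm, mode = mode, r = sr$r_obs,
                       p_spin = sr$p_spin, n_perm = sr$n_perm, seed = sr$seed)
    }
    vex <- eigenmode_variance_explained(tmap, basis)
    vex$effect <- nm
    vex_rows[[length(vex_rows) + 1L]] <- vex[, c("effect", "subset", "r.squared",
                                                 "n_vertices")]
  }
  spin_tab <- dplyr::bind_rows(spin_rows)
  emit(function(x, p) jsonlite::write_json(x, p, digits = NA, auto_unbox = TRUE),
       spin_tab, "spin_results.json")
  emit(function(x, p) readr::write_csv(x, p), dplyr::bind_rows(vex_rows),
       "variance_explained.csv")

  cfg_path <- file.path(out, "config.json")
  cfg_json <- config
  cfg_json$out <- NULL
  jsonlite::write_json(cfg_json, cfg_path, auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, "config.json")
  manifest <- list(
    package = "neolaminar",
    version = as.character(utils::packageVersion("neolaminar")),
    seed = seed, stage_seeds = stage_seeds,
    config_md5 = unname(tools::md5sum(cfg_path)),
    artifacts = c(artifacts, "manifest.json"),
    log = log_lines)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("done: %d artifacts in %s", length(manifest$artifacts), out)
  invisible(list(cohort = cohort, moments = moments, effects = effects,
                 comparison = comparison, basis = basis, spin = spin_tab,
                 variance_explained = dplyr::bind_rows(vex_rows),
                 out = out, manifest = manifest))
}
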