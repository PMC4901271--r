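# End-to-end experiment orchestration: simulate -> RDMs -> comparison ->
# inference -> report, with deterministic seeding and JSON manifests.  These
# are the functions behind the command-line entry point in inst/cli.

#' Default experiment configuration
#'
#' Desk-scale defaults for the synthetic end-to-end experiments: 15
#' subjects, 16 conditions, 8 layers with latencies 100 + 10 l ms, 32
#' sensors, a -50..300 ms epoch at 5 ms steps, M = 10 trials sub-averaged in
#' groups of k = 5, 50 decoding repetitions, and 1000-sample permutation
#' inference.  See the methods vignette for the rationale behind each value.
#'
#' @param ... overrides for any field.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_subjects = 15L, n_conditions = 16L, n_layers = 8L,
    hierarchy_sign = +1, latency_base = 100, latency_step = 10,
    noise_sd = 10, kernel_sd_ms = 20, signal_amplitude = 1,
    n_sensors = 32L, n_trials = 10L,
    times_ms = seq(-50, 300, by = 5),
    k = 5L, n_reps = 50L,
    units_per_layer = 1000L,
    n_voxels_per_region = 100L, fmri_noise_scale = 0.1,
    mesh_rows = 10L, mesh_cols = 10L, mesh_spacing_mm = 3,
    searchlight_radius_mm = 9,
    n_perm = 1000L, cluster_def_p = 0.05, cluster_p = 0.05,
    peak_window_ms = NULL,
    seed = 1L)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Read a YAML run configuration
#'
#' Fields missing from the file fall back to [default_config()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configurations")
  do.call(default_config, yaml::read_yaml(path))
}

cfg_ground_truth <- function(cfg) {
  lat <- cfg$latency_base + cfg$latency_step * seq_len(cfg$n_layers)
  if (cfg$hierarchy_sign == -1) lat <- rev(lat)
  if (cfg$hierarchy_sign == 0) lat <- rep(mean(lat), cfg$n_layers)
  ground_truth(cfg$n_conditions, cfg$n_layers, layer_latency_ms = lat,
               hierarchy_sign = cfg$hierarchy_sign, noise_sd = cfg$noise_sd,
               kernel_sd_ms = cfg$kernel_sd_ms,
               signal_amplitude = cfg$signal_amplitude, seed = cfg$seed)
}

#' Run the temporal (MEG-style) experiment end to end
#'
#' Simulates a multi-subject MEG experiment with a known layer-latency
#' hierarchy, computes time-resolved decoding RDMs per subject, correlates
#' them with each layer's model RDM, runs cluster-corrected group inference
#' per layer (Bonferroni over layers), extracts peak and onset latencies,
#' and computes the layer-vs-peak-latency hierarchy statistic.
#'
#' @param cfg configuration from [default_config()].
#' @param out_dir optional output directory for CSV exports and the JSON
#'   manifest.
#' @return An object of class `"rsa_temporal_report"`: `timecourses` (one
#'   [similarity_timecourse()] per layer), `cluster_results`,
#'   `peak_latencies` (subjects x layers, ms), `onset_latencies` (per
#'   layer, ms), `hierarchy` ([hierarchy_statistic()] result), `gt`, `cfg`.
#' @export
run_temporal_experiment <- function(cfg = default_config(), out_dir = NULL) {
  gt <- cfg_ground_truth(cfg)
  acts <- simulate_layer_activations(gt, cfg$units_per_layer)
  lrdms <- layer_rdms(acts, quiet = TRUE)
  series <- lapply(seq_len(cfg$n_subjects), function(s) {
    meg <- simulate_meg_subject(gt, n_sensors = cfg$n_sensors,
                                n_trials = cfg$n_trials,
                                times_ms = cfg$times_ms, subject = s)
    decoding_rdm_timeseries(meg, k = cfg$k, n_reps = cfg$n_reps,
                            seed = derive_seed(cfg$seed, "decode", s))
  })
  timecourses <- lapply(seq_len(cfg$n_layers), function(l)
    stack_timecourses(lapply(series, timecourse, model_rdm = lrdms[[l]],
                             label = paste0("layer", l))))
  names(timecourses) <- names(lrdms)
  cluster_results <- lapply(seq_len(cfg$n_layers), function(l)
    cluster_extent_correct(timecourses[[l]]$values,
                           cluster_def_p = cfg$cluster_def_p,
                           cluster_p = cfg$cluster_p, n_perm = cfg$n_perm,
                           bonferroni_factor = cfg$n_layers,
                           seed = derive_seed(cfg$seed, "cluster", l)))
  names(cluster_results) <- names(lrdms)
  peaks <- vapply(timecourses, peak_latency, window_ms = cfg$peak_window_ms,
                  numeric(cfg$n_subjects))
  onsets <- vapply(seq_len(cfg$n_layers), function(l)
    onset_latency(timecourses[[l]], cluster_results[[l]]$significant_mask),
    numeric(1))
  hier <- hierarchy_statistic(peaks, n_perm = cfg$n_perm,
                              seed = derive_seed(cfg$seed, "hier"))
  report <- structure(list(timecourses = timecourses,
                           cluster_results = cluster_results,
                           peak_latencies = peaks, onset_latencies = onsets,
                           hierarchy = hier, layer_rdms = lrdms,
                           gt = gt, cfg = cfg),
                      class = "rsa_temporal_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (l in seq_len(cfg$n_layers))
      write_timecourse_csv(timecourses[[l]],
                           file.path(out_dir, sprintf("timecourse_layer%d.csv", l)))
    utils::write.csv(data.frame(subject = rep(seq_len(cfg$n_subjects), cfg$n_layers),
                                layer = rep(seq_len(cfg$n_layers), each = cfg$n_subjects),
                                peak_latency_ms = as.vector(peaks)),
                     file.path(out_dir, "peak_latencies.csv"), row.names = FALSE)
    write_manifest(cfg, file.path(out_dir, "manifest.json"),
                   extra = list(experiment = "temporal",
                                group_R = hier$group_R, p_value = hier$p_value))
  }
  report
}

#' @export
print.rsa_temporal_report <- function(x, ...) {
  cat(sprintf("rsa_temporal_report: %d subjects, %d layers, %d timepoints\n",
              nrow(x$peak_latencies), ncol(x$peak_latencies),
              length(x$timecourses[[1]]$times_ms)))
  cat(sprintf("  group mean peak latency per layer (ms): %s\n",
              paste(round(colMeans(x$peak_latencies, na.rm = TRUE), 1), collapse = ", ")))
  cat(sprintf("  hierarchy: group R = %.3f, P = %.4g\n",
              x$hierarchy$group_R, x$hierarchy$p_value))
  invisible(x)
}

#' Run the spatial (fMRI searchlight) experiment end to end
#'
#' Builds a flat toy cortical mesh, paints the deepest layer's
#' representational structure onto an "anterior" patch of the mesh (the
#' remaining vertices carry pure noise), simulates per-subject voxel
#' patterns, computes geodesic searchlight RDMs and per-vertex similarity
#' maps against every layer RDM, and runs cluster-corrected group inference
#' on the deepest layer's map using mesh adjacency.
#'
#' @inheritParams run_temporal_experiment
#' @return An object of class `"rsa_spatial_report"`: `maps` (per layer,
#'   subjects x vertices), `group_maps` (per layer, mean over subjects),
#'   `cluster_result` (deepest layer), `patch_vertices`, `peak_vertex`
#'   (vertex of the deepest layer's group-map maximum),
#'   `peak_in_patch`, `mesh`, `gt`, `cfg`.
#' @export
run_spatial_experiment <- function(cfg = default_config(), out_dir = NULL) {
  gt <- cfg_ground_truth(cfg)
  mesh <- build_toy_mesh(cfg$mesh_rows, cfg$mesh_cols, cfg$mesh_spacing_mm)
  nv_mesh <- nrow(mesh$vertex_coords)
  # anterior patch: the top 30% of mesh rows carries the deepest layer
  patch <- which(mesh$vertex_coords[, "y"] >=
                   0.7 * max(mesh$vertex_coords[, "y"]))
  w <- matrix(0, 2, cfg$n_layers, dimnames = list(c("patch", "background"), NULL))
  w["patch", cfg$n_layers] <- 1
  gt$layer_region_weights <- w
  vox <- character(nv_mesh)
  vox[patch] <- paste0("patch_v", seq_along(patch))
  vox[-patch] <- paste0("background_v", seq_len(nv_mesh - length(patch)))
  mesh$vertex_to_voxel <- vox
  acts <- simulate_layer_activations(gt, cfg$units_per_layer)
  lrdms <- layer_rdms(acts, quiet = TRUE)
  disks <- build_disks(mesh, cfg$searchlight_radius_mm, quiet = TRUE)
  subj_patterns <- lapply(seq_len(cfg$n_subjects), function(s) {
    pats <- simulate_fmri_subject(gt, n_voxels_per_region =
                                    c(length(patch), nv_mesh - length(patch)),
                                  subject = s, noise_scale = cfg$fmri_noise_scale)
    spatial_patterns(cbind(pats$patch$data, pats$background$data),
                     voxel_ids = c(pats$patch$voxel_ids, pats$background$voxel_ids))
  })
  maps <- lapply(seq_len(cfg$n_layers), function(l) {
    m <- t(vapply(subj_patterns, function(p)
      searchlight_similarity_map(searchlight_rdms(disks, p), lrdms[[l]])$similarity,
      numeric(length(disks))))
    colnames(m) <- names(disks)
    m
  })
  names(maps) <- names(lrdms)
  group_maps <- lapply(maps, colMeans, na.rm = TRUE)
  adjacency <- mesh_edges(mesh$faces, mesh$vertex_coords)$edges
  # adjacency must refer to positions within the retained disk list
  keep <- as.integer(names(disks))
  adj <- adjacency[adjacency[, 1] %in% keep & adjacency[, 2] %in% keep, , drop = FALSE]
  adj <- cbind(match(adj[, 1], keep), match(adj[, 2], keep))
  deepest <- maps[[cfg$n_layers]]
  deepest[!is.finite(deepest)] <- 0
  clu <- cluster_extent_correct(deepest, cluster_def_p = cfg$cluster_def_p,
                                cluster_p = cfg$cluster_p, n_perm = cfg$n_perm,
                                bonferroni_factor = cfg$n_layers,
                                seed = derive_seed(cfg$seed, "spatial_cluster"),
                                adjacency = adj)
  gm <- group_maps[[cfg$n_layers]]
  peak_vertex <- keep[which.max(gm)]
  report <- structure(list(maps = maps, group_maps = group_maps,
                           cluster_result = clu, patch_vertices = patch,
                           peak_vertex = peak_vertex,
                           peak_in_patch = peak_vertex %in% patch,
                           mesh = mesh, disks = disks, gt = gt, cfg = cfg),
                      class = "rsa_spatial_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (l in seq_len(cfg$n_layers))
      write_map_csv(data.frame(vertex = keep, similarity = group_maps[[l]]),
                    file.path(out_dir, sprintf("map_layer%d.csv", l)))
    write_mesh_off(mesh, file.path(out_dir, "mesh.off"))
    write_manifest(cfg, file.path(out_dir, "manifest.json"),
                   extra = list(experiment = "spatial",
                                peak_vertex = peak_vertex,
                                peak_in_patch = peak_vertex %in% patch))
  }
  report
}

#' @export
print.rsa_spatial_report <- function(x, ...) {
  cat(sprintf("rsa_spatial_report: %d subjects, %d layers, %d searchlights\n",
              nrow(x$maps[[1]]), length(x$maps), ncol(x$maps[[1]])))
  cat(sprintf("  deepest-layer peak at vertex %d (inside painted patch: %s)\n",
              x$peak_vertex, x$peak_in_patch))
  invisible(x)
}

#' Run a model-comparison experiment
#'
#' Compares two whole models against the same simulated MEG data: each
#' model's PCA-balanced summary RDM ([summary_rdm()]) is correlated with the
#' time-resolved decoding RDMs, the two time courses are subtracted per
#' subject, and the difference curve is tested with two-sided
#' cluster-corrected inference.  Model A is the generating model (its layer
#' targets drive the simulated signal); model B is an independent control
#' model, so the difference should favour A after the signal emerges.
#'
#' @inheritParams run_temporal_experiment
#' @param models optional named list of two [layer_activations()] objects
#'   (`a`, `b`); by default model A is the generator's own activations and
#'   model B an independently seeded control.
#' @return An object of class `"rsa_contrast_report"`: `timecourse_a`,
#'   `timecourse_b`, `difference`, `cluster_result`, `divergence_ms`
#'   (first significant post-onset timepoint of the difference, `NA` if
#'   none), `cfg`.
#' @export
run_model_comparison <- function(cfg = default_config(), models = NULL,
                                 out_dir = NULL) {
  gt <- cfg_ground_truth(cfg)
  if (is.null(models)) {
    gt_control <- ground_truth(cfg$n_conditions, cfg$n_layers,
                               noise_sd = gt$noise_sd,
                               seed = derive_seed(cfg$seed, "control_model"))
    models <- list(a = simulate_layer_activations(gt, cfg$units_per_layer),
                   b = simulate_layer_activations(gt_control, cfg$units_per_layer))
  }
  stopifnot(length(models) == 2L)
  summaries <- lapply(models, summary_rdm)
  series <- lapply(seq_len(cfg$n_subjects), function(s) {
    meg <- simulate_meg_subject(gt, n_sensors = cfg$n_sensors,
                                n_trials = cfg$n_trials,
                                times_ms = cfg$times_ms, subject = s)
    decoding_rdm_timeseries(meg, k = cfg$k, n_reps = cfg$n_reps,
                            seed = derive_seed(cfg$seed, "decode", s))
  })
  tc_a <- stack_timecourses(lapply(series, timecourse, model_rdm = summaries[[1]],
                                   label = names(models)[1]))
  tc_b <- stack_timecourses(lapply(series, timecourse, model_rdm = summaries[[2]],
                                   label = names(models)[2]))
  diff <- model_difference_timecourse(tc_a, tc_b)
  clu <- cluster_extent_correct(diff$values, cluster_def_p = cfg$cluster_def_p,
                                cluster_p = cfg$cluster_p, n_perm = cfg$n_perm,
                                seed = derive_seed(cfg$seed, "contrast_cluster"),
                                tail = "two.sided")
  divergence <- onset_latency(diff, clu$significant_mask)
  report <- structure(list(timecourse_a = tc_a, timecourse_b = tc_b,
                           difference = diff, cluster_result = clu,
                           divergence_ms = divergence, cfg = cfg),
                      class = "rsa_contrast_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_timecourse_csv(tc_a, file.path(out_dir, "timecourse_model_a.csv"))
    write_timecourse_csv(tc_b, file.path(out_dir, "timecourse_model_b.csv"))
    write_manifest(cfg, file.path(out_dir, "manifest.json"),
                   extra = list(experiment = "contrast", divergence_ms = divergence))
  }
  report
}

#' @export
print.rsa_contrast_report <- function(x, ...) {
  cat(sprintf("rsa_contrast_report: %s vs %s, %d subjects\n",
              x$timecourse_a$label, x$timecourse_b$label, nrow(x$difference$values)))
  cat(sprintf("  divergence (first significant difference after onset): %s ms\n",
              ifelse(is.na(x$divergence_ms), "none", format(x$divergence_ms))))
  invisible(x)
}
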