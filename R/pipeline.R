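#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations of the ensemble refinement
#' protocol. The Cartesian k-means route requires a known-state model to
#' align the ensemble to first; the dRMSD k-medoids route does not, and
#' is the option when no structure is known in any state.
#'
#' @param ens an `ensemble` (or path to a multi-model PDB).
#' @param target_map a `density_map` (or MRC path). Required.
#' @param known_model optional `structure_model` (or PDB path); required
#'   for `method = "kmeans_cartesian"`.
#' @param target_model optional ground-truth `structure_model`, used only
#'   for validation RMSDs in the report, never for selection.
#' @param blur_sigma Gaussian blur applied to the target map before
#'   fitting, Angstrom (default 1.0; 0 disables).
#' @param filter a `filter_config`.
#' @param clustering list(method, k, seed); method one of
#'   `"kmeans_cartesian"`, `"kmedoids_drmsd"`.
#' @param fit a `fit_config`.
#' @param refine a `refine_config`.
#' @param spread `spread_config` used for per-frame scoring.
#' @param selection_mode `"per_trajectory"` (default) or `"global"`.
#' @param regions optional list of `region_spec` for validation RMSDs.
#' @param output_dir optional directory for final model/report files.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(ens, target_map, known_model = NULL,
                            target_model = NULL, blur_sigma = 1.0,
                            filter = filter_config(),
                            clustering = list(method = "kmeans_cartesian",
                                              k = 20, seed = 1),
                            fit = fit_config(), refine = refine_config(),
                            spread = spread_config(),
                            selection_mode = "per_trajectory",
                            regions = NULL, output_dir = NULL) {
  if (is.character(ens)) ens <- read_ensemble(ens)
  if (missing(target_map) || is.null(target_map))
    stop("validation error: no target map configured")
  if (is.character(target_map)) target_map <- read_map(target_map)
  if (is.character(known_model)) known_model <- read_structure(known_model)
  if (is.character(target_model))
    target_model <- read_structure(target_model)
  if (clustering$method == "kmeans_cartesian" && is.null(known_model))
    stop("validation error: kmeans_cartesian clustering requires a ",
         "known-state model to align to")
  structure(list(ens = ens, target_map = target_map,
                 known_model = known_model, target_model = target_model,
                 blur_sigma = blur_sigma, filter = filter,
                 clustering = clustering, fit = fit, refine = refine,
                 spread = spread, selection_mode = selection_mode,
                 regions = regions, output_dir = output_dir),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' File paths (`ensemble`, `target_map`, `known_structure`,
#' `target_structure`) are resolved relative to the YAML file; scalar
#' stage settings map onto the corresponding configuration constructors.
#'
#' @param path YAML config path.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (!is.null(p) && !file.exists(p))
    file.path(base, p) else p
  grab <- function(lst, ctor) do.call(ctor, if (is.null(lst)) list()
                                      else lst)
  pipeline_config(
    ens = rel(y$ensemble),
    target_map = rel(y$target_map),
    known_model = rel(y$known_structure),
    target_model = rel(y$target_structure),
    blur_sigma = if (is.null(y$blur_sigma)) 1.0 else y$blur_sigma,
    filter = grab(y$filter, filter_config),
    clustering = utils::modifyList(list(method = "kmeans_cartesian",
                                        k = 20, seed = 1),
                                   if (is.null(y$clustering)) list()
                                   else y$clustering),
    fit = grab(y$fit, fit_config),
    refine = grab(y$refine, refine_config),
    selection_mode = if (is.null(y$selection_mode)) "per_trajectory"
    else y$selection_mode,
    output_dir = y$output_dir)
}

align_full_model <- function(model, reference) {
  tr <- superpose(ca_coordinates(model), ca_coordinates(reference))$transform
  apply_transform(tr, model)
}

validation_rmsds <- function(final_model, config) {
  if (is.null(config$target_model)) return(NULL)
  out <- list(final_rmsd_to_target = ca_rmsd(final_model,
                                             config$target_model))
  if (!is.null(config$known_model))
    out$known_rmsd_to_target <- ca_rmsd(config$known_model,
                                        config$target_model)
  if (!is.null(config$regions)) {
    out$region_rmsd <- lapply(config$regions, function(r)
      ca_rmsd(final_model, config$target_model, region = r))
  }
  out
}

refine_and_score <- function(start_models, map_fit, config, id_prefix,
                             seed_base) {
  all_series <- list()
  results <- list()
  for (r in seq_along(start_models)) {
    fit_cfg <- config$fit
    fit_cfg$seed <- seed_base + r
    fit <- rigid_body_fit(start_models[[r]], map_fit, fit_cfg)
    ref_cfg <- config$refine
    ref_cfg$seed <- seed_base + r
    res <- refine_model(fit$model, map_fit, config = ref_cfg,
                        spread = config$spread)
    id <- sprintf("%s%02d", id_prefix, r)
    series <- score_trajectory(res, map_fit, config$spread,
                               trajectory_id = id)
    all_series[[id]] <- series
    results[[id]] <- list(fit_cc = fit$cc, initial_cc = fit$initial_cc,
                          termination = res$termination,
                          trajectory = res$trajectory, series = series)
  }
  list(series = all_series, results = results)
}

finalise_report <- function(report, selection, results, config) {
  chosen <- results[[selection$chosen_trajectory]]
  frame_pos <- match(selection$chosen_frame,
                     chosen$series$frame_indices)
  final_model <- chosen$trajectory$frames[[frame_pos]]
  report$selection <- list(
    chosen_trajectory = selection$chosen_trajectory,
    chosen_frame = selection$chosen_frame,
    mean_cc = as.list(selection$mean_cc),
    final_cc = chosen$series$cc[frame_pos],
    final_geometry_scaled = chosen$series$geometry_scaled[frame_pos],
    compound = selection$compound,
    normalization_mode = selection$normalization_mode)
  report$validation <- validation_rmsds(final_model, config)
  report$final_model <- final_model
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_structure(final_model,
                    file.path(config$output_dir, "final_model.pdb"))
    for (id in names(results))
      write_score_series(results[[id]]$series,
                         file.path(config$output_dir,
                                   sprintf("scores_%s.csv", id)))
    json <- report[setdiff(names(report), "final_model")]
    jsonlite::write_json(json, file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Run the full ensemble refinement pipeline
#'
#' Stages, in order: geometry-score the ensemble, filter at the scaled
#' threshold, align to the known state (k-means route), cluster, take
#' cluster representatives, blur the target map, rigid-body fit each
#' representative into it, run density-guided refinement from each fitted
#' pose, score every frame, pick the trajectory with the highest mean
#' cross-correlation, and within it the frame with the highest compound
#' score. Ground-truth RMSDs, when a target structure is supplied, go
#' into the validation block only — they play no part in selection.
#'
#' @param config a `pipeline_config`.
#' @param scores optional pre-computed list of `geometry_score` (e.g.
#'   from [read_external_scores()]); default: internal fallback scorer.
#' @return report list: per-stage counts, scores, cluster labels,
#'   per-trajectory results, `selection`, `validation`, `final_model`.
#' @export
run_ensemble_pipeline <- function(config, scores = NULL) {
  ens <- config$ens
  if (is.null(scores)) scores <- score_ensemble(ens)
  kept <- suppressWarnings(filter_models(ens, scores, config$filter))
  report <- list(stage_counts = list(n_input = length(ens),
                                     n_kept = length(kept),
                                     n_filtered = length(ens) - length(kept)),
                 scaled_scores = vapply(scores, `[[`, 0, "scaled"),
                 kept_indices = kept)
  if (!length(kept))
    stop("abort: no models survive the geometry filter (",
         length(ens), " scored, threshold ", config$filter$threshold, ")")
  kept_models <- ens$models[kept]
  k <- config$clustering$k
  if (k > length(kept)) {
    warning("k reduced from ", k, " to ", length(kept),
            " (post-filter ensemble size)")
    k <- length(kept)
  }
  if (config$clustering$method == "kmeans_cartesian") {
    aligned_models <- lapply(kept_models, align_full_model,
                             reference = config$known_model)
    stack <- array(0, c(length(aligned_models),
                        n_residues(config$known_model), 3))
    for (i in seq_along(aligned_models))
      stack[i, , ] <- ca_coordinates(aligned_models[[i]])
    cl <- kmeans_cluster(stack, k = k, seed = config$clustering$seed)
    reps <- aligned_models[cl$representative_indices]
  } else if (config$clustering$method == "kmedoids_drmsd") {
    dmat <- internal_distance_rmsd_matrix(ensemble(kept_models))
    cl <- kmedoids_cluster(dmat, k = k, seed = config$clustering$seed)
    reps <- kept_models[cl$representative_indices]
  } else stop("unknown clustering method: ", config$clustering$method)
  report$clustering <- list(method = cl$method, k = cl$k,
                            labels = cl$labels,
                            representative_kept_indices =
                              cl$representative_indices,
                            representative_model_indices =
                              kept[cl$representative_indices],
                            seed = cl$seed)
  map_fit <- gaussian_blur(config$target_map, config$blur_sigma)
  rs <- refine_and_score(reps, map_fit, config, "rep", config$fit$seed)
  selection <- select_final(rs$series, mode = config$selection_mode)
  report$trajectories <- lapply(rs$results, function(r)
    list(fit_cc = r$fit_cc, initial_cc = r$initial_cc,
         termination = r$termination, mean_cc = mean(r$series$cc)))
  finalise_report(report, selection, rs$results, config)
}

#' Run the single-known-structure baseline
#'
#' The conventional protocol: rigid-body fit the known structure into the
#' (blurred) target map and run density-guided refinement from it,
#' replicated with distinct seeds; the final frame is chosen by compound
#' score within the replicate with the highest mean cross-correlation.
#'
#' @param config a `pipeline_config` with `known_model` set.
#' @param n_replicates independent replicates (default 5).
#' @return report list, same layout as [run_ensemble_pipeline()].
#' @export
run_single_model_baseline <- function(config, n_replicates = 5) {
  if (is.null(config$known_model))
    stop("baseline requires known_model")
  stopifnot(n_replicates >= 1)
  map_fit <- gaussian_blur(config$target_map, config$blur_sigma)
  starts <- rep(list(config$known_model), n_replicates)
  rs <- refine_and_score(starts, map_fit, config, "baseline",
                         config$fit$seed + 1000)
  selection <- select_final(rs$series, mode = config$selection_mode)
  report <- list(stage_counts = list(n_replicates = n_replicates),
                 trajectories = lapply(rs$results, function(r)
                   list(fit_cc = r$fit_cc, initial_cc = r$initial_cc,
                        termination = r$termination,
                        mean_cc = mean(r$series$cc))))
  finalise_report(report, selection, rs$results, config)
}
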