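#' Per-frame score series for one trajectory
#'
#' @param frame_indices strictly increasing integer frame indices.
#' @param cc per-frame map cross-correlations in [-1, 1].
#' @param geometry_scaled per-frame scaled geometry scores (more negative
#'   = better).
#' @param trajectory_id label for the trajectory.
#' @return object of class `score_series`.
#' @export
score_series <- function(frame_indices, cc, geometry_scaled,
                         trajectory_id = "traj") {
  if (!length(frame_indices)) stop("empty score series")
  stopifnot(length(cc) == length(frame_indices),
            length(geometry_scaled) == length(frame_indices))
  if (any(diff(frame_indices) <= 0))
    stop("frame_indices must be strictly increasing")
  structure(list(frame_indices = as.integer(frame_indices), cc = cc,
                 geometry_scaled = geometry_scaled,
                 trajectory_id = trajectory_id),
            class = "score_series")
}

#' @export
print.score_series <- function(x, ...) {
  cat(sprintf("<score_series> '%s': %d frames, mean cc %.3f, best geometry %.4g\n",
              x$trajectory_id, length(x$cc), mean(x$cc),
              min(x$geometry_scaled)))
  invisible(x)
}

#' Min-max normalisation to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant series maps to all zeros with a
#' warning (no spread to normalise over).
#'
#' @param x numeric vector, length >= 1.
#' @param range optional c(min, max) to normalise against (used for
#'   global normalisation across pooled trajectories).
#' @return numeric vector in [0, 1].
#' @export
min_max_normalize <- function(x, range = NULL) {
  if (!length(x)) stop("empty series")
  if (is.null(range)) range <- c(min(x), max(x))
  span <- range[2] - range[1]
  if (span == 0) {
    warning("constant series: min-max normalisation returns zeros")
    return(rep(0, length(x)))
  }
  (x - range[1]) / span
}

#' Compound score per frame
#'
#' Sum of the min-max-normalised cross-correlation and the min-max-
#' normalised geometry-score magnitude, so that better map fit and better
#' geometry both increase the score; values lie in [0, 2]. Geometry
#' scores must be negative (more negative = better): taking the absolute
#' value of a positive score would invert the ordering, so any
#' non-negative score is an error. With `mode = "per_trajectory"` the
#' extrema of this series are used; with `mode = "global"` extrema are
#' pooled across all series in `pool`.
#'
#' @param series a `score_series`.
#' @param pool list of `score_series` to pool extrema over (global mode).
#' @param mode `"per_trajectory"` (default) or `"global"`.
#' @return numeric vector of compound scores in [0, 2].
#' @export
compound_scores <- function(series, pool = NULL,
                            mode = c("per_trajectory", "global")) {
  mode <- match.arg(mode)
  check_geom <- function(g) {
    if (any(g >= 0))
      stop("geometry scores must be negative (more negative = better); ",
           "|score| on a non-negative score would invert the ranking")
  }
  check_geom(series$geometry_scaled)
  if (mode == "global") {
    if (is.null(pool)) pool <- list(series)
    for (s in pool) check_geom(s$geometry_scaled)
    all_cc <- unlist(lapply(pool, `[[`, "cc"))
    all_g <- abs(unlist(lapply(pool, `[[`, "geometry_scaled")))
    cc_rng <- c(min(all_cc), max(all_cc))
    g_rng <- c(min(all_g), max(all_g))
  } else {
    cc_rng <- NULL
    g_rng <- NULL
  }
  min_max_normalize(series$cc, cc_rng) +
    min_max_normalize(abs(series$geometry_scaled), g_rng)
}

#' Select the trajectory with the highest mean cross-correlation
#'
#' Mean is over stored frames; ties go to the lexicographically smallest
#' trajectory label.
#'
#' @param all_series list of `score_series`.
#' @return the chosen trajectory's label.
#' @export
select_trajectory <- function(all_series) {
  stopifnot(length(all_series) >= 1)
  labels <- vapply(all_series, `[[`, "", "trajectory_id")
  means <- vapply(all_series, function(s) mean(s$cc), 0)
  best <- max(means)
  candidates <- labels[means == best]
  sort(candidates)[1]
}

#' Select the frame with the highest compound score
#'
#' Ties go to the earliest frame.
#'
#' @param series a `score_series`.
#' @param pool list of `score_series` for global normalisation.
#' @param mode `"per_trajectory"` or `"global"`.
#' @return the chosen frame index (value of `frame_indices`).
#' @export
select_frame <- function(series, pool = NULL,
                         mode = c("per_trajectory", "global")) {
  comp <- suppressWarnings(compound_scores(series, pool, mode))
  series$frame_indices[which.max(comp)]
}

#' Full final-model selection over a set of scored trajectories
#'
#' The pipeline's selection rule: pick the trajectory with the highest
#' mean cross-correlation, then within it the frame with the highest
#' compound score (per-trajectory normalisation by default; the global
#' variant pools extrema across all trajectories).
#'
#' @param all_series list of `score_series`.
#' @param mode `"per_trajectory"` (default) or `"global"`.
#' @return object of class `selection_report`: `chosen_trajectory`,
#'   `mean_cc` (named per trajectory), `chosen_frame`, `compound`
#'   (scores within the chosen trajectory), `normalization_mode`.
#' @export
select_final <- function(all_series, mode = c("per_trajectory", "global")) {
  mode <- match.arg(mode)
  label <- select_trajectory(all_series)
  labels <- vapply(all_series, `[[`, "", "trajectory_id")
  chosen <- all_series[[which(labels == label)[1]]]
  comp <- suppressWarnings(compound_scores(chosen, all_series, mode))
  structure(list(
    chosen_trajectory = label,
    mean_cc = stats::setNames(vapply(all_series, function(s) mean(s$cc), 0),
                              labels),
    chosen_frame = chosen$frame_indices[which.max(comp)],
    compound = comp,
    normalization_mode = mode), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> trajectory '%s' (mean cc %.3f), frame %d, %s normalisation\n",
              x$chosen_trajectory, x$mean_cc[[x$chosen_trajectory]],
              x$chosen_frame, x$normalization_mode))
  invisible(x)
}

#' Write a score series as CSV
#' @param series a `score_series`.
#' @param path output path.
#' @export
write_score_series <- function(series, path) {
  utils::write.csv(data.frame(frame = series$frame_indices,
                              cc = series$cc,
                              geometry_scaled = series$geometry_scaled,
                              trajectory_id = series$trajectory_id),
                   path, row.names = FALSE)
  invisible(path)
}
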