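#' Cross-correlation configuration
#'
#' @param mean_subtract use the mean-subtracted (Pearson) form
#'   (default TRUE); otherwise a normalised inner product.
#' @param mask_threshold if set, only voxels where the *second* (target)
#'   map exceeds this value enter the correlation.
#' @return object of class `cc_config`.
#' @export
cc_config <- function(mean_subtract = TRUE, mask_threshold = NULL) {
  structure(list(mean_subtract = mean_subtract,
                 mask_threshold = mask_threshold), class = "cc_config")
}

grids_match <- function(a, b) {
  identical(dim(a$grid), dim(b$grid)) &&
    max(abs(a$voxel_size - b$voxel_size)) < 1e-6 &&
    max(abs(a$origin - b$origin)) < 1e-6
}

cc_vectors <- function(a, b, config) {
  if (!is.null(config$mask_threshold)) {
    keep <- b > config$mask_threshold
    a <- a[keep]
    b <- b[keep]
  }
  if (length(a) < 2) stop("empty overlap between maps")
  if (config$mean_subtract) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero-variance map: cross-correlation defined as 0")
      return(0)
    }
    stats::cor(a, b)
  } else {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) {
      warning("zero-norm map: cross-correlation defined as 0")
      return(0)
    }
    sum(a * b) / (na * nb)
  }
}

#' Cross-correlation between two density maps
#'
#' Standard map similarity: with `mean_subtract`, the Pearson correlation
#' over included voxels (scale- and offset-invariant); without, the
#' normalised inner product. Maps must share grid, voxel size and origin.
#'
#' @param map_a,map_b `density_map`s on identical grids.
#' @param config a `cc_config`.
#' @return correlation in [-1, 1].
#' @export
cross_correlation <- function(map_a, map_b, config = cc_config()) {
  if (!grids_match(map_a, map_b))
    stop("grid mismatch: maps must share shape, voxel size and origin")
  cc_vectors(as.numeric(map_a$grid), as.numeric(map_b$grid), config)
}

#' Model-to-map cross-correlation
#'
#' Simulates the model on the target grid (Gaussian spreading) and
#' correlates with the target. If the model plus its spreading cutoff
#' extends beyond the target grid, the target is zero-padded to cover it,
#' with a warning.
#'
#' @param model a `structure_model`.
#' @param target a `density_map`.
#' @param spread a `spread_config`.
#' @param config a `cc_config`.
#' @return correlation in [-1, 1].
#' @export
model_map_cc <- function(model, target, spread = spread_config(),
                         config = cc_config()) {
  xyz <- atom_coords(model)[heavy_mask(model), , drop = FALSE]
  d <- dim(target$grid)
  hi <- target$origin + (d - 1L) * target$voxel_size
  if (any(apply(xyz, 2, min) - spread$cutoff < target$origin) ||
      any(apply(xyz, 2, max) + spread$cutoff > hi)) {
    warning("model extends beyond the target grid: zero-padding target")
    target <- pad_map_to_cover(target, xyz, margin = spread$cutoff)
  }
  sim <- simulate_on_grid(model, target, spread)
  cc_vectors(as.numeric(sim), as.numeric(target$grid), config)
}

#' Rigid-body fit configuration
#'
#' @param n_starts number of optimisation starts: the identity pose plus
#'   `n_starts - 1` seeded random perturbations within the bounds.
#' @param max_iter Nelder-Mead iterations per start.
#' @param rotation_bound start-perturbation rotation bound, degrees.
#' @param translation_bound start-perturbation translation bound, Angstrom.
#' @param seed RNG seed.
#' @param spread `spread_config` used to simulate the model.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(n_starts = 5, max_iter = 200, rotation_bound = 30,
                       translation_bound = 5, seed = 1,
                       spread = spread_config()) {
  stopifnot(n_starts >= 1)
  structure(list(n_starts = n_starts, max_iter = max_iter,
                 rotation_bound = rotation_bound,
                 translation_bound = translation_bound, seed = seed,
                 spread = spread), class = "fit_config")
}

quat_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

axis_angle_quat <- function(axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle_rad / 2), sin(angle_rad / 2) * axis)
}

rotation_angle_deg <- function(rot) {
  ca <- (sum(diag(rot)) - 1) / 2
  acos(min(1, max(-1, ca))) * 180 / pi
}

# pose = (q[1:4], t[1:3]); rotation about `center`, then translation
pose_transform <- function(p, center) {
  rot <- quat_to_rotation(p[1:4])
  rigid_transform(rot, center - as.numeric(rot %*% center) + p[5:7])
}

#' Rigid-body fit of a model into a density map
#'
#' Maximises the model-to-map cross-correlation over rotations and
#' translations by multi-start derivative-free (Nelder-Mead) optimisation
#' of a quaternion + translation pose, rotations taken about the model
#' centroid. The identity pose is always one of the starts, so the
#' returned correlation never falls below the input pose's. Intended for
#' roughly pre-posed models (cluster representatives aligned to a known
#' state), not a global density search.
#'
#' @param model a `structure_model`.
#' @param target a `density_map` (blur first if the pipeline blurs).
#' @param config a `fit_config`.
#' @param cc a `cc_config`.
#' @return list with `transform` (`rigid_transform`), `model` (fitted),
#'   `cc`, `initial_cc`, `n_starts`, `seed`.
#' @export
rigid_body_fit <- function(model, target, config = fit_config(),
                           cc = cc_config()) {
  if (stats::sd(as.numeric(target$grid)) == 0)
    stop("target map is constant")
  xyz0 <- atom_coords(model)
  sw <- spread_weights(model, config$spread)
  center <- colMeans(sw$coords)
  # pad once so every pose the optimiser explores stays on-grid
  target_p <- pad_map_to_cover(
    target, sw$coords,
    margin = config$spread$cutoff + config$translation_bound + 2)
  tvec <- as.numeric(target_p$grid)
  masked <- !is.null(cc$mask_threshold)
  objective <- function(p) {
    moved <- apply_transform(pose_transform(p, center), sw$coords)
    if (masked) {
      sim <- cpp_spread_atoms(moved, sw$weights, dim(target_p$grid),
                              target_p$origin, target_p$voxel_size,
                              config$spread$sigma, config$spread$cutoff)
      return(-cc_vectors(as.numeric(sim), tvec, cc))
    }
    -cpp_spread_cc(moved, sw$weights, tvec, dim(target_p$grid),
                   target_p$origin, target_p$voxel_size,
                   config$spread$sigma, config$spread$cutoff,
                   cc$mean_subtract)
  }
  identity_pose <- c(1, 0, 0, 0, 0, 0, 0)
  initial_cc <- -objective(identity_pose)
  set.seed(config$seed)
  starts <- c(list(identity_pose), lapply(seq_len(config$n_starts - 1),
    function(i) {
      ang <- stats::runif(1, 0, config$rotation_bound) * pi / 180
      ax <- stats::rnorm(3)
      tr <- stats::rnorm(3)
      tr <- tr / sqrt(sum(tr^2)) *
        stats::runif(1, 0, config$translation_bound)
      c(axis_angle_quat(ax, ang), tr)
    }))
  best <- NULL
  failed <- 0L
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, objective, method = "Nelder-Mead",
                   control = list(maxit = config$max_iter,
                                  reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) { failed <- failed + 1L; next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # Nelder-Mead simplices collapse on this landscape; restarting from
  # the incumbent with a fresh simplex recovers the lost progress
  for (round in seq_len(5)) {
    if (is.null(best)) break
    again <- tryCatch(
      stats::optim(best$par, objective, method = "Nelder-Mead",
                   control = list(maxit = config$max_iter,
                                  reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(again) || again$value > best$value - 1e-5) {
      if (!is.null(again) && again$value < best$value) best <- again
      break
    }
    best <- again
  }
  if (is.null(best) || -best$value < initial_cc) {
    if (is.null(best))
      warning("optimiser failed on all starts: returning identity pose")
    best <- list(par = identity_pose, value = -initial_cc)
  }
  tr <- pose_transform(best$par, center)
  fitted <- set_atom_coords(model, apply_transform(tr, xyz0))
  list(transform = tr, model = fitted, cc = -best$value,
       initial_cc = initial_cc, n_starts = config$n_starts,
       seed = config$seed)
}
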