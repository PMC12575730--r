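#' Density-guided refinement configuration
#'
#' The refiner is damped steepest descent on a stereochemical restraint
#' energy (bonds + angles) plus a density bias force applied every
#' `apply_every` steps. The bias force constant starts at `k_density` and
#' is multiplied by `adaptive_growth` every `growth_interval` bias
#' applications (adaptive force scaling); the run stops at `max_steps` or
#' as soon as any atom's per-step displacement exceeds
#' `displacement_limit` — the observable consequence of forces growing
#' too large for stable integration.
#'
#' @param k_density initial bias force factor in the restraint energy
#'   scale (default 5000, chosen so the initial bias displacement per
#'   application is a small fraction of `displacement_clip`, leaving the
#'   adaptive schedule in control of the run).
#' @param apply_every apply the bias force every this many steps
#'   (default 2).
#' @param adaptive_growth multiplicative growth factor (default 1.05).
#' @param growth_interval bias applications per growth step (default 10).
#' @param step_size displacement per unit force, Angstrom (default 1e-4).
#' @param relax_steps bias-free clipped-descent steps run first to
#'   relax the starting stereochemistry (the minimisation/equilibration
#'   phase of an MD workflow; default 200). Not subject to the
#'   termination criterion.
#' @param max_steps maximum biased descent steps (default 1200 — a
#'   simulation budget a few times the relaxation time of a well-posed
#'   start, so refinement quality reflects starting-point quality rather
#'   than unbounded optimisation).
#' @param frame_stride store every this many steps (default 30).
#' @param displacement_limit per-step max raw displacement triggering
#'   termination, Angstrom (default 0.5).
#' @param displacement_clip per-atom displacement cap actually applied
#'   each step, Angstrom (default 0.05) — the steepest-descent trust
#'   region that keeps stiff restraint relaxation stable; termination is
#'   judged on the raw (unclipped) displacement.
#' @param k_bond,k_angle,k_torsion restraint stiffnesses (energy per
#'   Angstrom^2 / per radian^2 / per radian^2). The torsion term gives
#'   the chain the torsional rigidity a real backbone has; without it a
#'   bond/angle-only chain bends almost freely.
#' @param bias_mode `"cc_gradient"` (default): force = k times the
#'   analytic gradient of the Pearson correlation between the simulated
#'   and target maps, whose stationary point is the generating structure;
#'   `"map_gradient"`: the simpler point-sampling force, k times the map
#'   gradient at each atom (pulls atoms up the local density, but
#'   contracts dense structures and has no fixed point at a perfect fit).
#' @param seed RNG seed (recorded; the refiner is deterministic).
#' @return object of class `refine_config`.
#' @export
refine_config <- function(k_density = 5000, apply_every = 2,
                          adaptive_growth = 1.05, growth_interval = 10,
                          step_size = 1e-4, relax_steps = 200,
                          max_steps = 1200,
                          frame_stride = 30, displacement_limit = 0.5,
                          displacement_clip = 0.05,
                          k_bond = 2000, k_angle = 200, k_torsion = 100,
                          bias_mode = c("cc_gradient", "map_gradient"),
                          seed = 1) {
  bias_mode <- match.arg(bias_mode)
  stopifnot(apply_every >= 1, adaptive_growth >= 1,
            displacement_limit > 0, step_size > 0)
  structure(list(k_density = k_density, apply_every = as.integer(apply_every),
                 bias_mode = bias_mode,
                 adaptive_growth = adaptive_growth,
                 growth_interval = as.integer(growth_interval),
                 step_size = step_size,
                 relax_steps = as.integer(relax_steps),
                 max_steps = as.integer(max_steps),
                 frame_stride = as.integer(frame_stride),
                 displacement_limit = displacement_limit,
                 displacement_clip = displacement_clip,
                 k_bond = k_bond, k_angle = k_angle,
                 k_torsion = k_torsion, seed = seed),
            class = "refine_config")
}

#' Build bond/angle restraints from a model
#'
#' Bonds come from standard residue connectivity (backbone N-CA-C=O,
#' CA-CB, inter-residue peptide C-N) plus, for any remaining side-chain or
#' nonstandard atoms, a distance heuristic (heavy-atom pairs < 1.9 A
#' within a residue). Angles are all bonded triples and torsions all
#' bonded quadruples. Standard-connectivity bonds are restrained to
#' their ideal lengths (as a force field would, so distorted bonds relax
#' to sound stereochemistry); heuristic bonds, all angles and all
#' torsions take their reference from the input model, since angles and
#' torsions can legitimately carry conformational signal. The torsion
#' term is weak, mimicking backbone torsional rigidity without
#' secondary-structure restraints, deliberately leaving the backbone
#' free to change conformation.
#'
#' @param model a `structure_model`.
#' @return object of class `restraint_topology` with `bonds`
#'   (i, j, ref Angstrom), `angles` (i, j, k with vertex j, ref rad) and
#'   `torsions` (i, j, k, l, ref rad).
#' @export
build_restraints <- function(model) {
  a <- model$atoms
  xyz <- atom_coords(model)
  named <- backbone_bonds(model)
  pairs <- cbind(named$i, named$j)
  # distance-heuristic bonds for atoms not covered by the named set,
  # within each residue (side chains, nonstandard residues)
  covered <- a$name %in% c("N", "CA", "C", "O", "CB") & !a$het
  if (any(!covered & heavy_mask(model))) {
    reskey <- paste(a$chain, a$resno, a$insert, sep = "\r")
    for (key in unique(reskey[!covered & heavy_mask(model)])) {
      idx <- which(reskey == key & heavy_mask(model))
      if (length(idx) < 2) next
      d <- as.matrix(stats::dist(xyz[idx, , drop = FALSE]))
      hit <- which(d < 1.9 & upper.tri(d), arr.ind = TRUE)
      if (nrow(hit)) {
        extra <- cbind(idx[hit[, 1]], idx[hit[, 2]])
        new <- !(paste(pmin(extra[, 1], extra[, 2]),
                       pmax(extra[, 1], extra[, 2])) %in%
                   paste(pmin(pairs[, 1], pairs[, 2]),
                         pmax(pairs[, 1], pairs[, 2])))
        pairs <- rbind(pairs, extra[new, , drop = FALSE])
      }
    }
  }
  dvec <- xyz[pairs[, 1], , drop = FALSE] - xyz[pairs[, 2], , drop = FALSE]
  ref <- sqrt(rowSums(dvec^2))
  # standard-connectivity bonds are restrained to their ideal lengths
  # (as a force field would); only heuristic bonds keep measured refs
  n_named <- nrow(named)
  if (n_named) ref[seq_len(n_named)] <- named$ideal
  if (any(ref <= 0.8 | ref >= 2.2))
    warning("bond reference length(s) outside (0.8, 2.2) A; ",
            "starting model geometry is distorted")
  bonds <- data.frame(i = pairs[, 1], j = pairs[, 2], ref = ref)
  # angles: every pair of distinct neighbours around a common vertex
  nbrs <- split(c(bonds$j, bonds$i), c(bonds$i, bonds$j))
  ai <- integer(0); aj <- integer(0); ak <- integer(0)
  for (v in names(nbrs)) {
    nb <- sort(unique(nbrs[[v]]))
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    ai <- c(ai, cmb[1, ]); aj <- c(aj, rep(as.integer(v), ncol(cmb)))
    ak <- c(ak, cmb[2, ])
  }
  # angle references are measured from the input model: bond angles can
  # legitimately carry conformational signal (e.g. a hinge), and the
  # soft angle term only needs to hold the local geometry together
  aref <- if (length(ai)) angle_values(xyz, ai, aj, ak) else numeric(0)
  # torsions: every bonded quadruple i-j-k-l around each central bond j-k
  ti <- integer(0); tj <- integer(0); tk <- integer(0); tl <- integer(0)
  for (b in seq_len(nrow(bonds))) {
    j <- bonds$i[b]; k <- bonds$j[b]
    for (i2 in setdiff(nbrs[[as.character(j)]], k))
      for (l2 in setdiff(nbrs[[as.character(k)]], j)) {
        if (i2 == l2) next
        ti <- c(ti, i2); tj <- c(tj, j); tk <- c(tk, k); tl <- c(tl, l2)
      }
  }
  tref <- if (length(ti)) torsion_values(xyz, ti, tj, tk, tl)
  else numeric(0)
  structure(list(bonds = bonds,
                 angles = data.frame(i = ai, j = aj, k = ak, ref = aref),
                 torsions = data.frame(i = ti, j = tj, k = tk, l = tl,
                                       ref = tref)),
            class = "restraint_topology")
}

torsion_values <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
  b2 <- xyz[k, , drop = FALSE] - xyz[j, , drop = FALSE]
  b3 <- xyz[l, , drop = FALSE] - xyz[k, , drop = FALSE]
  cross_rows <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                     a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                     a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross_rows(b1, b2)
  n2 <- cross_rows(b2, b3)
  lb2 <- sqrt(rowSums(b2^2))
  atan2(rowSums(cross_rows(n1, n2) * b2) / lb2, rowSums(n1 * n2))
}

wrap_angle <- function(x) atan2(sin(x), cos(x))

angle_values <- function(xyz, i, j, k) {
  u <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
  v <- xyz[k, , drop = FALSE] - xyz[j, , drop = FALSE]
  cosang <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  acos(pmin(1, pmax(-1, cosang)))
}

accumulate_rows <- function(force, idx, contrib) {
  agg <- rowsum(contrib, idx, reorder = TRUE)
  rows <- as.integer(rownames(agg))
  force[rows, ] <- force[rows, ] + agg
  force
}

restraint_energy <- function(xyz, rt, k_bond, k_angle, k_torsion = 0) {
  b <- rt$bonds
  d <- sqrt(rowSums((xyz[b$i, , drop = FALSE] -
                       xyz[b$j, , drop = FALSE])^2))
  e <- sum(k_bond * (d - b$ref)^2)
  if (nrow(rt$angles)) {
    th <- angle_values(xyz, rt$angles$i, rt$angles$j, rt$angles$k)
    e <- e + sum(k_angle * (th - rt$angles$ref)^2)
  }
  to <- rt$torsions
  if (k_torsion > 0 && !is.null(to) && nrow(to)) {
    phi <- torsion_values(xyz, to$i, to$j, to$k, to$l)
    e <- e + sum(k_torsion * wrap_angle(phi - to$ref)^2)
  }
  e
}

restraint_forces <- function(xyz, rt, k_bond, k_angle, k_torsion = 0) {
  f <- matrix(0, nrow(xyz), 3)
  b <- rt$bonds
  dvec <- xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE]
  d <- sqrt(rowSums(dvec^2))
  fb <- dvec * (-2 * k_bond * (d - b$ref) / pmax(d, 1e-8))
  f <- accumulate_rows(f, b$i, fb)
  f <- accumulate_rows(f, b$j, -fb)
  an <- rt$angles
  if (nrow(an)) {
    u <- xyz[an$i, , drop = FALSE] - xyz[an$j, , drop = FALSE]
    v <- xyz[an$k, , drop = FALSE] - xyz[an$j, , drop = FALSE]
    lu <- sqrt(rowSums(u^2)); lv <- sqrt(rowSums(v^2))
    uh <- u / lu; vh <- v / lv
    cosang <- pmin(1, pmax(-1, rowSums(uh * vh)))
    sinang <- pmax(sqrt(1 - cosang^2), 0.05)
    th <- acos(cosang)
    # taper the (1/sin)-divergent force smoothly to zero near collinear
    taper <- pmin(1, (sinang - 0.05) / 0.3)
    taper[taper < 0] <- 0
    pref <- -2 * k_angle * (th - an$ref) * taper
    # dtheta/dx_i = -(vh - cos uh) / (|u| sin); same with u<->v for k
    gi <- -(vh - cosang * uh) / (lu * sinang)
    gk <- -(uh - cosang * vh) / (lv * sinang)
    fi <- pref * gi
    fk <- pref * gk
    f <- accumulate_rows(f, an$i, fi)
    f <- accumulate_rows(f, an$k, fk)
    f <- accumulate_rows(f, an$j, -(fi + fk))
  }
  to <- rt$torsions
  if (k_torsion > 0 && !is.null(to) && nrow(to)) {
    cross_rows <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                       a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                       a[, 1] * b[, 2] - a[, 2] * b[, 1])
    b1 <- xyz[to$j, , drop = FALSE] - xyz[to$i, , drop = FALSE]
    b2 <- xyz[to$k, , drop = FALSE] - xyz[to$j, , drop = FALSE]
    b3 <- xyz[to$l, , drop = FALSE] - xyz[to$k, , drop = FALSE]
    n1 <- cross_rows(b1, b2)
    n2 <- cross_rows(b2, b3)
    lb2 <- sqrt(rowSums(b2^2))
    phi <- atan2(rowSums(cross_rows(n1, n2) * b2) / lb2,
                 rowSums(n1 * n2))
    dphi <- wrap_angle(phi - to$ref)
    n1sq <- rowSums(n1^2)
    n2sq <- rowSums(n2^2)
    # near-collinear quadruples have ill-defined torsions with divergent
    # gradients: taper their contribution to zero rather than blow up
    taper_t <- pmin(1, (pmin(n1sq, n2sq) - 0.05) / 0.95)
    taper_t[taper_t < 0] <- 0
    dphi <- dphi * taper_t
    n1sq <- pmax(n1sq, 0.05)
    n2sq <- pmax(n2sq, 0.05)
    g1 <- -n1 * (lb2 / n1sq)           # dphi/dx_i
    g4 <- n2 * (lb2 / n2sq)            # dphi/dx_l
    tfac <- rowSums(b1 * b2) / pmax(lb2^2, 1e-10)
    sfac <- rowSums(b3 * b2) / pmax(lb2^2, 1e-10)
    g2 <- -(1 + tfac) * g1 + sfac * g4  # dphi/dx_j
    g3 <- tfac * g1 - (1 + sfac) * g4   # dphi/dx_k
    pref <- -2 * k_torsion * dphi
    f <- accumulate_rows(f, to$i, pref * g1)
    f <- accumulate_rows(f, to$j, pref * g2)
    f <- accumulate_rows(f, to$k, pref * g3)
    f <- accumulate_rows(f, to$l, pref * g4)
  }
  f
}

#' Density bias force on every atom
#'
#' Force pulling atoms up the density gradient: `k` times the map
#' gradient at each atom position (the uniform-weight point-sampling
#' limit of a map-similarity bias). The gradient is the analytic
#' derivative of the trilinear interpolant at the atom position, and is
#' therefore piecewise constant per grid cell: it vanishes at a
#' symmetric density peak when the peak is centred within a cell. Zero
#' where the map is flat.
#'
#' @param model a `structure_model`.
#' @param target a `density_map`; it is zero-padded automatically if any
#'   atom lies within one voxel of (or beyond) the boundary.
#' @param k bias force constant.
#' @return n_atoms x 3 force matrix.
#' @export
density_bias_force <- function(model, target, k) {
  xyz <- atom_coords(model)
  target <- pad_map_to_cover(target, xyz,
                             margin = 2 * max(target$voxel_size))
  k * value_and_gradient(target, xyz)$gradient
}

#' Density-guided refinement of a model into a target map
#'
#' Damped steepest descent on the restraint energy with a density bias
#' force applied every `apply_every` steps, adaptive growth of the bias
#' constant, and automatic termination when any per-step displacement
#' exceeds the configured limit. The target map is max-normalised
#' internally so `k_density` has consistent units across maps, and
#' zero-padded so atoms can move outside the original box. Frames
#' (including the start, and the final state) are stored every
#' `frame_stride` steps. The run is deterministic for a given
#' configuration.
#'
#' @param model starting `structure_model`.
#' @param target a `density_map` (pre-blurred if the pipeline blurs).
#' @param restraints a `restraint_topology` (default: built from `model`).
#' @param config a `refine_config`.
#' @param spread `spread_config` used to simulate the model map for the
#'   correlation-gradient bias.
#' @return object of class `refine_result`: `trajectory`, per-frame `log`
#'   (frame, step, k, max_disp), and `termination` reason
#'   (`"max_steps"` or `"displacement_limit"`).
#' @export
refine_model <- function(model, target, restraints = NULL,
                         config = refine_config(),
                         spread = spread_config()) {
  if (is.null(restraints)) restraints <- build_restraints(model)
  set.seed(config$seed)
  gmax <- max(abs(target$grid))
  norm_target <- if (gmax > 0)
    density_map(target$grid / gmax, target$voxel_size, target$origin)
  else target
  xyz <- atom_coords(model)
  # pad generously once: room for the whole run's drift
  norm_target <- pad_map_to_cover(norm_target, xyz, margin = 12)
  tvec <- as.numeric(norm_target$grid)
  heavy <- heavy_mask(model)
  w_bias <- rep(1, sum(heavy))
  k <- config$k_density
  n_bias <- 0L
  # bias-free relaxation: clipped descent to sound starting geometry
  for (step in seq_len(config$relax_steps)) {
    f <- restraint_forces(xyz, restraints, config$k_bond, config$k_angle,
                          config$k_torsion)
    disp <- config$step_size * f
    dnorm <- sqrt(rowSums(disp^2))
    over <- dnorm > config$displacement_clip
    if (any(over))
      disp[over, ] <- disp[over, , drop = FALSE] *
        (config$displacement_clip / dnorm[over])
    xyz <- xyz + disp
  }
  frames <- list(set_atom_coords(model, xyz))
  log <- data.frame(frame = 1L, step = 0L, k = k, max_disp = 0)
  termination <- "max_steps"
  last_step <- 0L
  for (step in seq_len(config$max_steps)) {
    f <- restraint_forces(xyz, restraints, config$k_bond, config$k_angle,
                          config$k_torsion)
    if (k > 0 && step %% config$apply_every == 0) {
      if (config$bias_mode == "cc_gradient") {
        g <- cpp_cc_gradient(xyz[heavy, , drop = FALSE], w_bias, tvec,
                             dim(norm_target$grid), norm_target$origin,
                             norm_target$voxel_size, spread$sigma,
                             spread$cutoff)
        f[heavy, ] <- f[heavy, ] + k * g
      } else {
        vg <- value_and_gradient(norm_target,
                                 xyz[heavy, , drop = FALSE])
        f[heavy, ] <- f[heavy, ] + k * vg$gradient
      }
      n_bias <- n_bias + 1L
      if (n_bias %% config$growth_interval == 0)
        k <- k * config$adaptive_growth
    }
    disp <- config$step_size * f
    dnorm <- sqrt(rowSums(disp^2))
    max_disp <- max(dnorm)
    if (max_disp > config$displacement_limit) {
      if (step == 1)
        stop("config error: displacement ", signif(max_disp, 3),
             " A at step 1 exceeds the limit; reduce step_size")
      termination <- "displacement_limit"
      last_step <- step
      break
    }
    over <- dnorm > config$displacement_clip
    if (any(over))
      disp[over, ] <- disp[over, , drop = FALSE] *
        (config$displacement_clip / dnorm[over])
    xyz <- xyz + disp
    last_step <- step
    if (step %% config$frame_stride == 0) {
      frames[[length(frames) + 1]] <- set_atom_coords(model, xyz)
      log <- rbind(log, data.frame(frame = length(frames), step = step,
                                   k = k, max_disp = max_disp))
    }
  }
  if (log$step[nrow(log)] != last_step) {
    frames[[length(frames) + 1]] <- set_atom_coords(model, xyz)
    log <- rbind(log, data.frame(frame = length(frames), step = last_step,
                                 k = k, max_disp = NA))
  }
  structure(list(trajectory = trajectory(frames,
                                         frame_interval = config$frame_stride),
                 log = log, termination = termination,
                 config = config),
            class = "refine_result")
}

#' @export
print.refine_result <- function(x, ...) {
  cat(sprintf("<refine_result> %d frames, terminated: %s, final k = %.4g\n",
              length(x$trajectory$frames), x$termination,
              x$log$k[nrow(x$log)]))
  invisible(x)
}

#' Score every frame of a trajectory
#'
#' Per-frame model-to-map cross-correlation and scaled geometry score,
#' the two ingredients of the compound selection score.
#'
#' @param traj a `trajectory` or `refine_result`.
#' @param target target `density_map`.
#' @param spread a `spread_config` for the simulated frame maps.
#' @param geometry_scorer function(model) returning a `geometry_score`
#'   (default the internal fallback scorer).
#' @param trajectory_id label for the resulting series.
#' @return a `score_series`.
#' @export
score_trajectory <- function(traj, target, spread = spread_config(),
                             geometry_scorer = fallback_geometry_score,
                             trajectory_id = "traj") {
  if (inherits(traj, "refine_result")) traj <- traj$trajectory
  cc <- vapply(traj$frames, function(f)
    suppressWarnings(model_map_cc(f, target, spread)), 0)
  geom <- vapply(traj$frames, function(f) geometry_scorer(f)$scaled, 0)
  score_series(seq_along(traj$frames), cc, geom, trajectory_id)
}
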