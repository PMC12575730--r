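#' Toy two-state system configuration
#'
#' Defaults describe a 40-residue poly-alanine helix whose target state is
#' kinked by 40 degrees at the midpoint — a minimal analogue of a single
#' transmembrane helix that is straight in the known state and bent in
#' the state captured by the target density. The ensemble mixes models
#' sampled around both states with isotropic per-atom Gaussian noise,
#' standing in for the conformational spread of an AI-generated ensemble.
#'
#' @param n_res residues (default 40).
#' @param kink_residue hinge residue (default midpoint).
#' @param kink_angle hinge angle, degrees (default 40).
#' @param ensemble_size models in the ensemble (default 200).
#' @param state_b_fraction fraction of models sampled around the target
#'   state (default 0.2).
#' @param noise_sigma per-atom coordinate noise, Angstrom (default 0.5).
#' @param decoy_fraction fraction of coordinate-scrambled decoys
#'   (default 0).
#' @param map_voxel voxel size of the simulated target map, Angstrom
#'   (default 1.0).
#' @param map_sigma Gaussian spreading width, Angstrom (default 1.5).
#' @param blur_sigma extra blur applied to the target map, Angstrom
#'   (default 1.0).
#' @param seed RNG seed.
#' @return object of class `toy_system_config`.
#' @export
toy_system_config <- function(n_res = 40, kink_residue = n_res %/% 2,
                              kink_angle = 40, ensemble_size = 200,
                              state_b_fraction = 0.2, noise_sigma = 0.5,
                              decoy_fraction = 0, map_voxel = 1.0,
                              map_sigma = 1.5, blur_sigma = 1.0,
                              seed = 1) {
  stopifnot(kink_residue > 1, kink_residue < n_res,
            state_b_fraction >= 0, state_b_fraction <= 1,
            decoy_fraction >= 0, decoy_fraction <= 1)
  structure(as.list(environment()), class = "toy_system_config")
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

unit <- function(v) v / sqrt(sum(v^2))

# natural extension of reference frame: place D from A-B-C with bond
# |CD| = r, angle B-C-D = theta, torsion A-B-C-D = phi (degrees)
nerf_place <- function(a, b, c, r, theta, phi) {
  theta <- theta * pi / 180
  phi <- phi * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi),
         r * sin(theta) * sin(phi))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# backbone geometry (lengths A, angles deg) and ideal helix dihedrals
HELIX_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                   ca_cb = 1.521, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
                   ang_c_n_ca = 121.7, ang_ca_c_o = 120.5,
                   ang_n_ca_cb = 110.5, phi = -57, psi = -47,
                   omega = 180, chi_cb = -122.6)

#' Build an ideal poly-alanine alpha-helix
#'
#' Backbone (N, CA, C, O) plus CB, built residue by residue from ideal
#' bond geometry at phi = -57, psi = -47 — the canonical alpha-helix with
#' ~100 degrees twist and ~1.5 A rise per residue.
#'
#' @param n_res number of residues (>= 2).
#' @return a `structure_model` (chain "A", residues numbered from 1).
#' @export
make_helix <- function(n_res) {
  stopifnot(n_res >= 2)
  g <- HELIX_GEOM
  n_pos <- ca_pos <- c_pos <- o_pos <- cb_pos <-
    matrix(0, n_res, 3)
  n_pos[1, ] <- c(0, 0, 0)
  ca_pos[1, ] <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * pi / 180
  c_pos[1, ] <- ca_pos[1, ] + g$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      n_pos[i, ] <- nerf_place(n_pos[i - 1, ], ca_pos[i - 1, ],
                               c_pos[i - 1, ], g$c_n, g$ang_ca_c_n, g$psi)
      ca_pos[i, ] <- nerf_place(ca_pos[i - 1, ], c_pos[i - 1, ],
                                n_pos[i, ], g$n_ca, g$ang_c_n_ca, g$omega)
      c_pos[i, ] <- nerf_place(c_pos[i - 1, ], n_pos[i, ], ca_pos[i, ],
                               g$ca_c, g$ang_n_ca_c, g$phi)
    }
    o_pos[i, ] <- nerf_place(n_pos[i, ], ca_pos[i, ], c_pos[i, ], g$c_o,
                             g$ang_ca_c_o, g$psi + 180)
    cb_pos[i, ] <- nerf_place(c_pos[i, ], n_pos[i, ], ca_pos[i, ],
                              g$ca_cb, g$ang_n_ca_cb, g$chi_cb)
  }
  per_res <- function(i) data.frame(
    element = c("N", "C", "C", "O", "C"),
    name = c("N", "CA", "C", "O", "CB"),
    resno = i, resname = "ALA", chain = "A", insert = "",
    x = c(n_pos[i, 1], ca_pos[i, 1], c_pos[i, 1], o_pos[i, 1], cb_pos[i, 1]),
    y = c(n_pos[i, 2], ca_pos[i, 2], c_pos[i, 2], o_pos[i, 2], cb_pos[i, 2]),
    z = c(n_pos[i, 3], ca_pos[i, 3], c_pos[i, 3], o_pos[i, 3], cb_pos[i, 3]),
    stringsAsFactors = FALSE)
  structure_model(do.call(rbind, lapply(seq_len(n_res), per_res)))
}

rodrigues <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  u <- unit(axis)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + sin(a) * ux + (1 - cos(a)) * (ux %*% ux)
}

helix_axis <- function(model) {
  ca <- ca_coordinates(model)
  sv <- svd(scale(ca, scale = FALSE))
  ax <- sv$v[, 1]
  # orient from first to last residue for reproducibility
  if (sum((ca[nrow(ca), ] - ca[1, ]) * ax) < 0) ax <- -ax
  ax
}

#' Build a kinked poly-alanine helix
#'
#' Residues beyond the hinge are rotated rigidly about an axis
#' perpendicular to the helix axis. The rotation pivot is the backbone N
#' of the first rotated residue, so every bond length — including the
#' peptide bond across the hinge — is preserved exactly; only the hinge
#' angles change.
#'
#' @param n_res number of residues.
#' @param kink_residue last unrotated residue (the hinge).
#' @param kink_angle hinge angle, degrees.
#' @return a `structure_model`.
#' @export
make_kinked_helix <- function(n_res, kink_residue = n_res %/% 2,
                              kink_angle = 40) {
  stopifnot(kink_residue > 1, kink_residue < n_res)
  model <- make_helix(n_res)
  if (kink_angle == 0) return(model)
  ax <- helix_axis(model)
  perp <- unit(cross3(ax, c(0, 0, 1)))
  if (!all(is.finite(perp))) perp <- unit(cross3(ax, c(0, 1, 0)))
  a <- model$atoms
  moving <- which(a$resno > kink_residue)
  pivot <- as.numeric(a[a$resno == kink_residue + 1 & a$name == "N",
                        c("x", "y", "z")])
  rot <- rodrigues(perp, kink_angle)
  xyz <- atom_coords(model)
  xyz[moving, ] <- sweep(sweep(xyz[moving, , drop = FALSE], 2, pivot) %*%
                           t(rot), 2, pivot, "+")
  set_atom_coords(model, xyz)
}

scramble_model <- function(model) {
  xyz <- atom_coords(model)
  set_atom_coords(model, xyz[sample.int(nrow(xyz)), , drop = FALSE])
}

#' Sample a noisy ensemble around a set of states
#'
#' Each model is a copy of one state (chosen by weight) with i.i.d.
#' Gaussian per-atom noise; optionally a fraction of models are
#' coordinate-scrambled decoys (for exercising the geometry filter).
#' Deterministic for a given seed.
#'
#' @param states list of topology-identical `structure_model`s.
#' @param weights state probabilities (sum to 1).
#' @param n number of models.
#' @param noise_sigma per-coordinate noise, Angstrom.
#' @param seed RNG seed.
#' @param decoy_fraction probability a model is scrambled (default 0).
#' @param state_names labels (default "A", "B", ...).
#' @return list with `ensemble` (an `ensemble` with source labels) and
#'   `labels` (state name per model; decoys labelled `"decoy"`).
#' @export
sample_ensemble <- function(states, weights, n, noise_sigma, seed = 1,
                            decoy_fraction = 0,
                            state_names = LETTERS[seq_along(states)]) {
  stopifnot(abs(sum(weights) - 1) < 1e-9,
            length(weights) == length(states))
  set.seed(seed)
  labels <- character(n)
  models <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sample.int(length(states), 1, prob = weights)
    m <- states[[s]]
    xyz <- atom_coords(m)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sigma),
                        ncol = 3)
    m <- set_atom_coords(m, xyz)
    if (decoy_fraction > 0 && stats::runif(1) < decoy_fraction) {
      m <- scramble_model(m)
      labels[i] <- "decoy"
    } else {
      labels[i] <- state_names[s]
    }
    models[[i]] <- m
  }
  ens <- ensemble(models,
                  source_labels = sprintf("model_%03d_%s", seq_len(n),
                                          labels))
  list(ensemble = ens, labels = labels)
}

#' Assemble the full synthetic two-state system
#'
#' Known state = straight helix; target state = kinked helix; target map
#' simulated from the target state (with an optional Gaussian blur as
#' used before fitting); ensemble sampled around both states. Everything
#' is seeded and reproducible.
#'
#' @param config a `toy_system_config`.
#' @return object of class `synthetic_system` with fields `known_model`,
#'   `target_model`, `target_map` (pre-blur), `target_map_blur`,
#'   `ensemble`, `generating_labels`, `config`.
#' @export
make_toy_system <- function(config = toy_system_config()) {
  known <- make_helix(config$n_res)
  target <- make_kinked_helix(config$n_res, config$kink_residue,
                              config$kink_angle)
  spread <- spread_config(sigma = config$map_sigma)
  target_map <- simulate_map(target, config$map_voxel, spread)
  target_map_blur <- gaussian_blur(target_map, config$blur_sigma)
  samp <- sample_ensemble(
    list(known, target),
    weights = c(1 - config$state_b_fraction, config$state_b_fraction),
    n = config$ensemble_size, noise_sigma = config$noise_sigma,
    seed = config$seed, decoy_fraction = config$decoy_fraction)
  structure(list(known_model = known, target_model = target,
                 target_map = target_map,
                 target_map_blur = target_map_blur,
                 ensemble = samp$ensemble,
                 generating_labels = samp$labels, config = config),
            class = "synthetic_system")
}

#' @export
print.synthetic_system <- function(x, ...) {
  cat(sprintf("<synthetic_system> %d res, %d models (%s), map %s voxels\n",
              x$config$n_res, length(x$ensemble),
              paste(names(table(x$generating_labels)),
                    table(x$generating_labels), collapse = " ",
                    sep = ":"),
              paste(dim(x$target_map$grid), collapse = "x")))
  invisible(x)
}

#' Write a synthetic system to a directory
#'
#' Writes known.pdb, target.pdb, target.mrc, target_blur.mrc,
#' ensemble.pdb (multi-model), labels.csv and config.yaml.
#'
#' @param system a `synthetic_system`.
#' @param dir output directory (created if needed).
#' @export
write_toy_system <- function(system, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_structure(system$known_model, file.path(dir, "known.pdb"))
  write_structure(system$target_model, file.path(dir, "target.pdb"))
  write_map(system$target_map, file.path(dir, "target.mrc"))
  write_map(system$target_map_blur, file.path(dir, "target_blur.mrc"))
  write_ensemble(system$ensemble, file.path(dir, "ensemble.pdb"))
  utils::write.csv(data.frame(model = seq_along(system$ensemble),
                              label = system$generating_labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(system$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
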