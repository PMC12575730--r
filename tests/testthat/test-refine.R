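test_that("build_restraints encodes standard connectivity", {
  h2 <- make_helix(2)
  rt <- build_restraints(h2)
  # exactly one peptide bond C(1)-N(2)
  nm <- h2$atoms$name
  rn <- h2$atoms$resno
  pep <- (nm[rt$bonds$i] == "C" & nm[rt$bonds$j] == "N" &
            rn[rt$bonds$j] - rn[rt$bonds$i] == 1) |
    (nm[rt$bonds$j] == "C" & nm[rt$bonds$i] == "N" &
       rn[rt$bonds$i] - rn[rt$bonds$j] == 1)
  expect_equal(sum(pep), 1)
  # enumeration oracle for poly-ALA n = 5:
  # per residue N-CA, CA-C, C-O, CA-CB = 4 bonds, plus n-1 peptide bonds
  rt5 <- build_restraints(make_helix(5))
  expect_equal(nrow(rt5$bonds), 5 * 4 + 4)
  expect_true(all(rt5$bonds$ref > 0.8 & rt5$bonds$ref < 2.2))
  # single glycine-like residue: no inter-residue bonds
  g <- read_structure(write_ala_gly())
  single <- structure_model(g$atoms[g$atoms$resno == 2, ])
  rt1 <- build_restraints(single)
  expect_equal(nrow(rt1$bonds), 3)  # N-CA, CA-C, C-O
})

test_that("density_bias_force follows the map gradient", {
  m <- two_atom_model(60)
  single <- structure_model(m$atoms[1, , drop = FALSE], validate = FALSE)
  # pad 10.5 puts the atom (and blob peak) at the centre of a grid cell
  blob <- simulate_map(single, 1, spread_config(2, cutoff = 8), pad = 10.5)
  # atom at the blob peak: symmetric, near-zero force
  f0 <- density_bias_force(single, blob, k = 10)
  expect_lt(max(abs(f0)), 1e-6 * 10)
  # atom on the +x flank is pushed in -x (up the gradient toward the peak)
  flank <- single
  flank$atoms$x <- 2.5
  f1 <- density_bias_force(flank, blob, k = 10)
  expect_lt(f1[1, 1], 0)
  # finite-difference oracle on the interpolated value
  p <- c(1.3, 0.4, -0.7)
  probe <- single
  probe$atoms$x <- p[1]; probe$atoms$y <- p[2]; probe$atoms$z <- p[3]
  f <- density_bias_force(probe, blob, k = 3)
  eps <- 1e-5
  for (d in 1:3) {
    hi <- lo <- p
    hi[d] <- hi[d] + eps; lo[d] <- lo[d] - eps
    fd <- 3 * (value_and_gradient(blob, hi)$value -
                 value_and_gradient(blob, lo)$value) / (2 * eps)
    expect_equal(f[1, d], fd, tolerance = 1e-4)
  }
})

test_that("refining a model into its own map is a fixed point", {
  m <- make_kinked_helix(20, 10, 40)
  sp <- spread_config(1.5)
  target <- gaussian_blur(simulate_map(m, 1, sp), 1)
  cc_initial <- suppressWarnings(model_map_cc(m, target, sp))
  res <- refine_model(m, target, config = refine_config(max_steps = 600),
                      spread = sp)
  final <- res$trajectory$frames[[length(res$trajectory$frames)]]
  expect_lt(ca_rmsd(final, m, align = FALSE), 0.3)
  ser <- suppressWarnings(score_trajectory(res, target, sp))
  expect_gte(mean(ser$cc), cc_initial - 0.01)
})

test_that("state A refines toward a state-B map", {
  h <- make_helix(30)
  kk <- make_kinked_helix(30, 15, 40)
  sp <- spread_config(1.5)
  target <- gaussian_blur(simulate_map(kk, 1, sp), 1)
  fit <- rigid_body_fit(h, target, fit_config(n_starts = 3, seed = 2,
                                              spread = sp))
  rmsd0 <- ca_rmsd(fit$model, kk, align = FALSE)
  cc0 <- suppressWarnings(model_map_cc(fit$model, target, sp))
  res <- refine_model(fit$model, target, config = refine_config(),
                      spread = sp)
  final <- res$trajectory$frames[[length(res$trajectory$frames)]]
  expect_lt(ca_rmsd(final, kk, align = FALSE), rmsd0)
  expect_gt(suppressWarnings(model_map_cc(final, target, sp)), cc0)
})

test_that("zero bias with no growth is pure restraint relaxation", {
  m <- make_helix(15)
  sp <- spread_config(1.5)
  target <- simulate_map(m, 1, sp)
  cc0 <- model_map_cc(m, target, sp)
  res <- refine_model(m, target,
                      config = refine_config(k_density = 0,
                                             adaptive_growth = 1,
                                             max_steps = 400),
                      spread = sp)
  final <- res$trajectory$frames[[length(res$trajectory$frames)]]
  expect_lt(ca_rmsd(final, m, align = FALSE), 0.1)
  expect_equal(suppressWarnings(model_map_cc(final, target, sp)), cc0,
               tolerance = 0.01)
})

test_that("refinement is deterministic and logs a monotone force scale", {
  m <- make_kinked_helix(12, 6, 30)
  sp <- spread_config(1.5)
  target <- simulate_map(m, 1, sp)
  pert <- m
  pert$atoms$x <- pert$atoms$x + 0.5
  cfg <- refine_config(max_steps = 300, frame_stride = 20)
  r1 <- refine_model(pert, target, config = cfg, spread = sp)
  r2 <- refine_model(pert, target, config = cfg, spread = sp)
  expect_identical(lapply(r1$trajectory$frames, ensemblefit:::atom_coords),
                   lapply(r2$trajectory$frames, ensemblefit:::atom_coords))
  expect_identical(r1$log, r2$log)
  expect_true(all(diff(r1$log$k) >= 0))
  expect_true(r1$termination %in% c("max_steps", "displacement_limit"))
})

test_that("restraint energy never increases during bias-free descent", {
  set.seed(8)
  m <- make_helix(10)
  noisy <- m
  noisy$atoms$x <- noisy$atoms$x + rnorm(nrow(noisy$atoms), sd = 0.1)
  rt <- build_restraints(noisy)
  xyz <- ensemblefit:::atom_coords(noisy)
  e_prev <- ensemblefit:::restraint_energy(xyz, rt, 2000, 200, 100)
  for (i in 1:100) {
    f <- ensemblefit:::restraint_forces(xyz, rt, 2000, 200, 100)
    xyz <- xyz + 2e-5 * f
    e <- ensemblefit:::restraint_energy(xyz, rt, 2000, 200, 100)
    expect_lte(e, e_prev + 1e-9)
    e_prev <- e
  }
})

test_that("restraint forces are the negative gradient of the energy", {
  set.seed(14)
  m <- make_helix(4)
  xyz <- ensemblefit:::atom_coords(m) +
    matrix(rnorm(nrow(ensemblefit:::atom_coords(m)) * 3, sd = 0.05),
           ncol = 3)
  rt <- build_restraints(m)
  f <- ensemblefit:::restraint_forces(xyz, rt, 100, 50, 20)
  eps <- 1e-6
  for (pick in list(c(3, 1), c(7, 2), c(12, 3))) {
    hi <- lo <- xyz
    hi[pick[1], pick[2]] <- hi[pick[1], pick[2]] + eps
    lo[pick[1], pick[2]] <- lo[pick[1], pick[2]] - eps
    fd <- -(ensemblefit:::restraint_energy(hi, rt, 100, 50, 20) -
              ensemblefit:::restraint_energy(lo, rt, 100, 50, 20)) /
      (2 * eps)
    expect_equal(f[pick[1], pick[2]], fd, tolerance = 1e-3)
  }
})

test_that("score_trajectory matches op-by-op recomputation", {
  m <- make_helix(8)
  sp <- spread_config(1.5)
  target <- simulate_map(m, 1, sp)
  frames <- lapply(c(0, 0.3, 0.6), function(dx) {
    f <- m; f$atoms$x <- f$atoms$x + dx; f
  })
  tr <- trajectory(frames)
  ser <- suppressWarnings(score_trajectory(tr, target, sp,
                                           trajectory_id = "t"))
  expect_length(ser$cc, 3)
  for (i in 1:3) {
    expect_equal(ser$cc[i],
                 suppressWarnings(model_map_cc(frames[[i]], target, sp)),
                 tolerance = 1e-12)
    expect_equal(ser$geometry_scaled[i],
                 fallback_geometry_score(frames[[i]])$scaled,
                 tolerance = 1e-12)
  }
  one <- score_trajectory(trajectory(frames[1]), target, sp)
  expect_length(one$cc, 1)
  const <- suppressWarnings(
    score_trajectory(trajectory(frames[c(1, 1, 1)][1:3]), target, sp))
  expect_equal(length(unique(round(const$cc, 12))), 1)
})
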