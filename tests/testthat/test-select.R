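test_that("min_max_normalize maps to [0,1] with the degenerate rule", {
  expect_equal(min_max_normalize(c(0.2, 0.5, 0.8)), c(0, 0.5, 1))
  expect_warning(z <- min_max_normalize(c(7, 7, 7)), "constant")
  expect_equal(z, c(0, 0, 0))
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(sample(2:20, 1))
    nx <- min_max_normalize(x)
    expect_equal(range(nx), c(0, 1))
  }
  expect_error(min_max_normalize(numeric(0)), "empty")
})

test_that("compound scores combine normalised cc and geometry magnitude", {
  s <- score_series(1:2, cc = c(0.2, 0.8),
                    geometry_scaled = c(-90, -100), "t1")
  expect_equal(compound_scores(s), c(0, 2))
  expect_equal(select_frame(s), 2L)
  s2 <- score_series(1:2, cc = c(0.8, 0.2),
                     geometry_scaled = c(-100, -90), "t2")
  expect_equal(compound_scores(s2), c(2, 0))
  # positive geometry scores must fail loudly
  bad <- score_series(1:2, cc = c(0.1, 0.2),
                      geometry_scaled = c(-5, 5), "t3")
  expect_error(compound_scores(bad), "negative")
})

test_that("global normalisation pools extrema across trajectories", {
  a <- score_series(1:3, cc = c(0.1, 0.5, 0.9),
                    geometry_scaled = c(-80, -90, -100), "a")
  b <- score_series(1:3, cc = c(0.1, 0.3, 0.9),
                    geometry_scaled = c(-80, -85, -100), "b")
  # both trajectories attain the pooled extrema, so global == per-trajectory
  expect_equal(compound_scores(a, list(a, b), "global"),
               compound_scores(a, mode = "per_trajectory"))
  # a trajectory not attaining the pooled extrema differs
  c_ <- score_series(1:3, cc = c(0.2, 0.4, 0.6),
                     geometry_scaled = c(-85, -90, -95), "c")
  glob <- compound_scores(c_, list(a, b, c_), "global")
  per <- compound_scores(c_, mode = "per_trajectory")
  expect_false(isTRUE(all.equal(glob, per)))
  expect_true(all(glob >= 0 & glob <= 2))
})

test_that("compound scores stay in [0,2]; 2 only at both extrema", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(2:15, 1)
    s <- score_series(seq_len(n), cc = runif(n, -1, 1),
                      geometry_scaled = -runif(n, 50, 150), "x")
    comp <- suppressWarnings(compound_scores(s))
    expect_true(all(comp >= -1e-12 & comp <= 2 + 1e-12))
    at_two <- which(abs(comp - 2) < 1e-12)
    for (f in at_two) {
      expect_equal(s$cc[f], max(s$cc))
      expect_equal(abs(s$geometry_scaled[f]), max(abs(s$geometry_scaled)))
    }
  }
})

test_that("trajectory selection takes the highest mean cc, ties by label", {
  mk <- function(ccs, id) score_series(seq_along(ccs), ccs,
                                       rep(-100, length(ccs)), id)
  expect_equal(select_trajectory(list(mk(0.4, "a"), mk(0.7, "b"),
                                      mk(0.5, "c"))), "b")
  expect_equal(select_trajectory(list(mk(0.3, "only"))), "only")
  expect_equal(select_trajectory(list(mk(0.5, "z"), mk(0.5, "a"))), "a")
})

test_that("frame selection ties break to the earliest frame", {
  s <- score_series(c(4L, 9L, 12L), cc = c(0.1, 0.9, 0.9),
                    geometry_scaled = c(-90, -100, -100), "t")
  expect_equal(select_frame(s), 9L)
  mono <- score_series(1:4, cc = c(0.1, 0.2, 0.3, 0.4),
                       geometry_scaled = c(-90, -95, -99, -100), "t")
  expect_equal(select_frame(mono), 4L)
})

test_that("selection equals a brute-force recomputation oracle", {
  set.seed(91)
  for (rep in 1:50) {
    n_traj <- sample(1:5, 1)
    series <- lapply(seq_len(n_traj), function(t) {
      n <- sample(2:10, 1)
      score_series(seq_len(n), cc = runif(n, 0, 1),
                   geometry_scaled = -runif(n, 80, 120),
                   sprintf("t%02d", t))
    })
    sel <- select_final(series)
    # oracle: independent argmax recomputation
    means <- vapply(series, function(s) mean(s$cc), 0)
    labs <- vapply(series, `[[`, "", "trajectory_id")
    best_lab <- sort(labs[means == max(means)])[1]
    chosen <- series[[which(labs == best_lab)]]
    ncc <- (chosen$cc - min(chosen$cc)) /
      max(max(chosen$cc) - min(chosen$cc), .Machine$double.xmin)
    g <- abs(chosen$geometry_scaled)
    ng <- (g - min(g)) / max(max(g) - min(g), .Machine$double.xmin)
    expect_equal(sel$chosen_trajectory, best_lab)
    expect_equal(sel$chosen_frame,
                 chosen$frame_indices[which.max(ncc + ng)])
  }
})

test_that("full selection is invariant to trajectory list order", {
  set.seed(6)
  series <- lapply(1:4, function(t) {
    n <- 6
    score_series(seq_len(n), cc = runif(n), -runif(n, 90, 110),
                 sprintf("t%d", t))
  })
  ref <- select_final(series)
  for (i in 1:5) {
    perm <- sample(4)
    sel <- select_final(series[perm])
    expect_equal(sel$chosen_trajectory, ref$chosen_trajectory)
    expect_equal(sel$chosen_frame, ref$chosen_frame)
  }
  # per-trajectory and global agree with a single trajectory
  one <- series[[1]]
  expect_equal(select_frame(one, list(one), "global"),
               select_frame(one, mode = "per_trajectory"))
})
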