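test_that("superpose recovers exact rigid transforms", {
  ca <- ca_coordinates(make_helix(10))
  s <- superpose(ca, ca)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  expect_equal(s$transform$rotation, diag(3), tolerance = 1e-9)
  rot90 <- rodrigues_test(c(0, 0, 1), 90)
  moved <- sweep(ca %*% t(rot90), 2, c(5, 0, 0), "+")
  s2 <- superpose(moved, ca)
  expect_equal(s2$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_transform(s2$transform, moved), ca,
               tolerance = 1e-9)
  expect_error(superpose(ca[1:2, ], ca[1:2, ]), ">= 3")
  collinear <- cbind(1:5, 0, 0)
  expect_error(superpose(collinear * 1.0, collinear * 1.0), "degenerate")
})

test_that("superpose matches the quaternion-method oracle on noisy pairs", {
  set.seed(17)
  ca <- ca_coordinates(make_helix(20))
  for (i in 1:5) {
    noisy <- apply_transform(random_rigid_transform(),
                             ca + matrix(rnorm(length(ca), sd = 0.1),
                                         ncol = 3))
    expect_equal(superpose(noisy, ca)$rmsd,
                 quaternion_rmsd_oracle(noisy, ca), tolerance = 1e-6)
  }
})

test_that("align_ensemble collapses rigid-transformed copies", {
  ref <- make_helix(12)
  set.seed(23)
  ens <- ensemble(lapply(1:6, function(i)
    apply_transform(random_rigid_transform(), ref)))
  stack <- align_ensemble(ens, ref)
  expect_equal(dim(stack), c(6, 12, 3))
  for (i in 2:6)
    expect_equal(stack[i, , ], stack[1, , ], tolerance = 1e-6)
  # single-model ensemble
  one <- align_ensemble(ensemble(list(ref)), ref)
  expect_equal(dim(one), c(1, 12, 3))
  # alignment never changes internal distances
  d_before <- internal_distance_rmsd_matrix(ens)
  aligned_models <- lapply(seq_len(6), function(i) {
    m <- ens$models[[i]]
    ca <- ca_coordinates(m)
    tr <- superpose(ca, ca_coordinates(ref))$transform
    apply_transform(tr, m)
  })
  d_after <- internal_distance_rmsd_matrix(ensemble(aligned_models))
  expect_equal(d_after, d_before, tolerance = 1e-9)
})

test_that("k-means recovers two well-separated blobs", {
  set.seed(9)
  n <- 50
  base <- ca_coordinates(make_helix(8))
  truth <- rep(1:2, each = n)
  stack <- array(0, c(2 * n, 8, 3))
  for (i in seq_len(2 * n)) {
    off <- if (truth[i] == 1) 0 else 100
    stack[i, , ] <- base + matrix(rnorm(24, sd = 0.1), ncol = 3) + off
  }
  cl <- kmeans_cluster(stack, k = 2, seed = 4)
  expect_equal(rand_index(cl$labels, truth), 1.0)
  # oracle: nearest generating centre gives the same partition
  expect_true(all(table(cl$labels, truth) %in% c(0, n)))
  # representatives belong to their cluster
  expect_equal(cl$labels[cl$representative_indices], 1:2)
})

test_that("k-means degenerate cases: k = 1 and k = n", {
  set.seed(2)
  stack <- array(rnorm(10 * 5 * 3), c(10, 5, 3))
  c1 <- kmeans_cluster(stack, k = 1, seed = 1)
  expect_equal(unique(c1$labels), 1L)
  x <- matrix(stack, nrow = 10)
  d2 <- colSums((t(x) - colMeans(x))^2)
  expect_equal(c1$representative_indices, which.min(d2))
  cn <- kmeans_cluster(stack, k = 10, seed = 1)
  expect_equal(sort(cn$representative_indices), 1:10)
  expect_error(kmeans_cluster(stack, k = 11, seed = 1), "exceeds")
})

test_that("k-means is reproducible and at least as tight as the truth", {
  set.seed(13)
  stack <- array(0, c(40, 6, 3))
  truth <- rep(1:2, each = 20)
  for (i in 1:40)
    stack[i, , ] <- matrix(rnorm(18, sd = 0.5), ncol = 3) +
      (truth[i] - 1) * 20
  a <- kmeans_cluster(stack, k = 2, seed = 7)
  b <- kmeans_cluster(stack, k = 2, seed = 7)
  expect_identical(a$labels, b$labels)
  expect_identical(a$representative_indices, b$representative_indices)
  # within-cluster SS of the fit <= that of the generating assignment
  x <- matrix(stack, nrow = 40)
  wss <- function(lab) sum(vapply(unique(lab), function(c) {
    xc <- x[lab == c, , drop = FALSE]
    sum(sweep(xc, 2, colMeans(xc))^2)
  }, 0))
  expect_lte(wss(a$labels), wss(truth) + 1e-9)
})

test_that("dRMSD matrix: hand example, symmetry, rigid invariance", {
  # 3-residue toy: gaps 3.8/3.8 vs 3.8/4.8, end-to-end 7.6 vs 8.6
  mk3 <- function(x2, x3) structure_model(data.frame(
    element = "C", name = "CA", resno = 1:3, resname = "ALA",
    chain = "A", insert = "", x = c(0, x2, x3), y = 0.001 * (0:2)^2,
    z = 0, stringsAsFactors = FALSE))
  a <- mk3(3.8, 7.6)
  b <- mk3(3.8, 8.6)
  # overwrite the tiny y-bend: use exact collinear coordinates
  a$atoms$y <- 0; b$atoms$y <- 0
  dm <- internal_distance_rmsd_matrix(ensemble(list(a, b)))
  expect_equal(dm[1, 2], sqrt((0^2 + 1^2 + 1^2) / 3), tolerance = 1e-9)
  expect_equal(dm[2, 1], dm[1, 2])
  expect_equal(diag(dm), c(0, 0))
  # identical models give the zero matrix
  z <- internal_distance_rmsd_matrix(ensemble(list(a, a, a)))
  expect_equal(max(abs(z)), 0)
  # a rigid transform of a model leaves all entries unchanged
  set.seed(3)
  ens1 <- ensemble(lapply(1:4, function(i) {
    m <- make_helix(10)
    m$atoms$x <- m$atoms$x + rnorm(nrow(m$atoms), sd = 0.3)
    m
  }))
  d1 <- internal_distance_rmsd_matrix(ens1)
  ens2 <- ensemble(lapply(ens1$models, function(m)
    apply_transform(random_rigid_transform(), m)))
  d2 <- internal_distance_rmsd_matrix(ens2)
  expect_equal(d2, d1, tolerance = 1e-9)
})

test_that("k-medoids recovers block structure and matches the exhaustive oracle", {
  set.seed(6)
  n1 <- 5; n2 <- 6; n <- n1 + n2
  truth <- rep(1:2, c(n1, n2))
  dm <- matrix(runif(n * n, 8, 10), n, n)
  within <- outer(truth, truth, "==")
  dm[within] <- runif(sum(within), 0.1, 1)
  dm <- (dm + t(dm)) / 2
  diag(dm) <- 0
  cl <- kmedoids_cluster(dm, k = 2, seed = 1)
  expect_equal(rand_index(cl$labels, truth), 1.0)
  # exhaustive medoid-pair oracle
  best <- Inf; best_pair <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cost <- sum(pmin(dm[, i], dm[, j]))
    if (cost < best) { best <- cost; best_pair <- c(i, j) }
  }
  expect_setequal(cl$representative_indices, best_pair)
  cost_fit <- sum(dm[cbind(seq_len(n),
                           cl$representative_indices[cl$labels])])
  expect_equal(cost_fit, best, tolerance = 1e-12)
})

test_that("k-medoids degenerate and validation cases", {
  dm <- matrix(0, 4, 4)
  c1 <- kmedoids_cluster(dm, k = 1, seed = 1)
  expect_equal(length(unique(c1$labels)), 1)
  set.seed(1)
  d <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  cn <- kmedoids_cluster(d, k = 6, seed = 1)
  expect_setequal(cn$representative_indices, 1:6)
  bad <- d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(kmedoids_cluster(bad, k = 2, seed = 1), "symmetric")
  neg <- d; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(kmedoids_cluster(neg, k = 2, seed = 1), "negative")
})
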