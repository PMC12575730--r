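#' Rigid transform (proper rotation + translation)
#'
#' Applied to row-vector coordinates as `x %*% t(rotation) + translation`.
#'
#' @param rotation 3x3 proper rotation matrix (orthogonal, det +1).
#' @param translation length-3 numeric, Angstrom.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be a proper rotation matrix")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates or a model
#' @param transform a `rigid_transform`.
#' @param x n x 3 coordinate matrix or a `structure_model`.
#' @return transformed object of the same kind.
#' @export
apply_transform <- function(transform, x) {
  if (inherits(x, "structure_model"))
    return(set_atom_coords(x, apply_transform(transform, atom_coords(x))))
  sweep(x %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose two rigid transforms (first `b`, then `a`)
#' @param a,b `rigid_transform`s.
#' @return a `rigid_transform` equal to `a(b(x))`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' `mobile` and `reference` over the selected subset, via SVD of the
#' covariance matrix with the usual determinant sign correction.
#'
#' @param mobile,reference n x 3 coordinate matrices of equal shape.
#' @param subset indices used to compute the fit (default all rows);
#'   needs >= 3 non-degenerate points.
#' @return list with `transform` (a `rigid_transform`) and `rmsd`
#'   (Angstrom, evaluated over the subset after transforming).
#' @export
superpose <- function(mobile, reference, subset = NULL) {
  stopifnot(identical(dim(mobile), dim(reference)))
  if (is.null(subset)) subset <- seq_len(nrow(mobile))
  if (length(subset) < 3) stop("need >= 3 points to superpose")
  m <- mobile[subset, , drop = FALSE]
  r <- reference[subset, , drop = FALSE]
  cm <- colMeans(m)
  cr <- colMeans(r)
  h <- crossprod(sweep(m, 2, cm), sweep(r, 2, cr))
  sv <- svd(h)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("degenerate geometry: points are (nearly) collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rigid_transform(rot, cr - as.numeric(rot %*% cm))
  moved <- apply_transform(tr, m)
  list(transform = tr, rmsd = sqrt(mean(rowSums((moved - r)^2))))
}

#' Superpose every ensemble member onto a reference model
#'
#' Each model's C-alpha coordinates are Kabsch-superposed onto the
#' reference C-alphas (the "known state" in the standard pipeline); the
#' aligned coordinates are returned as a stack for Cartesian clustering.
#'
#' @param ens an `ensemble`.
#' @param reference a `structure_model` with the same C-alpha count.
#' @return numeric array n_models x n_residues x 3 of aligned C-alpha
#'   coordinates.
#' @export
align_ensemble <- function(ens, reference) {
  ref_ca <- ca_coordinates(reference)
  n_res <- nrow(ref_ca)
  out <- array(0, c(length(ens), n_res, 3))
  for (i in seq_along(ens$models)) {
    ca <- ca_coordinates(ens$models[[i]])
    if (nrow(ca) != n_res)
      stop("topology mismatch: model ", i, " has ", nrow(ca),
           " residues, reference has ", n_res)
    out[i, , ] <- apply_transform(superpose(ca, ref_ca)$transform, ca)
  }
  out
}

#' Clustering result
#' @param labels integer cluster label per model, in 1..k.
#' @param representative_indices model index of each cluster's
#'   representative (length k).
#' @param method `"kmeans_cartesian"` or `"kmedoids_drmsd"`.
#' @param seed RNG seed used.
#' @return object of class `cluster_result`.
#' @export
cluster_result <- function(labels, representative_indices, method, seed) {
  k <- length(representative_indices)
  if (!setequal(unique(labels), seq_len(k)))
    stop("every cluster in 1..k must be non-empty")
  if (any(labels[representative_indices] != seq_len(k)))
    stop("representative must belong to its own cluster")
  structure(list(labels = as.integer(labels), k = k,
                 representative_indices = as.integer(representative_indices),
                 method = method, seed = seed),
            class = "cluster_result")
}

# seeded k-means++ initial centres (stats::kmeans has no ++ initialiser)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[centers[1], ], "-")^2)
  if (k > 1) for (c in 2:k) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0)
      centers[c] <- sample.int(n, 1)
    else centers[c] <- sample.int(n, 1, prob = p)
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[c], ], "-")^2))
  }
  x[centers, , drop = FALSE]
}

#' k-means clustering of superposed C-alpha coordinates
#'
#' Lloyd iterations (via `stats::kmeans`) on flattened aligned C-alpha
#' Cartesian vectors, with seeded k-means++ initialisation and multiple
#' restarts (best inertia kept). Representatives are the models nearest
#' each centroid in Euclidean norm, ties broken by lowest model index.
#'
#' @param aligned n_models x n_residues x 3 array from [align_ensemble()].
#' @param k number of clusters (default 20).
#' @param seed RNG seed (clustering is deterministic given the seed).
#' @param n_restarts independent k-means++ restarts (default 10).
#' @return a `cluster_result`.
#' @export
kmeans_cluster <- function(aligned, k = 20, seed = 1, n_restarts = 10) {
  n <- dim(aligned)[1]
  if (k > n) stop("k = ", k, " exceeds number of models ", n)
  x <- matrix(aligned, nrow = n)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_centers(x, k)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = 300,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  reps <- vapply(seq_len(k), function(c) {
    members <- which(best$cluster == c)
    d2 <- colSums((t(x[members, , drop = FALSE]) - best$centers[c, ])^2)
    members[which.min(d2)]  # which.min takes the first (lowest index) tie
  }, 0L)
  cluster_result(best$cluster, reps, "kmeans_cartesian", seed)
}

#' Pairwise internal-distance RMSD (dRMSD) matrix
#'
#' Entry (i, j) is the RMS difference between the C-alpha/C-alpha internal
#' distances of models i and j over all unordered residue pairs. The
#' matrix is symmetric with zero diagonal and every entry is invariant
#' under rigid motion of either model, so no prior alignment (and no known
#' reference state) is needed.
#'
#' @param ens an `ensemble` with >= 2 residues per model.
#' @return symmetric n x n numeric matrix, Angstrom.
#' @export
internal_distance_rmsd_matrix <- function(ens) {
  n <- length(ens)
  dists <- t(vapply(ens$models,
                    function(m) as.numeric(stats::dist(ca_coordinates(m))),
                    numeric(length(stats::dist(ca_coordinates(ens$models[[1]]))))))
  npair <- ncol(dists)
  if (npair < 1) stop("need >= 2 residues for internal distances")
  dm <- as.matrix(stats::dist(dists)) / sqrt(npair)
  dimnames(dm) <- NULL
  dm
}

#' k-medoids clustering of a dissimilarity matrix
#'
#' PAM (build + swap) via `cluster::pam` on an arbitrary dissimilarity
#' matrix, typically the dRMSD matrix. Representatives are the medoids
#' themselves. PAM's build/swap phases are deterministic; the seed is
#' recorded for provenance.
#'
#' @param dmat square symmetric non-negative matrix with zero diagonal.
#' @param k number of clusters.
#' @param seed RNG seed (recorded; PAM itself is deterministic).
#' @return a `cluster_result`.
#' @export
kmedoids_cluster <- function(dmat, k, seed = 1) {
  if (!is.matrix(dmat) || nrow(dmat) != ncol(dmat))
    stop("dissimilarity matrix must be square")
  if (max(abs(dmat - t(dmat))) > 1e-8)
    stop("validation error: dissimilarity matrix is not symmetric")
  if (any(dmat < 0)) stop("validation error: negative dissimilarities")
  if (any(abs(diag(dmat)) > 1e-12))
    stop("validation error: nonzero diagonal")
  if (k > nrow(dmat)) stop("k exceeds number of models")
  if (k == nrow(dmat))  # every point its own medoid, total cost 0
    return(cluster_result(seq_len(k), seq_len(k), "kmedoids_drmsd", seed))
  set.seed(seed)
  fit <- cluster::pam(stats::as.dist(dmat), k = k, diss = TRUE,
                      nstart = 1, variant = "original")
  labels <- as.integer(fit$clustering)
  cluster_result(labels, as.integer(fit$id.med), "kmedoids_drmsd", seed)
}
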