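# shared fixtures, built in code at test time

# hand-written 2-residue ALA-GLY PDB (9 heavy atoms)
ala_gly_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.792   5.170  -4.246  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      10.960   5.160  -3.022  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      13.080   5.558  -5.199  1.00  0.00           C",
    "ATOM      6  N   GLY A   2       9.897   4.408  -4.866  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       9.003   3.503  -4.148  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       7.564   3.987  -4.206  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       7.294   5.151  -4.503  1.00  0.00           O",
    "END")
}

write_ala_gly <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(ala_gly_pdb_lines(), path)
  path
}

# minimal two-residue model built directly (for ca/clash toys)
two_atom_model <- function(d, element = "C") {
  structure_model(data.frame(
    element = element, name = "CA", resno = 1:2, resname = "ALA",
    chain = "A", insert = "", x = c(0, d), y = 0, z = 0,
    stringsAsFactors = FALSE))
}

random_rigid_transform <- function() {
  ax <- stats::rnorm(3)
  rigid_transform(rodrigues_test(ax, stats::runif(1, 5, 170)),
                  stats::rnorm(3, sd = 10))
}

rodrigues_test <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + sin(a) * ux + (1 - cos(a)) * (ux %*% ux)
}

# independent quaternion-method superposition oracle (Horn 1987):
# returns the minimal RMSD of mobile onto reference
quaternion_rmsd_oracle <- function(mobile, reference) {
  m <- sweep(mobile, 2, colMeans(mobile))
  r <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(m, r)
  key <- function(i, j) S[i, j]
  K <- matrix(0, 4, 4)
  K[1, 1] <- key(1, 1) + key(2, 2) + key(3, 3)
  K[1, 2] <- K[2, 1] <- key(2, 3) - key(3, 2)
  K[1, 3] <- K[3, 1] <- key(3, 1) - key(1, 3)
  K[1, 4] <- K[4, 1] <- key(1, 2) - key(2, 1)
  K[2, 2] <- key(1, 1) - key(2, 2) - key(3, 3)
  K[2, 3] <- K[3, 2] <- key(1, 2) + key(2, 1)
  K[2, 4] <- K[4, 2] <- key(1, 3) + key(3, 1)
  K[3, 3] <- -key(1, 1) + key(2, 2) - key(3, 3)
  K[3, 4] <- K[4, 3] <- key(2, 3) + key(3, 2)
  K[4, 4] <- -key(1, 1) - key(2, 2) + key(3, 3)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  ssq <- sum(m^2) + sum(r^2) - 2 * lam
  sqrt(max(0, ssq) / nrow(mobile))
}

# Rand index between two labelings
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}
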