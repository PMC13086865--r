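# Shared test fixtures and small independent oracles.

# Random rigid transform (unit-quaternion rotation + translation), written
# independently of the package internals for invariance checks.
rigid_transform <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
  t <- rnorm(3, sd = 25)
  function(m) sweep(m %*% t(R), 2, t, "+")
}

# Apply one rigid transform to every structure in a pose ensemble.
transform_ensemble <- function(ensemble, f) {
  ensemble$receptor_xyz <- f(ensemble$receptor_xyz)
  for (m in seq_len(dim(ensemble$poses)[3]))
    ensemble$poses[, , m] <- f(ensemble$poses[, , m])
  ensemble
}

# Apply one rigid transform to every frame of a trajectory.
transform_trajectory <- function(trajectory, f) {
  for (m in seq_len(n_frames(trajectory)))
    trajectory$coords[, , m] <- f(trajectory$coords[, , m])
  trajectory
}

# Pose ensemble with a planted winner geometry: `n_contact` identical poses
# with `contacts` of `length` residues in range, plus `n_far` poses displaced
# far from the receptor. Cluster structure and contact outcome are both known.
make_split_contact_ensemble <- function(n_contact, n_far, length = 28,
                                        contacts = 18, cutoff = 10) {
  base <- make_contact_pose(length, contacts, cutoff)
  n <- n_contact + n_far
  poses <- array(NA_real_, dim = c(length, 3L, n))
  for (i in seq_len(n_contact)) poses[, , i] <- base$poses[, , 1]
  far <- sweep(base$poses[, , 1], 2, c(0, 500, 0), "+")
  for (i in seq_len(n_far)) poses[, , n_contact + i] <- far
  pose_ensemble(base$receptor_atoms, base$receptor_xyz, base$peptide_atoms,
                poses)
}

# Adjusted Rand index between two labelings (closed form on the pair
# contingency table); independent of any clustering package.
ari <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
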