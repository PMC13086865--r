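test_that("pose RMSD matches direct per-atom arithmetic", {
  set.seed(7)
  n_atoms <- 5
  atoms <- data.frame(chain = "P", resno = 1:n_atoms, resid = "GLY",
                      elety = "CA", element = "C")
  rec <- data.frame(chain = "E", resno = 1:3, resid = "GLY",
                    elety = "CA", element = "C")
  poses <- array(rnorm(n_atoms * 3 * 2, sd = 10), dim = c(n_atoms, 3, 2))
  ens <- pose_ensemble(rec, matrix(0, 3, 3), atoms, poses)
  # brute-force oracle: sqrt(mean of squared per-atom displacements)
  by_hand <- sqrt(sum((poses[, , 1] - poses[, , 2])^2) / n_atoms)
  expect_equal(pose_rmsd(ens, 1, 2), by_hand)
  expect_equal(pose_rmsd(ens, 1, 1), 0)
  # a rigid (3,4,0) translation gives exactly 5
  poses[, , 2] <- sweep(poses[, , 1], 2, c(3, 4, 0), "+")
  ens2 <- pose_ensemble(rec, matrix(0, 3, 3), atoms, poses)
  expect_equal(pose_rmsd(ens2, 1, 2), 5)
  # the pairwise matrix agrees with the scalar routine and is symmetric
  m <- pose_rmsd_matrix(ens)
  expect_equal(m[1, 2], by_hand)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(0, 0), ignore_attr = TRUE)
})

test_that("k-medoids bookkeeping sums occupancies and finds planted blobs", {
  blobs <- make_pose_blobs(n_poses = 300, n_clusters = 3, spread_A = 1,
                           separation_A = 40, seed = 5)
  cs <- kmedoids_cluster(blobs$ensemble, k = 3, seed = 1)
  expect_equal(sum(cs$occupancies), 300)
  expect_equal(cs$mean_occupancy, 100)
  expect_equal(ari(cs$labels, blobs$labels), 1)
  # each medoid belongs to its own cluster
  expect_equal(cs$labels[cs$medoids], seq_len(cs$k))
  # k = N: every pose its own cluster at zero cost
  tiny <- make_pose_blobs(n_poses = 8, n_clusters = 2, seed = 2)
  all_k <- kmedoids_cluster(tiny$ensemble, k = 8)
  expect_true(all(all_k$occupancies == 1))
  expect_equal(all_k$cost, 0)
  expect_error(kmedoids_cluster(tiny$ensemble, k = 9), "exceeds")
})

test_that("clustering cost is non-increasing in k", {
  blobs <- make_pose_blobs(n_poses = 120, n_clusters = 4, spread_A = 3,
                           separation_A = 25, seed = 9)
  dmat <- pose_rmsd_matrix(blobs$ensemble)
  costs <- vapply(2:8, function(k)
    kmedoids_cluster(blobs$ensemble, k = k, dist_matrix = dmat)$cost,
    numeric(1))
  expect_true(all(diff(costs) <= 1e-9))
})

test_that("contact analysis reproduces the published fraction arithmetic", {
  rows <- list(c(22, 18, 81.82), c(26, 22, 84.62),
               c(28, 18, 64.29), c(30, 18, 60.00))
  for (r in rows) {
    ens <- make_contact_pose(r[1], r[2])
    rep <- contact_analysis(ens)
    expect_equal(rep$contacts, r[2])
    expect_equal(rep$fraction_pct, r[3])
    expect_true(rep$selected)
  }
  # boundary and degenerate plants
  none <- contact_analysis(make_contact_pose(20, 0))
  expect_equal(none$fraction_pct, 0)
  expect_false(none$selected)
  all_in <- contact_analysis(make_contact_pose(20, 20))
  expect_equal(all_in$fraction_pct, 100)
  # exactly half is NOT selected (strict > 50 %)
  half <- contact_analysis(make_contact_pose(20, 10))
  expect_equal(half$fraction_pct, 50)
  expect_false(half$selected)
})

test_that("contact count is monotone in the cutoff and rigid-invariant", {
  ens <- make_contact_pose(25, 12, cutoff_A = 10)
  cuts <- c(4, 6, 8, 10, 12, 16, 30)
  counts <- vapply(cuts, function(ct)
    contact_analysis(ens, cutoff_A = ct)$contacts, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # fraction invariant when receptor and pose move together
  set.seed(31)
  for (i in 1:5) {
    moved <- transform_ensemble(ens, rigid_transform())
    expect_equal(contact_analysis(moved)$fraction_pct,
                 contact_analysis(ens)$fraction_pct)
  }
})

test_that("selection rules apply strict occupancy and coincidence logic", {
  # planted most-populated cluster that is also lowest energy
  blobs <- make_pose_blobs(n_poses = 100, n_clusters = 4, spread_A = 0.5,
                           separation_A = 40, seed = 13,
                           occupancy_weights = c(4, 1, 1, 1),
                           cluster_energy = c(-10, 0, 0, 0))
  cs <- kmedoids_cluster(blobs$ensemble, k = 4, seed = 1)
  sel <- select_candidates(blobs$ensemble, cs)
  expect_true(sel$coincident)
  expect_true(sel$occupancy_above_mean)
  expect_equal(sel$occupancy, max(cs$occupancies), ignore_attr = TRUE)
  # occupancy exactly N/k fails the strict "above the average" rule
  even <- make_split_contact_ensemble(n_contact = 5, n_far = 5)
  cs2 <- kmedoids_cluster(even, k = 2)
  sel2 <- select_candidates(even, cs2)
  expect_equal(sel2$occupancy, 5)
  expect_false(sel2$occupancy_above_mean)
  expect_true(is.na(sel2$coincident))  # no energies
  # winner geometry: contact-rich cluster dominates
  win <- make_split_contact_ensemble(n_contact = 7, n_far = 3)
  sel3 <- select_candidates(win, kmedoids_cluster(win, k = 2))
  expect_true(sel3$selected && sel3$occupancy_above_mean)
  expect_equal(sel3$fraction_pct, 64.29)
})

test_that("pose ensembles round-trip through multi-model PDB", {
  blobs <- make_pose_blobs(n_poses = 6, n_clusters = 2, peptide_length = 4,
                           seed = 17,
                           cluster_energy = c(-3, 1))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(blobs$ensemble, f)
  back <- read_ensemble_pdb(f, peptide_chain = "P")
  expect_equal(dim(back$poses), dim(blobs$ensemble$poses))
  # PDB fixed-point coordinates carry 3 decimals
  expect_lt(max(abs(back$poses - blobs$ensemble$poses)), 1e-3)
  expect_lt(max(abs(back$receptor_xyz - blobs$ensemble$receptor_xyz)), 1e-3)
  expect_equal(back$peptide_atoms$resno, blobs$ensemble$peptide_atoms$resno)
  expect_equal(back$energies, blobs$ensemble$energies, tolerance = 1e-4)
  # clustering is unchanged across the round trip
  expect_equal(kmedoids_cluster(back, 2)$labels,
               kmedoids_cluster(blobs$ensemble, 2)$labels)
})
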