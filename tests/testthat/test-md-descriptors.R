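make_point_trajectory <- function(coords_list, elements = NULL,
                                  chains = NULL) {
  n <- nrow(coords_list[[1]])
  if (is.null(elements)) elements <- rep("C", n)
  if (is.null(chains)) chains <- rep("A", n)
  atoms <- data.frame(chain = chains, resno = seq_len(n), resid = "GLY",
                      elety = "CA", element = elements)
  arr <- array(NA_real_, dim = c(n, 3, length(coords_list)))
  for (k in seq_along(coords_list)) arr[, , k] <- coords_list[[k]]
  md_trajectory(atoms, arr)
}

test_that("COM distance matches hand-computed centroids", {
  # two single atoms 7 apart
  tr <- make_point_trajectory(list(rbind(c(0, 0, 0), c(7, 0, 0))))
  expect_equal(com_distance(tr, 1, 1, 2), 7)
  expect_equal(com_distance(tr, 1, 1, 1), 0)
  # mass-weighted oracle with mixed elements, arithmetic written out
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(10, 0, 0))
  tr2 <- make_point_trajectory(list(xyz), elements = c("C", "O", "N"))
  com_ab <- (12.011 * xyz[1, ] + 15.999 * xyz[2, ]) / (12.011 + 15.999)
  by_hand <- sqrt(sum((com_ab - xyz[3, ])^2))
  expect_equal(com_distance(tr2, 1, c(1, 2), 3), by_hand)
  # geometric option ignores masses
  expect_equal(com_distance(tr2, 1, c(1, 2), 3, mass_weighted = FALSE),
               10 - 1)
  expect_error(com_distance(tr2, 1, integer(0), 3), "non-empty")
})

test_that("vertex angles hit exact geometric cases and clamp to [0, 180]", {
  tr <- make_point_trajectory(list(rbind(c(-1, 0, 0), c(0, 0, 0),
                                         c(1, 0, 0), c(0, 1, 0))))
  expect_equal(interchain_angle(tr, 1, 1, 2, 3), 180)
  expect_equal(interchain_angle(tr, 1, 3, 2, 4), 90)
  expect_equal(interchain_angle(tr, 1, 3, 2, 3), 0)
  expect_error(interchain_angle(tr, 1, 2, 2, 3), "zero-length")
})

test_that("d and theta are invariant under joint rigid motion to 1e-9", {
  plant <- make_trajectory(data.frame(state = c("bound", "unbound"),
                                      n_frames = c(5, 5),
                                      theta = c(85, 70)))
  tr <- plant$trajectory
  pep <- select_atoms(tr, chain = "P")
  rec <- select_atoms(tr, chain = c("A", "B"))
  set.seed(57)
  for (i in 1:5) {
    moved <- transform_trajectory(tr, rigid_transform())
    for (f in c(1, 6)) {
      expect_lt(abs(com_distance(moved, f, pep, rec) -
                      com_distance(tr, f, pep, rec)) /
                  com_distance(tr, f, pep, rec), 1e-9)
      a <- interchain_angle(moved, f, plant$angle_atoms[1],
                            plant$angle_atoms[2], plant$angle_atoms[3])
      b <- interchain_angle(tr, f, plant$angle_atoms[1],
                            plant$angle_atoms[2], plant$angle_atoms[3])
      expect_lt(abs(a - b), 1e-9)
    }
  }
})

test_that("binding-state classification partitions distances", {
  expect_equal(classify_binding(40), "bound")
  expect_equal(classify_binding(45), "bound")      # boundary inclusive
  expect_equal(classify_binding(47), "intermediate")
  expect_equal(classify_binding(50), "intermediate")
  expect_equal(classify_binding(55), "unbound")
  # every distance maps to exactly one state
  d <- seq(0, 120, by = 0.25)
  states <- classify_binding(d)
  expect_true(all(states %in% c("bound", "intermediate", "unbound")))
  expect_equal(length(states), length(d))
  expect_error(classify_binding(10, bound_max = 60, unbound_min = 50),
               "bound_max")
})

test_that("planted binding-state sequences are recovered exactly", {
  plant <- make_trajectory(data.frame(
    state = c("bound", "intermediate", "unbound", "bound"),
    n_frames = c(12, 5, 9, 4)))
  tr <- plant$trajectory
  tab <- descriptor_table(tr, select_atoms(tr, chain = "P"),
                          select_atoms(tr, chain = c("A", "B")),
                          angle_atoms = plant$angle_atoms)
  expect_identical(tab$state, plant$truth$state)
  expect_equal(tab$d_A, plant$truth$d, tolerance = 1e-9)
  expect_equal(tab$theta_deg, plant$truth$theta, tolerance = 1e-6)
})

test_that("2D density grids conserve the frame count", {
  # single frame lands in a single bin
  g1 <- density_2d(40, 70)
  expect_equal(sum(g1$counts), 1L)
  set.seed(3)
  x <- runif(500, 30, 70); y <- runif(500, 50, 110)
  g <- density_2d(x, y, bins = 151)
  expect_equal(sum(g$counts), 500L)
  expect_equal(dim(g$counts), c(151L, 151L))
  expect_equal(length(g$x_edges), 152L)
  # flatness of a uniform sample on a coarse grid
  gc <- density_2d(x, y, bins = 4)
  p <- stats::chisq.test(as.vector(gc$counts))$p.value
  expect_gt(p, 1e-3)
  expect_error(density_2d(c(1, 2), c(3, 4), xlim = c(5, 5)), "degenerate")
})

test_that("quality-threshold clustering separates planted conformer families", {
  # two families of peptide placements far beyond the cutoff
  plant <- make_trajectory(data.frame(state = c("bound", "unbound"),
                                      n_frames = c(14, 6)))
  tr <- plant$trajectory
  pep <- select_atoms(tr, chain = "P")
  rec <- select_atoms(tr, chain = c("A", "B"))
  cl <- qt_cluster(tr, pep, rmsd_cutoff_A = 5, align_idx = rec)
  expect_length(cl, 2L)
  sizes <- vapply(cl, function(x) length(x$members), numeric(1))
  expect_equal(sizes, c(14, 6))  # non-increasing by construction
  expect_setequal(cl[[1]]$members, 1:14)
  expect_setequal(cl[[2]]$members, 15:20)
  # clusters are disjoint and cover all frames
  all_members <- unlist(lapply(cl, `[[`, "members"))
  expect_setequal(all_members, seq_len(n_frames(tr)))
  expect_equal(anyDuplicated(all_members), 0L)
  # infinite cutoff: one cluster; identical frames: one cluster
  expect_length(qt_cluster(tr, pep, rmsd_cutoff_A = Inf, align_idx = rec), 1L)
  same <- make_point_trajectory(rep(list(rbind(c(0, 0, 0), c(1, 1, 1))), 6))
  expect_length(qt_cluster(same, 1:2, rmsd_cutoff_A = 0.1), 1L)
})

test_that("contact lifetimes hit planted targets and persistence boundaries", {
  plant <- make_trajectory(
    data.frame(state = "bound", n_frames = 100),
    contacts = data.frame(receptor_resno = 100L,
                          peptide_resno = c(1L, 2L, 3L),
                          lambda = c(1, 0.4, 0.5)),
    peptide_length = 6)
  tr <- plant$trajectory
  cl <- contact_lifetimes(tr, "P", c("A", "B"),
                          frames = seq_len(n_frames(tr)))
  lam <- setNames(cl$lambda, cl$resno_a)
  expect_equal(lam[["1"]], 1.0)
  expect_equal(lam[["2"]], 0.4)
  expect_equal(lam[["3"]], 0.5)
  per <- setNames(cl$persistent, cl$resno_a)
  expect_true(per[["1"]])
  expect_false(per[["2"]])
  expect_true(per[["3"]])  # lambda >= 0.5 is persistent (boundary)
  # sorted by decreasing lifetime
  expect_true(all(diff(cl$lambda) <= 0))
  # lifetimes are monotone non-decreasing in the cutoff
  cl_wide <- contact_lifetimes(tr, "P", c("A", "B"), heavy_cutoff_A = 8,
                               frames = seq_len(n_frames(tr)))
  for (k in seq_len(nrow(cl))) {
    match <- cl_wide$lambda[cl_wide$resno_a == cl$resno_a[k]]
    expect_gte(max(match), cl$lambda[k])
  }
  expect_error(contact_lifetimes(tr, "P", "A", frames = integer(0)), "empty")
})

test_that("the analysis window selects the trailing fraction of frames", {
  expect_equal(analysis_window(1000), 301:1000)
  expect_equal(analysis_window(10, last_fraction = 1), 1:10)
  expect_error(analysis_window(10, last_fraction = 0), "last_fraction")
  plant <- make_trajectory(data.frame(state = "bound", n_frames = 10))
  expect_equal(analysis_window(plant$trajectory), 4:10)
})

test_that("trajectories round-trip through PDB and plain tables", {
  plant <- make_trajectory(data.frame(state = c("bound", "unbound"),
                                      n_frames = c(3, 2), theta = c(90, 60)))
  tr <- plant$trajectory
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, f1)
  b1 <- read_trajectory_pdb(f1)
  expect_equal(n_frames(b1), 5L)
  expect_lt(max(abs(b1$coords - tr$coords)), 1e-3)
  expect_equal(b1$atoms$chain, tr$atoms$chain)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_table(tr, f2)
  b2 <- read_trajectory_table(f2)
  expect_equal(b2$coords, tr$coords, tolerance = 1e-9)
  expect_equal(b2$atoms$resno, tr$atoms$resno)
})
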