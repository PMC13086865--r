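# Seeded synthetic-structure generators with planted ground truth. These
# stand in for the external docking and simulation engines: they produce the
# same containers the analysis stages consume (pose ensembles, trajectories,
# parent sequences) together with the truth that was planted, so every stage
# can be verified without any external input. Geometry is deliberately
# minimal — C-alpha scaffolds with valid metadata, not physical
# conformations.

ca_atoms <- function(chain, resno, resid = "GLY", element = "C") {
  data.frame(chain = chain, resno = as.integer(resno), resid = resid,
             elety = "CA", element = element)
}

#' Random parent protein sequence
#'
#' Uniform over the 20 standard residues; deterministic under seed.
#'
#' @param length Residue count.
#' @param seed Integer seed.
#' @param id Identifier.
#' @param numbering_offset Absolute index of position 1.
#' @return A [parent_protein()].
#' @export
synthetic_parent <- function(length, seed, id = "synthetic",
                             numbering_offset = 1L) {
  seq <- with_seed(seed,
    paste(sample(aa_alphabet(), length, replace = TRUE), collapse = ""))
  parent_protein(id, seq, numbering_offset)
}

#' Synthetic parent with given subsequences embedded at absolute positions
#'
#' Builds a parent region of `region[1]..region[2]` whose residues are filled
#' uniformly at random except where `embed` pins them: each embedded entry is
#' a sequence anchored at an absolute start index. Overlapping embeddings
#' must agree. Used to reconstruct a study region from published peptide
#' spans when the full parent sequence is not available; the filler positions
#' are synthetic.
#'
#' @param embed Data frame with columns `sequence` and `parent_start`
#'   (absolute).
#' @param region Length-2 integer vector, absolute first/last residue.
#' @param seed Integer seed for the filler residues.
#' @param id Identifier.
#' @return A [parent_protein()] with `numbering_offset = region[1]`.
#' @export
synthetic_parent_embed <- function(embed, region, seed, id = "embedded") {
  offset <- as.integer(region[1])
  L <- as.integer(region[2]) - offset + 1L
  slots <- rep(NA_character_, L)
  for (k in seq_len(nrow(embed))) {
    chars <- aa_chars(embed$sequence[k])
    at <- as.integer(embed$parent_start[k]) - offset + 1L
    idx <- at + seq_along(chars) - 1L
    if (any(idx < 1L | idx > L))
      stop("embedded sequence ", k, " exceeds the region")
    clash <- !is.na(slots[idx]) & slots[idx] != chars
    if (any(clash))
      stop("embedded sequences disagree at absolute position(s) ",
           paste(offset + idx[clash] - 1L, collapse = ", "))
    slots[idx] <- chars
  }
  fill <- with_seed(seed,
    sample(aa_alphabet(), sum(is.na(slots)), replace = TRUE))
  slots[is.na(slots)] <- fill
  parent_protein(id, paste(slots, collapse = ""), offset)
}

#' Synthetic pose ensemble with planted cluster structure
#'
#' Poses are copies of a straight C-alpha peptide template placed at
#' `n_clusters` well-separated anchor sites along a rigid receptor scaffold,
#' with a per-pose rigid Gaussian translation jitter of s.d. `spread_A`.
#' With `spread_A = 0` intra-cluster RMSD is exactly 0; with
#' `separation_A >> spread_A` k-medoids recovers the plant exactly.
#'
#' @param n_poses Total pose count.
#' @param n_clusters Number of planted sites.
#' @param peptide_length Peptide residue count (one C-alpha per residue).
#' @param spread_A Jitter s.d. in Angstrom (default 1).
#' @param separation_A Distance between neighbouring anchors (default 30).
#' @param seed Integer seed.
#' @param occupancy_weights Optional sampling weights per cluster (default
#'   uniform assignment).
#' @param cluster_energy Optional numeric vector (length `n_clusters`) of
#'   base energies; per-pose energies are the base plus U(0, 0.1) noise.
#' @return List: `ensemble` (a [pose_ensemble()]), `labels` (planted cluster
#'   of each pose), `anchors` (n_clusters x 3 matrix).
#' @export
make_pose_blobs <- function(n_poses, n_clusters, peptide_length = 10,
                            spread_A = 1, separation_A = 30, seed = 1,
                            occupancy_weights = NULL,
                            cluster_energy = NULL) {
  stopifnot(n_clusters >= 1, spread_A >= 0, n_poses >= n_clusters)
  if (separation_A < 4 * spread_A && spread_A > 0)
    warning("anchor separation (", separation_A,
            " A) is small relative to spread (", spread_A,
            " A); planted clusters may overlap")
  n_rec <- max(20L, n_clusters * 10L)
  rec_atoms <- ca_atoms("E", seq_len(n_rec))
  rec_xyz <- cbind(3.8 * seq_len(n_rec), 0, 0)
  pep_atoms <- ca_atoms("P", seq_len(peptide_length))
  template <- cbind(3.8 * seq_len(peptide_length), 8, 0)
  anchors <- cbind(separation_A * (seq_len(n_clusters) - 1L), 0, 0)
  out <- with_seed(seed, {
    labels <- if (is.null(occupancy_weights))
      sample.int(n_clusters, n_poses, replace = TRUE)
    else
      sample.int(n_clusters, n_poses, replace = TRUE,
                 prob = occupancy_weights)
    poses <- array(NA_real_, dim = c(peptide_length, 3L, n_poses))
    for (i in seq_len(n_poses)) {
      shift <- anchors[labels[i], ] + rnorm(3, sd = spread_A)
      poses[, , i] <- sweep(template, 2, shift, "+")
    }
    energies <- NULL
    if (!is.null(cluster_energy)) {
      stopifnot(length(cluster_energy) == n_clusters)
      energies <- cluster_energy[labels] + runif(n_poses, 0, 0.1)
    }
    list(labels = labels, poses = poses, energies = energies)
  })
  list(ensemble = pose_ensemble(rec_atoms, rec_xyz, pep_atoms, out$poses,
                                out$energies),
       labels = out$labels, anchors = anchors)
}

#' Single pose with a planted number of contact residues
#'
#' Builds a receptor C-alpha row and one peptide pose in which exactly
#' `planted_contacts` peptide C-alphas lie strictly inside `cutoff_A` of a
#' receptor C-alpha (at `cutoff_A - 3`) and the rest lie outside by a >= 2 A
#' margin. Feeding the result to [contact_analysis()] returns exactly the
#' planted contact count.
#'
#' @param length Peptide residue count.
#' @param planted_contacts How many residues to place in contact
#'   (0..length).
#' @param cutoff_A Contact cutoff the plant is built for (default 10).
#' @return A [pose_ensemble()] with one pose.
#' @export
make_contact_pose <- function(length, planted_contacts, cutoff_A = 10) {
  stopifnot(planted_contacts >= 0, planted_contacts <= length)
  n_rec <- max(length, 10L)
  rec_atoms <- ca_atoms("E", seq_len(n_rec))
  rec_xyz <- cbind(3.8 * seq_len(n_rec), 0, 0)
  pep_atoms <- ca_atoms("P", seq_len(length))
  y <- c(rep(cutoff_A - 3, planted_contacts),
         rep(cutoff_A + 5, length - planted_contacts))
  pose <- array(cbind(3.8 * seq_len(length), y, 0),
                dim = c(length, 3L, 1L))
  pose_ensemble(rec_atoms, rec_xyz, pep_atoms, pose)
}

#' Synthetic trajectory with planted states, angles and contact lifetimes
#'
#' Builds a two-chain receptor (chains A and B) and a peptide (chain P).
#' Three designated C-alpha atoms (A:95, A:214 as vertex, B:95) realise the
#' planted inter-chain angle exactly in every frame; the peptide
#' centre-of-mass is placed at exactly the planted distance `d` from the
#' receptor centre-of-mass; planted residue-pair contacts are toggled frame
#' by frame so each pair's lifetime over all frames equals its target within
#' `1/n_frames`.
#'
#' @param segments Data frame (or list coercible to one) with columns
#'   `state` (`"bound"`, `"intermediate"`, `"unbound"`), `n_frames`, and
#'   optionally `d` (Angstrom; defaults 40 / 47.5 / 60 by state) and `theta`
#'   (degrees; default 70).
#' @param contacts Optional data frame with columns `receptor_resno`
#'   (residue on chain A), `peptide_resno`, `lambda` (target lifetime in
#'   `[0, 1]` over the full trajectory).
#' @param peptide_length Peptide residue count (>= 2 + planted contact
#'   residues; default 6).
#' @param bound_max,unbound_min Thresholds the plant must respect
#'   (defaults 45 / 50).
#' @return List: `trajectory` (an [md_trajectory()]), `truth` (per frame:
#'   `frame`, `state`, `d`, `theta`), `contacts` (the plan with realised
#'   `lambda`), `angle_atoms` (indices for [descriptor_table()]).
#' @export
make_trajectory <- function(segments, contacts = NULL, peptide_length = 6,
                            bound_max = 45, unbound_min = 50) {
  segments <- as.data.frame(segments)
  stopifnot(all(segments$state %in% c("bound", "intermediate", "unbound")),
            all(segments$n_frames >= 1))
  default_d <- c(bound = bound_max - 5,
                 intermediate = (bound_max + unbound_min) / 2,
                 unbound = unbound_min + 10)
  if (is.null(segments$d)) segments$d <- default_d[segments$state]
  if (is.null(segments$theta)) segments$theta <- 70
  ok <- (segments$state == "bound" & segments$d <= bound_max) |
    (segments$state == "intermediate" & segments$d > bound_max &
       segments$d <= unbound_min) |
    (segments$state == "unbound" & segments$d > unbound_min)
  if (!all(ok)) stop("planted d outside its state's interval")
  truth <- data.frame(
    frame = seq_len(sum(segments$n_frames)),
    state = rep(segments$state, segments$n_frames),
    d = rep(segments$d, segments$n_frames),
    theta = rep(segments$theta, segments$n_frames))
  nf <- nrow(truth)
  # receptor scaffold: A:95 and B:95 form the angle arms around vertex A:214
  rec_atoms <- rbind(ca_atoms("A", c(95L, 100L, 214L)),
                     ca_atoms("B", c(95L, 100L)))
  if (!is.null(contacts)) {
    contacts <- as.data.frame(contacts)
    stopifnot(all(contacts$lambda >= 0), all(contacts$lambda <= 1),
              all(contacts$receptor_resno %in% c(100L)),
              all(contacts$peptide_resno >= 1),
              all(contacts$peptide_resno <= peptide_length - 1L),
              !anyDuplicated(contacts$peptide_resno))
    contacts$n_contact <- as.integer(round(contacts$lambda * nf))
    contacts$lambda_realised <- contacts$n_contact / nf
    if (any(abs(contacts$lambda_realised - contacts$lambda) > 1 / nf))
      stop("target lifetime not reachable at ", nf, " frames")
  }
  pep_atoms <- ca_atoms("P", seq_len(peptide_length))
  atoms <- rbind(rec_atoms, pep_atoms)
  n_rec <- nrow(rec_atoms)
  coords <- array(NA_real_, dim = c(nrow(atoms), 3L, nf))
  arm <- 10
  a100 <- c(0, 0, 10)
  for (f in seq_len(nf)) {
    th <- truth$theta[f] * pi / 180
    rec_xyz <- rbind(
      c(arm, 0, 0),                       # A:95 CA
      a100,                               # A:100 CA (contact site)
      c(0, 0, 0),                         # A:214 CA (vertex)
      arm * c(cos(th), sin(th), 0),       # B:95 CA realises theta
      c(0, 0, -10))                       # B:100 CA
    rec_com <- colMeans(rec_xyz)
    pep_xyz <- matrix(NA_real_, peptide_length, 3L)
    com_target <- rec_com + c(truth$d[f], 0, 0)
    if (!is.null(contacts)) {
      for (k in seq_len(nrow(contacts))) {
        in_contact <- f <= contacts$n_contact[k]
        pep_xyz[contacts$peptide_resno[k], ] <-
          a100 + c(0, if (in_contact) 3 else 30, 0)
      }
    }
    free <- which(is.na(pep_xyz[, 1]))
    filler <- setdiff(free, peptide_length)
    for (j in seq_along(filler))
      pep_xyz[filler[j], ] <- com_target + c(0, 0, 4 * j)
    # last residue compensates so the peptide COM is exact
    pep_xyz[peptide_length, ] <-
      peptide_length * com_target -
      colSums(pep_xyz[-peptide_length, , drop = FALSE])
    coords[seq_len(n_rec), , f] <- rec_xyz
    coords[n_rec + seq_len(peptide_length), , f] <- pep_xyz
  }
  list(trajectory = md_trajectory(atoms, coords),
       truth = truth,
       contacts = contacts,
       angle_atoms = c(which(atoms$chain == "A" & atoms$resno == 95L),
                       which(atoms$chain == "A" & atoms$resno == 214L),
                       which(atoms$chain == "B" & atoms$resno == 95L)))
}
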