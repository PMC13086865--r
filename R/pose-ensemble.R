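# Docking-pose ensembles. A pose_ensemble holds one receptor structure and N
# peptide poses already placed in the receptor's coordinate frame (the frame
# docking engines report poses in), so pose-pose RMSD needs no superposition:
# what distinguishes poses is where on the receptor they sit.

#' Construct a docking pose ensemble
#'
#' @param receptor_atoms Data frame with columns `chain`, `resno`, `resid`,
#'   `elety` (atom name), `element` describing receptor atoms.
#' @param receptor_xyz Numeric matrix (n_receptor_atoms x 3).
#' @param peptide_atoms Data frame as above for the peptide; identical atom
#'   order for every pose.
#' @param poses Numeric array (n_peptide_atoms x 3 x n_poses).
#' @param energies Optional numeric vector (one score per pose; lower =
#'   better).
#' @return Object of class `pose_ensemble`.
#' @export
pose_ensemble <- function(receptor_atoms, receptor_xyz, peptide_atoms,
                          poses, energies = NULL) {
  stopifnot(is.data.frame(receptor_atoms), is.data.frame(peptide_atoms),
            nrow(receptor_atoms) == nrow(receptor_xyz),
            length(dim(poses)) == 3L, dim(poses)[2] == 3L,
            dim(poses)[1] == nrow(peptide_atoms))
  if (!is.null(energies))
    stopifnot(length(energies) == dim(poses)[3])
  structure(list(receptor_atoms = receptor_atoms,
                 receptor_xyz = as.matrix(receptor_xyz),
                 peptide_atoms = peptide_atoms,
                 poses = poses, energies = energies),
            class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat(sprintf(
    "<pose_ensemble> %d poses of a %d-atom peptide on a %d-atom receptor%s\n",
    dim(x$poses)[3], dim(x$poses)[1], nrow(x$receptor_atoms),
    if (is.null(x$energies)) "" else " (with energies)"))
  invisible(x)
}

n_poses <- function(ensemble) dim(ensemble$poses)[3]

# Indices of atoms matching a named selection within an atom table.
atom_selection_idx <- function(atoms, selection = c("calpha", "backbone",
                                                    "heavy", "all")) {
  selection <- match.arg(selection)
  switch(selection,
         calpha = which(atoms$elety == "CA"),
         backbone = which(atoms$elety %in% c("N", "CA", "C", "O")),
         heavy = which(atoms$element != "H"),
         all = seq_len(nrow(atoms)))
}

#' RMSD between two poses in the common receptor frame
#'
#' Plain coordinate root-mean-square deviation with no superposition: poses
#' are compared where the docking placed them. Rigidly translating one pose by
#' a vector of length t changes the RMSD to exactly t when starting from
#' identical coordinates.
#'
#' @param ensemble A [pose_ensemble()].
#' @param i,j Pose indices.
#' @param atom_selection `"calpha"`, `"backbone"`, `"heavy"` or `"all"`.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(ensemble, i, j, atom_selection = "calpha") {
  idx <- atom_selection_idx(ensemble$peptide_atoms, atom_selection)
  if (!length(idx)) stop("atom selection matched no atoms")
  a <- ensemble$poses[idx, , i, drop = FALSE]
  b <- ensemble$poses[idx, , j, drop = FALSE]
  d <- a - b
  sqrt(sum(d * d) / length(idx))
}

#' All pairwise pose RMSDs
#'
#' @inheritParams pose_rmsd
#' @return Symmetric n_poses x n_poses matrix (zero diagonal).
#' @export
pose_rmsd_matrix <- function(ensemble, atom_selection = "calpha") {
  idx <- atom_selection_idx(ensemble$peptide_atoms, atom_selection)
  if (!length(idx)) stop("atom selection matched no atoms")
  n <- n_poses(ensemble)
  # no-superposition RMSD = Euclidean distance of flattened coordinates
  # divided by sqrt(n_atoms), so one dist() call covers all pairs
  flat <- t(apply(ensemble$poses[idx, , , drop = FALSE], 3, as.vector))
  as.matrix(stats::dist(flat)) / sqrt(length(idx))
}

#' Cluster a pose ensemble with k-medoids (PAM)
#'
#' Partitions the poses into `k` clusters by PAM (greedy build plus
#' best-improvement swap to convergence) on the pairwise pose RMSD matrix,
#' then reports per-cluster occupancies, the most populated cluster and —
#' when pose energies are available — the lowest-energy cluster (minimum of
#' the per-cluster minimum energy). PAM on a fixed distance matrix is
#' deterministic; `seed` is recorded for provenance and for scorers that
#' randomise restarts.
#'
#' @param ensemble A [pose_ensemble()].
#' @param k Number of clusters (2..n_poses).
#' @param seed Integer seed recorded in the result.
#' @param atom_selection Atoms used for the RMSD metric (default `"calpha"`).
#' @param dist_matrix Optional precomputed distance matrix (skips RMSD).
#' @return Object of class `cluster_set`: `k`, `labels` (length n_poses),
#'   `medoids` (pose indices), `occupancies` (named by cluster), `cost`
#'   (summed distance to assigned medoids), `most_populated`,
#'   `lowest_energy` (NA without energies), `mean_occupancy`.
#' @export
kmedoids_cluster <- function(ensemble, k, seed = 1L,
                             atom_selection = "calpha",
                             dist_matrix = NULL) {
  n <- n_poses(ensemble)
  k <- as.integer(k)
  if (k > n) stop("k (", k, ") exceeds the number of poses (", n, ")")
  if (is.null(dist_matrix))
    dist_matrix <- pose_rmsd_matrix(ensemble, atom_selection)
  if (k == n) {
    # trivial partition: every pose its own medoid
    labels <- seq_len(n)
    medoids <- seq_len(n)
  } else {
    fit <- with_seed(seed,
      cluster::pam(stats::as.dist(dist_matrix), k = k, diss = TRUE,
                   pamonce = 5))
    labels <- as.integer(fit$clustering)
    medoids <- as.integer(fit$id.med)
  }
  occ <- tabulate(labels, nbins = k)
  names(occ) <- seq_len(k)
  cost <- sum(dist_matrix[cbind(seq_len(n), medoids[labels])])
  most_pop <- which.max(occ)  # ties: lowest cluster id
  lowest_en <- NA_integer_
  if (!is.null(ensemble$energies))
    lowest_en <- as.integer(which.min(
      vapply(seq_len(k), function(j)
        min(ensemble$energies[labels == j]), numeric(1))))
  structure(list(k = k, labels = labels, medoids = medoids,
                 occupancies = occ, cost = cost,
                 most_populated = as.integer(most_pop),
                 lowest_energy = lowest_en,
                 mean_occupancy = n / k, seed = as.integer(seed)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> k = %d, N = %d (mean occupancy %.1f)\n",
              x$k, sum(x$occupancies), x$mean_occupancy))
  cat("occupancies:", paste(x$occupancies, collapse = " "), "\n")
  cat(sprintf("most populated: %d%s\n", x$most_populated,
              if (is.na(x$lowest_energy)) ""
              else sprintf(", lowest energy: %d", x$lowest_energy)))
  invisible(x)
}

#' C-alpha contact analysis of one pose against the receptor
#'
#' A peptide residue is in contact when its C-alpha lies strictly within
#' `cutoff_A` of any receptor C-alpha. The contact fraction is
#' `100 * contacts / peptide length`, rounded to two decimals; a candidate is
#' `selected` when the fraction strictly exceeds `fraction_threshold`.
#'
#' @param ensemble A [pose_ensemble()].
#' @param pose Pose index.
#' @param cutoff_A Contact distance cutoff in Angstrom (default 10).
#' @param fraction_threshold Selection threshold in percent (default 50).
#' @return Object of class `contact_report`: `cutoff_A`, `contact_residues`
#'   (peptide residue numbers), `contacts`, `length`, `fraction_pct`,
#'   `selected`.
#' @export
contact_analysis <- function(ensemble, pose = 1L, cutoff_A = 10,
                             fraction_threshold = 50) {
  pep_ca <- which(ensemble$peptide_atoms$elety == "CA")
  rec_ca <- which(ensemble$receptor_atoms$elety == "CA")
  if (!length(pep_ca)) stop("no C-alpha atoms in the peptide")
  if (!length(rec_ca)) stop("no C-alpha atoms in the receptor")
  pep_xyz <- ensemble$poses[pep_ca, , pose, drop = FALSE][, , 1]
  if (is.null(dim(pep_xyz))) pep_xyz <- matrix(pep_xyz, ncol = 3)
  rec_xyz <- ensemble$receptor_xyz[rec_ca, , drop = FALSE]
  # min distance from each peptide CA to any receptor CA
  mind <- apply(pep_xyz, 1, function(p)
    sqrt(min(colSums((t(rec_xyz) - p)^2))))
  in_contact <- mind < cutoff_A  # strict
  len <- length(pep_ca)
  contacts <- sum(in_contact)
  fraction <- round(100 * contacts / len, 2)
  structure(list(cutoff_A = cutoff_A,
                 contact_residues = ensemble$peptide_atoms$resno[pep_ca][in_contact],
                 contacts = contacts, length = len,
                 fraction_pct = fraction,
                 selected = fraction > fraction_threshold),
            class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf(
    "<contact_report> %d / %d residues within %g A (%.2f%%) -> %s\n",
    x$contacts, x$length, x$cutoff_A, x$fraction_pct,
    if (x$selected) "selected" else "not selected"))
  invisible(x)
}

#' Apply the cluster-level selection rules to a clustered ensemble
#'
#' Computes contact reports on the representatives of the most populated and
#' (when energies exist) lowest-energy clusters and applies three rules:
#' contact fraction strictly above the threshold in either representative;
#' occupancy of the most populated cluster strictly above the ensemble mean
#' N/k; and coincidence of the most populated with the lowest-energy cluster.
#'
#' @param ensemble A [pose_ensemble()].
#' @param clusters A `cluster_set` from [kmedoids_cluster()].
#' @param cutoff_A Contact cutoff in Angstrom (default 10).
#' @param fraction_threshold Selection threshold in percent (default 50).
#' @param representative `"medoid"` (default) or `"lowest_energy"` member of
#'   each cluster.
#' @return List: `contacts`, `fraction_pct`, `selected` (fraction rule),
#'   `occupancy` (most populated cluster), `occupancy_above_mean`,
#'   `coincident` (most populated == lowest energy; NA without energies),
#'   `report_most_populated`, `report_lowest_energy`.
#' @export
select_candidates <- function(ensemble, clusters, cutoff_A = 10,
                              fraction_threshold = 50,
                              representative = c("medoid", "lowest_energy")) {
  representative <- match.arg(representative)
  stopifnot(inherits(clusters, "cluster_set"))
  rep_pose <- function(j) {
    members <- which(clusters$labels == j)
    if (representative == "lowest_energy" && !is.null(ensemble$energies))
      members[which.min(ensemble$energies[members])]
    else clusters$medoids[j]
  }
  rep_mp <- rep_pose(clusters$most_populated)
  report_mp <- contact_analysis(ensemble, rep_mp, cutoff_A,
                                fraction_threshold)
  report_le <- NULL
  if (!is.na(clusters$lowest_energy)) {
    rep_le <- rep_pose(clusters$lowest_energy)
    report_le <- contact_analysis(ensemble, rep_le, cutoff_A,
                                  fraction_threshold)
  }
  best <- report_mp
  if (!is.null(report_le) && report_le$fraction_pct > best$fraction_pct)
    best <- report_le
  occupancy <- unname(clusters$occupancies[clusters$most_populated])
  list(
    contacts = best$contacts,
    fraction_pct = best$fraction_pct,
    selected = best$selected,
    occupancy = occupancy,
    occupancy_above_mean = occupancy > clusters$mean_occupancy,
    coincident = if (is.na(clusters$lowest_energy)) NA
                 else clusters$most_populated == clusters$lowest_energy,
    report_most_populated = report_mp,
    report_lowest_energy = report_le
  )
}
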