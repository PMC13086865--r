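# Structure I/O. Reading goes through bio3d's PDB parser (MODEL/ENDMDL
# ensembles via multi = TRUE); writing multi-model files is done here with
# fixed-width ATOM records because the ensemble writer needs one MODEL block
# per pose/frame.

# Format one chain's atoms as PDB ATOM records.
format_atom_records <- function(atoms, xyz, serial_start = 1L) {
  n <- nrow(atoms)
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial_start + seq_len(n) - 1L,
          formatC(atoms$elety, width = -4),
          substr(atoms$resid, 1, 3),
          atoms$chain, atoms$resno,
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
          atoms$element)
}

#' Write a pose ensemble as a multi-model PDB file
#'
#' Each model holds the (fixed) receptor plus one peptide pose; pose energies,
#' when present, are recorded as `REMARK   1 ENERGY` lines per model.
#'
#' @param ensemble A [pose_ensemble()].
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_ensemble_pdb <- function(ensemble, file) {
  con <- file(file, "w")
  on.exit(close(con))
  n_rec <- nrow(ensemble$receptor_atoms)
  for (m in seq_len(n_poses(ensemble))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    if (!is.null(ensemble$energies))
      writeLines(sprintf("REMARK   1 ENERGY %12.4f", ensemble$energies[m]),
                 con)
    writeLines(format_atom_records(ensemble$receptor_atoms,
                                   ensemble$receptor_xyz), con)
    writeLines(format_atom_records(ensemble$peptide_atoms,
                                   ensemble$poses[, , m],
                                   serial_start = n_rec + 1L), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a multi-model PDB file into a pose ensemble
#'
#' Parses with bio3d; the chain given as `peptide_chain` becomes the pose
#' coordinates, everything else the receptor. The receptor is taken from the
#' first model (docking keeps it rigid); `REMARK   1 ENERGY` lines, if
#' present, populate the per-pose energies.
#'
#' @param file Multi-model PDB path.
#' @param peptide_chain Chain identifier of the peptide (default `"P"`).
#' @return A [pose_ensemble()].
#' @export
read_ensemble_pdb <- function(file, peptide_chain = "P") {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  is_pep <- atoms$chain == peptide_chain
  if (!any(is_pep))
    stop("no atoms on peptide chain '", peptide_chain, "'")
  xyz <- pdb$xyz  # n_models x 3N
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  coords_of <- function(model, idx) {
    v <- xyz[model, bio3d::atom2xyz(idx)]
    matrix(v, ncol = 3, byrow = TRUE)
  }
  pep_idx <- which(is_pep); rec_idx <- which(!is_pep)
  meta <- function(idx) data.frame(
    chain = atoms$chain[idx], resno = atoms$resno[idx],
    resid = atoms$resid[idx], elety = atoms$elety[idx],
    element = ifelse(is.na(atoms$elesy[idx]) | atoms$elesy[idx] == "",
                     substr(trimws(atoms$elety[idx]), 1, 1),
                     trimws(atoms$elesy[idx])))
  poses <- array(NA_real_, dim = c(length(pep_idx), 3L, n_models))
  for (m in seq_len(n_models)) poses[, , m] <- coords_of(m, pep_idx)
  energies <- NULL
  rem <- grep("^REMARK   1 ENERGY", readLines(file), value = TRUE)
  if (length(rem) == n_models)
    energies <- as.numeric(sub("^REMARK   1 ENERGY", "", rem))
  pose_ensemble(meta(rec_idx), coords_of(1L, rec_idx), meta(pep_idx),
                poses, energies)
}

#' Read a multi-model PDB file as an MD trajectory
#'
#' Every model becomes a frame; all chains are kept with their metadata.
#'
#' @param file Multi-model PDB path.
#' @return An [md_trajectory()].
#' @export
read_trajectory_pdb <- function(file) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_atoms <- nrow(atoms)
  coords <- array(NA_real_, dim = c(n_atoms, 3L, nrow(xyz)))
  for (m in seq_len(nrow(xyz)))
    coords[, , m] <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
  md_trajectory(
    data.frame(chain = atoms$chain, resno = atoms$resno,
               resid = atoms$resid, elety = atoms$elety,
               element = ifelse(is.na(atoms$elesy) | atoms$elesy == "",
                                substr(trimws(atoms$elety), 1, 1),
                                trimws(atoms$elesy))),
    coords)
}

#' Write an MD trajectory as a multi-model PDB file
#'
#' @param trajectory An [md_trajectory()].
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_trajectory_pdb <- function(trajectory, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (m in seq_len(n_frames(trajectory))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(format_atom_records(trajectory$atoms,
                                   trajectory$coords[, , m]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a plain per-frame coordinate table as a trajectory
#'
#' Whitespace-delimited text with a header and columns `frame`, `chain`,
#' `resno`, `resid`, `elety`, `element`, `x`, `y`, `z`; every frame must list
#' the same atoms in the same order.
#'
#' @param file Path to the table.
#' @return An [md_trajectory()].
#' @export
read_trajectory_table <- function(file) {
  tab <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE)
  frames <- sort(unique(tab$frame))
  first <- tab[tab$frame == frames[1], , drop = FALSE]
  n_atoms <- nrow(first)
  coords <- array(NA_real_, dim = c(n_atoms, 3L, length(frames)))
  for (k in seq_along(frames)) {
    sub <- tab[tab$frame == frames[k], , drop = FALSE]
    if (nrow(sub) != n_atoms) stop("frame ", frames[k], " has ", nrow(sub),
                                   " atoms; expected ", n_atoms)
    coords[, , k] <- as.matrix(sub[, c("x", "y", "z")])
  }
  md_trajectory(first[, c("chain", "resno", "resid", "elety", "element")],
                coords)
}

#' Write a trajectory as a plain per-frame coordinate table
#'
#' @param trajectory An [md_trajectory()].
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_trajectory_table <- function(trajectory, file) {
  n <- nrow(trajectory$atoms)
  frames <- n_frames(trajectory)
  tab <- do.call(rbind, lapply(seq_len(frames), function(m)
    cbind(frame = m, trajectory$atoms,
          x = trajectory$coords[, 1, m],
          y = trajectory$coords[, 2, m],
          z = trajectory$coords[, 3, m])))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
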