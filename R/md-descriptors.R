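# Geometric descriptors of MD trajectories: centre-of-mass separation d,
# inter-chain angle theta, binding-state classification, d/theta density
# grids, quality-threshold conformational clustering and residue-pair
# contact lifetimes.

# Standard atomic masses (Da) for the elements that appear in protein heavy
# atoms plus hydrogen.
.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974)

#' Construct an MD trajectory
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `element`, fixed across frames.
#' @param coords Numeric array (n_atoms x 3 x n_frames), Angstrom.
#' @return Object of class `md_trajectory`.
#' @export
md_trajectory <- function(atoms, coords) {
  stopifnot(is.data.frame(atoms), length(dim(coords)) == 3L,
            dim(coords)[1] == nrow(atoms), dim(coords)[2] == 3L)
  structure(list(atoms = atoms, coords = coords), class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d atoms (%d chains) x %d frames\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              n_frames(x)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory An [md_trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Select atom indices of a trajectory
#'
#' @param trajectory An [md_trajectory()].
#' @param chain Optional chain id(s).
#' @param resno Optional residue number(s).
#' @param elety Optional atom name(s), e.g. `"CA"`.
#' @param heavy_only Drop hydrogens.
#' @return Integer atom indices.
#' @export
select_atoms <- function(trajectory, chain = NULL, resno = NULL,
                         elety = NULL, heavy_only = FALSE) {
  a <- trajectory$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (heavy_only) keep <- keep & a$element != "H"
  which(keep)
}

# Centre of mass (or geometric centroid) of a coordinate block.
centroid <- function(xyz, masses = NULL) {
  if (is.null(masses)) return(colMeans(xyz))
  colSums(xyz * masses) / sum(masses)
}

#' Centre-of-mass distance between two atom selections in one frame
#'
#' @param trajectory An [md_trajectory()].
#' @param frame Frame index.
#' @param selection_a,selection_b Integer atom index vectors (see
#'   [select_atoms()]).
#' @param mass_weighted Use standard atomic masses (default); `FALSE` gives
#'   the geometric centroid.
#' @return Distance in Angstrom; invariant under joint rigid motion.
#' @export
com_distance <- function(trajectory, frame, selection_a, selection_b,
                         mass_weighted = TRUE) {
  if (!length(selection_a) || !length(selection_b))
    stop("atom selections must be non-empty")
  xyz <- trajectory$coords[, , frame, drop = FALSE][, , 1, drop = FALSE]
  dim(xyz) <- dim(xyz)[1:2]
  masses <- NULL
  if (mass_weighted) {
    el <- trajectory$atoms$element
    masses <- .element_mass[el]
    if (anyNA(masses)) stop("unknown element(s): ",
                            paste(unique(el[is.na(masses)]), collapse = ", "))
  }
  ca <- centroid(xyz[selection_a, , drop = FALSE],
                 if (mass_weighted) masses[selection_a])
  cb <- centroid(xyz[selection_b, , drop = FALSE],
                 if (mass_weighted) masses[selection_b])
  sqrt(sum((ca - cb)^2))
}

#' Angle at a vertex atom, in degrees
#'
#' The angle between the vectors vertex->atom1 and vertex->atom2, from the
#' normalised dot product, clamped to `[0, 180]`. When used as an inter-chain
#' opening angle the vertex is the middle of the three designated C-alpha
#' atoms.
#'
#' @param trajectory An [md_trajectory()].
#' @param frame Frame index.
#' @param atom1,vertex_atom,atom2 Single atom indices.
#' @return Angle in degrees.
#' @export
interchain_angle <- function(trajectory, frame, atom1, vertex_atom, atom2) {
  xyz <- trajectory$coords[, , frame]
  v1 <- xyz[atom1, ] - xyz[vertex_atom, ]
  v2 <- xyz[atom2, ] - xyz[vertex_atom, ]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero-length arm at the angle vertex")
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Classify a centre-of-mass distance into a binding state
#'
#' Bound when `d <= bound_max`, unbound when `d > unbound_min`, otherwise
#' intermediate; the defaults leave an explicit 45-50 Angstrom intermediate
#' band. Vectorised over `d`.
#'
#' @param d Distance(s) in Angstrom.
#' @param bound_max Upper bound of the bound state (default 45).
#' @param unbound_min Lower bound (exclusive) of the unbound state
#'   (default 50).
#' @return Character vector in `{"bound", "intermediate", "unbound"}`.
#' @export
classify_binding <- function(d, bound_max = 45, unbound_min = 50) {
  if (bound_max > unbound_min)
    stop("bound_max must be <= unbound_min")
  ifelse(d <= bound_max, "bound",
         ifelse(d > unbound_min, "unbound", "intermediate"))
}

#' Per-frame descriptor table (d, theta, binding state)
#'
#' @param trajectory An [md_trajectory()].
#' @param selection_a,selection_b Atom selections for the COM distance
#'   (typically peptide and protein).
#' @param angle_atoms Integer vector of three atom indices
#'   `(atom1, vertex, atom2)` for the inter-chain angle, or `NULL` to skip.
#' @param bound_max,unbound_min Binding-state thresholds in Angstrom.
#' @param mass_weighted Passed to [com_distance()].
#' @return Data frame: `frame`, `d_A`, `theta_deg` (NA when no angle atoms),
#'   `state`.
#' @export
descriptor_table <- function(trajectory, selection_a, selection_b,
                             angle_atoms = NULL, bound_max = 45,
                             unbound_min = 50, mass_weighted = TRUE) {
  frames <- seq_len(n_frames(trajectory))
  d <- vapply(frames, com_distance, numeric(1), trajectory = trajectory,
              selection_a = selection_a, selection_b = selection_b,
              mass_weighted = mass_weighted)
  theta <- rep(NA_real_, length(frames))
  if (!is.null(angle_atoms)) {
    stopifnot(length(angle_atoms) == 3L)
    theta <- vapply(frames, function(f)
      interchain_angle(trajectory, f, angle_atoms[1], angle_atoms[2],
                       angle_atoms[3]), numeric(1))
  }
  data.frame(frame = frames, d_A = d, theta_deg = theta,
             state = classify_binding(d, bound_max, unbound_min))
}

#' 2D histogram of paired descriptor values
#'
#' Uniform binning of (x, y) pairs (e.g. d and theta per frame) on an
#' `bins x bins` grid; the counts sum to the number of frames.
#'
#' @param x,y Numeric vectors of equal length.
#' @param bins Grid size per axis (default 151).
#' @param xlim,ylim Ranges; default the data range (degenerate ranges are an
#'   error).
#' @return List: `counts` (bins x bins matrix, x rows), `x_edges`, `y_edges`.
#' @export
density_2d <- function(x, y, bins = 151, xlim = range(x), ylim = range(y)) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (diff(xlim) <= 0 || diff(ylim) <= 0) {
    if (length(unique(x)) == 1L) xlim <- xlim + c(-0.5, 0.5)
    if (length(unique(y)) == 1L) ylim <- ylim + c(-0.5, 0.5)
    if (diff(xlim) <= 0 || diff(ylim) <= 0)
      stop("degenerate binning range")
  }
  xe <- seq(xlim[1], xlim[2], length.out = bins + 1L)
  ye <- seq(ylim[1], ylim[2], length.out = bins + 1L)
  ix <- findInterval(x, xe, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, ye, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins, bins)
  for (k in seq_along(ix))
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  list(counts = counts, x_edges = xe, y_edges = ye)
}

# Least-squares superposition (Kabsch via bio3d) of every frame onto the
# first, fitting on align_idx; returns frames x 3N matrix of fitted coords.
align_frames <- function(trajectory, align_idx) {
  nf <- n_frames(trajectory)
  flat <- t(vapply(seq_len(nf), function(m)
    as.vector(t(trajectory$coords[, , m])), numeric(3 * nrow(trajectory$atoms))))
  inds <- bio3d::atom2xyz(align_idx)
  bio3d::fit.xyz(fixed = flat[1, ], mobile = flat,
                 fixed.inds = inds, mobile.inds = inds)
}

#' Quality-threshold clustering of trajectory frames
#'
#' Frames are first superposed on `align_idx` (typically receptor C-alpha
#' atoms), then pairwise RMSD over `cluster_idx` (typically peptide backbone)
#' is thresholded at `rmsd_cutoff_A`. Clusters are grown greedily: the frame
#' whose cutoff-neighbourhood is largest becomes a cluster centre (ties to
#' the lowest frame index), its neighbourhood is removed, and the process
#' repeats. Every member lies within the cutoff of its centre; cluster sizes
#' are non-increasing in output order.
#'
#' @param trajectory An [md_trajectory()].
#' @param cluster_idx Atom indices defining the RMSD metric.
#' @param rmsd_cutoff_A RMSD cutoff in Angstrom (default 20).
#' @param align_idx Atom indices to superpose on first; `NULL` skips
#'   alignment.
#' @return List of clusters, each a list with `centre` (frame index) and
#'   `members` (frame indices, including the centre).
#' @export
qt_cluster <- function(trajectory, cluster_idx, rmsd_cutoff_A = 20,
                       align_idx = NULL) {
  nf <- n_frames(trajectory)
  if (nf < 1L) stop("empty trajectory")
  if (!is.null(align_idx) && length(align_idx)) {
    fitted <- align_frames(trajectory, align_idx)
  } else {
    fitted <- t(vapply(seq_len(nf), function(m)
      as.vector(t(trajectory$coords[, , m])),
      numeric(3 * nrow(trajectory$atoms))))
  }
  sub <- fitted[, bio3d::atom2xyz(cluster_idx), drop = FALSE]
  rmsd <- as.matrix(stats::dist(sub)) / sqrt(length(cluster_idx))
  within <- rmsd <= rmsd_cutoff_A
  remaining <- rep(TRUE, nf)
  clusters <- list()
  while (any(remaining)) {
    sizes <- rowSums(within[, remaining, drop = FALSE])
    sizes[!remaining] <- -1L
    centre <- which.max(sizes)  # ties -> lowest frame index
    members <- which(remaining & within[centre, ])
    clusters[[length(clusters) + 1L]] <- list(centre = centre,
                                              members = members)
    remaining[members] <- FALSE
  }
  clusters
}

#' Frame window selected by fraction of the trajectory
#'
#' Returns the frame indices of the trailing `last_fraction` of the
#' trajectory (default the last 70 %, i.e. equilibration discarded).
#'
#' @param trajectory An [md_trajectory()] (or a frame count).
#' @param last_fraction Fraction in (0, 1].
#' @return Integer frame indices.
#' @export
analysis_window <- function(trajectory, last_fraction = 0.7) {
  nf <- if (is.numeric(trajectory)) as.integer(trajectory)
        else n_frames(trajectory)
  if (last_fraction <= 0 || last_fraction > 1)
    stop("last_fraction must be in (0, 1]")
  first <- nf - floor(nf * last_fraction) + 1L
  if (first > nf) stop("analysis window is empty")
  first:nf
}

#' Residue-pair contact lifetimes over an analysis window
#'
#' For every residue pair between `chains_a` and `chains_b`, the lifetime
#' lambda is the fraction of analysed frames in which the minimum heavy-atom
#' distance is strictly below `heavy_cutoff_A`; pairs with
#' `lambda >= lifetime_threshold` are flagged persistent.
#'
#' @param trajectory An [md_trajectory()].
#' @param chains_a,chains_b Chain id vectors defining the two groups.
#' @param heavy_cutoff_A Heavy-atom distance cutoff in Angstrom (default 5).
#' @param lifetime_threshold Persistence threshold on lambda (default 0.5).
#' @param frames Frame indices to analyse (default [analysis_window()] of the
#'   last 70 %).
#' @return Data frame sorted by decreasing lambda: `chain_a`, `resno_a`,
#'   `chain_b`, `resno_b`, `lambda`, `persistent`. Only pairs ever in contact
#'   are listed.
#' @export
contact_lifetimes <- function(trajectory, chains_a, chains_b,
                              heavy_cutoff_A = 5, lifetime_threshold = 0.5,
                              frames = analysis_window(trajectory)) {
  if (!length(frames)) stop("frame range is empty")
  atoms <- trajectory$atoms
  heavy <- atoms$element != "H"
  ia <- which(heavy & atoms$chain %in% chains_a)
  ib <- which(heavy & atoms$chain %in% chains_b)
  if (!length(ia) || !length(ib)) stop("empty heavy-atom selection")
  key_a <- paste(atoms$chain[ia], atoms$resno[ia])
  key_b <- paste(atoms$chain[ib], atoms$resno[ib])
  res_a <- unique(key_a); res_b <- unique(key_b)
  hits <- matrix(0L, length(res_a), length(res_b),
                 dimnames = list(res_a, res_b))
  cutoff2 <- heavy_cutoff_A^2
  for (f in frames) {
    xa <- trajectory$coords[ia, , f, drop = FALSE]; dim(xa) <- c(length(ia), 3L)
    xb <- trajectory$coords[ib, , f, drop = FALSE]; dim(xb) <- c(length(ib), 3L)
    # squared distance matrix between the two heavy-atom sets
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    contact <- d2 < cutoff2
    # collapse atom-level contacts to residue pairs (any atom pair in range)
    byres_a <- rowsum(contact + 0, key_a, reorder = FALSE) > 0
    byres <- t(rowsum(t(byres_a) + 0, key_b, reorder = FALSE)) > 0
    hits <- hits + byres[res_a, res_b, drop = FALSE]
  }
  lam <- hits / length(frames)
  idx <- which(lam > 0, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(chain_a = character(0), resno_a = integer(0),
                      chain_b = character(0), resno_b = integer(0),
                      lambda = numeric(0), persistent = logical(0)))
  }
  split_key <- function(k) {
    parts <- strsplit(k, " ", fixed = TRUE)
    list(chain = vapply(parts, `[`, "", 1),
         resno = as.integer(vapply(parts, `[`, "", 2)))
  }
  ka <- split_key(rownames(lam)[idx[, 1]])
  kb <- split_key(colnames(lam)[idx[, 2]])
  out <- data.frame(chain_a = ka$chain, resno_a = ka$resno,
                    chain_b = kb$chain, resno_b = kb$resno,
                    lambda = lam[idx],
                    persistent = lam[idx] >= lifetime_threshold)
  out[order(-out$lambda, out$chain_a, out$resno_a, out$resno_b), ,
      drop = FALSE]
}
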