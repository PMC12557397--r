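#' Contact-distance trajectory
#'
#' Container for a single biased unbinding trajectory represented as a
#' matrix of ligand--protein contact distances: `K` rows (time steps) by
#' `M` columns (contacts), distances in nm.
#'
#' @param values Numeric matrix, `K x M`, nonnegative finite contact
#'   distances in nm.
#' @param dt Frame spacing in ps.
#' @param traj_id Character identifier for the trajectory.
#' @param contact_labels Character vector of length `M` naming the contact
#'   residues (e.g. `"A:123"`). Defaults to column names of `values` or
#'   `"c1" ... "cM"`.
#' @return An object of class `contact_trajectory`.
#' @export
contact_trajectory <- function(values, dt = 1, traj_id = "traj",
                               contact_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("contact distances must be finite (no NA/NaN/Inf)")
  if (any(values < 0))
    stop("contact distances must be nonnegative")
  new_contact_trajectory(values, dt, traj_id, contact_labels)
}

# internal constructor: skips the nonnegativity check so that preprocessed
# (standardized, PCA-projected) trajectories can reuse the container
new_contact_trajectory <- function(values, dt = 1, traj_id = "traj",
                                   contact_labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("a trajectory needs at least K = 2 time steps")
  if (ncol(values) < 1) stop("a trajectory needs at least M = 1 contact")
  if (any(!is.finite(values))) stop("contact distances must be finite")
  if (is.null(contact_labels)) {
    contact_labels <- colnames(values)
    if (is.null(contact_labels))
      contact_labels <- paste0("c", seq_len(ncol(values)))
  }
  if (length(contact_labels) != ncol(values))
    stop("contact_labels must have one entry per column")
  colnames(values) <- contact_labels
  structure(
    list(values = values, dt = as.numeric(dt), traj_id = as.character(traj_id),
         contact_labels = as.character(contact_labels)),
    class = "contact_trajectory")
}

#' @export
print.contact_trajectory <- function(x, ...) {
  cat(sprintf("contact_trajectory '%s': %d time steps x %d contacts, dt = %g ps\n",
              x$traj_id, nrow(x$values), ncol(x$values), x$dt))
  invisible(x)
}

#' @export
dim.contact_trajectory <- function(x) dim(x$values)

#' Trajectory ensemble
#'
#' A set of `N >= 2` [contact_trajectory] objects sharing the same contact
#' set (identical `contact_labels` in identical order); the number of time
#' steps `K` may differ between members. Optionally carries ground-truth
#' pathway labels.
#'
#' @param trajectories List of [contact_trajectory] objects.
#' @param labels Optional vector of ground-truth pathway labels, one per
#'   trajectory.
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(trajectories, labels = NULL) {
  if (!is.list(trajectories) || length(trajectories) < 2)
    stop("an ensemble needs at least N = 2 trajectories")
  ok <- vapply(trajectories, inherits, logical(1), "contact_trajectory")
  if (!all(ok)) stop("all elements must be contact_trajectory objects")
  ref <- trajectories[[1]]$contact_labels
  same <- vapply(trajectories, function(tr) identical(tr$contact_labels, ref),
                 logical(1))
  if (!all(same)) {
    bad <- vapply(trajectories[!same], function(tr) tr$traj_id, character(1))
    stop("trajectories with mismatching contact columns: ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(labels)) {
    if (length(labels) != length(trajectories))
      stop("labels must have one entry per trajectory")
    labels <- as.character(labels)
  }
  structure(list(trajectories = trajectories, labels = labels,
                 contact_labels = ref),
            class = "trajectory_ensemble")
}

#' @export
length.trajectory_ensemble <- function(x) length(x$trajectories)

#' @export
print.trajectory_ensemble <- function(x, ...) {
  ks <- vapply(x$trajectories, function(tr) nrow(tr$values), integer(1))
  cat(sprintf("trajectory_ensemble: N = %d trajectories, M = %d contacts, K in [%d, %d]\n",
              length(x), length(x$contact_labels), min(ks), max(ks)))
  if (!is.null(x$labels))
    cat("  labels:", paste(names(table(x$labels)), table(x$labels),
                           sep = " x ", collapse = ", "), "\n")
  invisible(x)
}

# TRUE if every member has the same number of time steps
equal_lengths <- function(ensemble) {
  ks <- vapply(ensemble$trajectories, function(tr) nrow(tr$values), integer(1))
  length(unique(ks)) == 1L
}

# stack all trajectories into one (N*K) x M matrix (requires equal K when
# alignment matters; callers that only pool samples may stack unequal K too)
pool_values <- function(ensemble) {
  do.call(rbind, lapply(ensemble$trajectories, function(tr) tr$values))
}

# apply a per-trajectory matrix transform, keeping metadata
map_ensemble <- function(ensemble, f) {
  out <- lapply(ensemble$trajectories, function(tr) {
    v <- f(tr$values)
    new_contact_trajectory(v, dt = tr$dt, traj_id = tr$traj_id,
                           contact_labels = colnames(v))
  })
  trajectory_ensemble(out, labels = ensemble$labels)
}

#' Per-frame coordinate set for contact extraction
#'
#' Raw Cartesian coordinates (nm) from which contact-distance features are
#' extracted: ligand heavy atoms, protein C-alpha atoms (one per residue)
#' and protein heavy atoms grouped by residue. All arrays are indexed
#' `[frame, atom, xyz]`.
#'
#' @param ligand_atoms Numeric array `F x A x 3` of ligand heavy-atom
#'   coordinates.
#' @param protein_calpha Numeric array `F x R x 3` of C-alpha coordinates;
#'   residue identities are taken from `residue_ids`.
#' @param protein_heavy Named list, one element per residue (names are the
#'   residue ids), each a numeric array `F x a_r x 3` of that residue's
#'   heavy-atom coordinates.
#' @param residue_ids Character vector of residue identifiers (conventionally
#'   `"chain:resnum"` with 1-based residue numbers) aligned with the second
#'   dimension of `protein_calpha`.
#' @return An object of class `coordinate_frame_set`.
#' @export
coordinate_frame_set <- function(ligand_atoms, protein_calpha, protein_heavy,
                                 residue_ids = NULL) {
  if (length(dim(ligand_atoms)) != 3 || dim(ligand_atoms)[3] != 3)
    stop("ligand_atoms must be an F x A x 3 array")
  if (length(dim(protein_calpha)) != 3 || dim(protein_calpha)[3] != 3)
    stop("protein_calpha must be an F x R x 3 array")
  nf <- dim(ligand_atoms)[1]
  if (dim(protein_calpha)[1] != nf)
    stop("frame counts of ligand and C-alpha arrays disagree")
  if (is.null(residue_ids))
    residue_ids <- names(protein_heavy)
  if (is.null(residue_ids))
    residue_ids <- paste0("A:", seq_len(dim(protein_calpha)[2]))
  if (length(residue_ids) != dim(protein_calpha)[2])
    stop("residue_ids must match the number of C-alpha residues")
  if (!is.list(protein_heavy) || length(protein_heavy) != length(residue_ids))
    stop("protein_heavy must be a list with one element per residue")
  names(protein_heavy) <- residue_ids
  for (r in residue_ids) {
    h <- protein_heavy[[r]]
    if (length(dim(h)) != 3 || dim(h)[3] != 3 || dim(h)[1] != nf)
      stop("heavy-atom array for residue ", r, " must be F x a x 3")
    if (any(!is.finite(h))) stop("non-finite coordinates in residue ", r)
  }
  if (any(!is.finite(ligand_atoms)) || any(!is.finite(protein_calpha)))
    stop("coordinates must be finite")
  structure(list(ligand_atoms = ligand_atoms, protein_calpha = protein_calpha,
                 protein_heavy = protein_heavy, residue_ids = residue_ids),
            class = "coordinate_frame_set")
}

#' Identify ligand--protein contact residues
#'
#' A residue is a contact if its C-alpha atom comes within `cutoff` of any
#' ligand atom in any frame. The comparison is inclusive (`<= cutoff`);
#' the measure-zero boundary makes the choice immaterial in practice, and
#' inclusive matches conventional contact definitions.
#'
#' @param coords A [coordinate_frame_set].
#' @param cutoff Contact cutoff in nm (default 0.45).
#' @return Character vector of contact residue ids, in residue order.
#' @export
identify_contacts <- function(coords, cutoff = 0.45) {
  stopifnot(inherits(coords, "coordinate_frame_set"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  nf <- dim(coords$ligand_atoms)[1]
  if (nf < 1) stop("no frames")
  nres <- length(coords$residue_ids)
  hit <- logical(nres)
  for (f in seq_len(nf)) {
    lig <- matrix(coords$ligand_atoms[f, , ], ncol = 3)
    ca <- matrix(coords$protein_calpha[f, , ], ncol = 3)
    d <- min_cross_dist(ca, lig)        # per-residue min over ligand atoms
    hit <- hit | (d <= cutoff)
  }
  if (!any(hit)) stop("no contacts found within cutoff ", cutoff, " nm")
  coords$residue_ids[hit]
}

# rowwise minimum Euclidean distance from each row of a to any row of b
min_cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(apply(d2, 1, min))
}

#' Compute minimal heavy-atom contact distances
#'
#' For each frame and contact residue, the minimal Euclidean distance
#' between any ligand heavy atom and any heavy atom of the residue.
#'
#' @param coords A [coordinate_frame_set].
#' @param contacts Character vector of residue ids (e.g. from
#'   [identify_contacts()]).
#' @param dt Frame spacing in ps for the resulting trajectory.
#' @param traj_id Identifier for the resulting trajectory.
#' @return A [contact_trajectory] with one column per contact residue.
#' @export
compute_contact_distances <- function(coords, contacts, dt = 1,
                                      traj_id = "traj") {
  stopifnot(inherits(coords, "coordinate_frame_set"))
  if (length(contacts) < 1) stop("contacts must be nonempty")
  missing <- setdiff(contacts, coords$residue_ids)
  if (length(missing) > 0)
    stop("residue(s) absent from coordinate set: ",
         paste(missing, collapse = ", "))
  nf <- dim(coords$ligand_atoms)[1]
  vals <- matrix(NA_real_, nf, length(contacts))
  for (f in seq_len(nf)) {
    lig <- matrix(coords$ligand_atoms[f, , ], ncol = 3)
    for (m in seq_along(contacts)) {
      h <- coords$protein_heavy[[contacts[m]]]
      res <- matrix(h[f, , ], ncol = 3)
      vals[f, m] <- min(min_cross_dist(res, lig))
    }
  }
  new_contact_trajectory(vals, dt = dt, traj_id = traj_id,
                         contact_labels = contacts)
}
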