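#' Trajectory container
#'
#' A `Trajectory` bundles an atom table with per-frame coordinates.  The
#' coordinate store follows the bio3d convention: a numeric matrix with one
#' row per frame and `3 * n_atoms` columns ordered `x1, y1, z1, x2, ...`,
#' all in Angstrom.  Every frame shares the same atom table; residues are
#' identified by the `(chain, res_id)` pair using author numbering.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `res_name`, `res_id`, `chain` (one row per atom).
#' @param xyz numeric matrix, frames x (3 * atoms), Angstrom.
#' @param frame_spacing time between consecutive frames in ns.
#' @return An object of class `Trajectory`.
#' @export
trajectory <- function(atoms, xyz, frame_spacing = 0.04) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  required <- c("serial", "name", "element", "res_name", "res_id", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("xyz has ", ncol(xyz), " columns but the atom table implies ",
         3L * nrow(atoms))
  if (!all(is.finite(xyz))) stop("non-finite coordinates in trajectory")
  key <- paste(atoms$chain, atoms$res_id, atoms$name, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (chain, res_id, name) atom keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  structure(
    list(atoms = atoms, xyz = xyz, frame_spacing = frame_spacing),
    class = "Trajectory"
  )
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames x", n_atoms(x), "atoms",
      sprintf("(%.3g ns/frame)\n", x$frame_spacing))
  cat("  residues:", nrow(unique(x$atoms[, c("chain", "res_id")])),
      " hydrogens:", ifelse(has_hydrogens(x), "present", "absent"), "\n")
  invisible(x)
}

#' Number of frames / atoms in a Trajectory
#' @param traj a `Trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' Does the trajectory contain hydrogen atoms?
#'
#' Hydrogen availability is reported at load time because only the
#' hydrogen-bond stage needs explicit hydrogens; every other analysis
#' silently ignores their absence.
#' @param traj a `Trajectory`.
#' @return logical scalar.
#' @export
has_hydrogens <- function(traj) any(traj$atoms$element == "H")

#' Coordinates of one frame as an atoms x 3 matrix
#' @param traj a `Trajectory`.
#' @param frame 1-based frame index.
#' @return numeric matrix, `n_atoms(traj)` x 3.
#' @export
frame_coords <- function(traj, frame) {
  if (frame < 1L || frame > n_frames(traj))
    stop("frame index ", frame, " out of range [1, ", n_frames(traj), "]")
  matrix(traj$xyz[frame, ], ncol = 3L, byrow = TRUE)
}

## flatten an atoms x 3 matrix back to one xyz row
.flatten_coords <- function(m) as.vector(t(m))

#' Select atoms of a trajectory
#'
#' Builds a `Selection`: a resolved, strictly increasing atom index list
#' that is stable across frames (the atom table is frame-invariant).
#' Filters combine with AND; `NULL` filters are ignored.
#'
#' @param traj a `Trajectory`.
#' @param res_id integer vector of author residue numbers to keep.
#' @param name character vector of atom names to keep (e.g. `"CA"`).
#' @param element character vector of element symbols to keep.
#' @param chain character vector of chain identifiers to keep.
#' @param heavy if `TRUE`, keep only C/N/O/S atoms.
#' @return An object of class `Selection` with fields `indices` and `label`.
#' @export
select_atoms <- function(traj, res_id = NULL, name = NULL, element = NULL,
                         chain = NULL, heavy = FALSE) {
  at <- traj$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(res_id))  keep <- keep & at$res_id %in% res_id
  if (!is.null(name))    keep <- keep & at$name %in% name
  if (!is.null(element)) keep <- keep & at$element %in% element
  if (!is.null(chain))   keep <- keep & at$chain %in% chain
  if (heavy)             keep <- keep & at$element %in% c("C", "N", "O", "S")
  parts <- c(
    if (!is.null(res_id)) paste0("res ", .range_label(res_id)),
    if (!is.null(name)) paste0("name ", paste(name, collapse = ",")),
    if (!is.null(element)) paste0("elem ", paste(element, collapse = ",")),
    if (!is.null(chain)) paste0("chain ", paste(chain, collapse = ",")),
    if (heavy) "heavy"
  )
  selection(which(keep), label = if (length(parts)) paste(parts, collapse = " & ") else "all")
}

.range_label <- function(v) {
  v <- sort(unique(v))
  if (length(v) > 2L && all(diff(v) == 1L)) paste0(v[1L], "-", v[length(v)])
  else paste(v, collapse = ",")
}

#' Construct a Selection from explicit atom indices
#' @param indices strictly increasing 1-based atom indices.
#' @param label human-readable description.
#' @return An object of class `Selection`.
#' @export
selection <- function(indices, label = "custom") {
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE))
    stop("selection indices must be strictly increasing")
  structure(list(indices = indices, label = label), class = "Selection")
}

#' @export
print.Selection <- function(x, ...) {
  cat("Selection [", x$label, "]: ", length(x$indices), " atoms\n", sep = "")
  invisible(x)
}

## resolve a Selection (or raw index vector, or NULL = all atoms) to indices
.sel_idx <- function(traj, sel) {
  if (is.null(sel)) return(seq_len(n_atoms(traj)))
  if (inherits(sel, "Selection")) sel <- sel$indices
  sel <- as.integer(sel)
  if (length(sel) == 0L) stop("empty atom selection")
  if (any(sel < 1L | sel > n_atoms(traj)))
    stop("selection index out of range")
  sel
}

## columns of the xyz matrix covered by atom indices
.xyz_cols <- function(idx) as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))

#' Residue table of a trajectory (one row per residue, in atom order)
#' @param traj a `Trajectory`.
#' @return data.frame with `chain`, `res_id`, `res_name`.
#' @export
residue_table <- function(traj) {
  at <- traj$atoms
  unique(at[, c("chain", "res_id", "res_name")])
}

#' Check that two trajectories share an identical atom table
#' @noRd
.check_same_atoms <- function(trajs) {
  ref <- trajs[[1L]]$atoms
  for (k in seq_along(trajs)) {
    a <- trajs[[k]]$atoms
    if (nrow(a) != nrow(ref) ||
        !all(a$name == ref$name & a$res_id == ref$res_id & a$chain == ref$chain))
      stop("ensemble error: trajectory ", k,
           " has a different atom table than trajectory 1")
  }
  invisible(TRUE)
}

## coerce a single Trajectory to a one-element ensemble list
.as_ensemble <- function(x) {
  if (inherits(x, "Trajectory")) list(x)
  else if (is.list(x) && all(vapply(x, inherits, logical(1), "Trajectory"))) x
  else stop("expected a Trajectory or a list of Trajectory objects")
}
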