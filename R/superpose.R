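#' Least-squares rigid-body superposition (Kabsch)
#'
#' Computes the proper rotation and translation minimizing the RMSD between
#' the selected atoms of a mobile and a reference frame.  The optimal
#' rotation comes from the SVD of the covariance of the centered selections
#' with the usual determinant sign correction, so the result is always a
#' proper rotation (no reflection).
#'
#' Conventions: coordinates are atoms x 3 row matrices and the fitted
#' mobile is `mobile %*% rotation + translation` (rows transform on the
#' right).
#'
#' @param mobile atoms x 3 coordinate matrix to be moved.
#' @param reference atoms x 3 coordinate matrix held fixed.
#' @param sel optional `Selection` or integer index vector naming the atoms
#'   used to fit (default: all atoms).  Both matrices must index alike.
#' @return An object of class `SuperpositionResult`: list with `rotation`
#'   (3 x 3, det +1), `translation` (length-3, Angstrom) and `rmsd`
#'   (Angstrom, over the fitting selection after the transform).
#' @export
superpose <- function(mobile, reference, sel = NULL) {
  idx <- if (is.null(sel)) seq_len(nrow(mobile)) else
    if (inherits(sel, "Selection")) sel$indices else as.integer(sel)
  if (length(idx) < 3L)
    stop("geometry error: superposition needs at least 3 atoms")
  m <- mobile[idx, , drop = FALSE]
  r <- reference[idx, , drop = FALSE]
  if (nrow(m) != nrow(r)) stop("selection sizes differ between frames")

  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2L, cm); rc <- sweep(r, 2L, cr)
  sv_m <- svd(mc)$d
  if (sv_m[2L] < 1e-8 * max(sv_m[1L], 1))
    stop("geometry error: selection is collinear")

  h <- crossprod(mc, rc)              # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)  # right-multiplication form
  trans <- cr - as.vector(cm %*% rot)

  fitted <- sweep(mc %*% rot, 2L, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - r)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("SuperpositionResult: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#' @param coords atoms x 3 matrix.
#' @param fit a `SuperpositionResult`.
#' @return transformed atoms x 3 matrix.
#' @export
apply_transform <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2L, fit$translation, "+")
}

#' RMSD between two coordinate sets without fitting
#' @noRd
.raw_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Align every frame of a trajectory onto reference coordinates
#'
#' Each frame is superposed on `ref_coords` over `align_sel`; the transform
#' is applied to all atoms of the frame.
#'
#' @param traj a `Trajectory`.
#' @param ref_coords atoms x 3 reference coordinates (full atom set).
#' @param align_sel `Selection`/indices used for the fit.
#' @return a `Trajectory` with aligned coordinates.
#' @export
align_frames <- function(traj, ref_coords, align_sel = NULL) {
  idx <- .sel_idx(traj, align_sel)
  out <- traj$xyz
  for (t in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, t)
    fit <- superpose(fr, ref_coords, sel = idx)
    out[t, ] <- .flatten_coords(apply_transform(fr, fit))
  }
  trajectory(traj$atoms, out, frame_spacing = traj$frame_spacing)
}

#' Pool an ensemble and align it to its iterated mean structure
#'
#' Frames from all trajectories are pooled and iteratively aligned to the
#' pooled mean over `align_sel` (fit on the selection, transform applied to
#' all atoms) until the mean structure moves by less than `tol` Angstrom,
#' the reference convention used for RMSF, PCA and the fluctuation series
#' feeding mutual information.
#'
#' @param ensemble a `Trajectory` or list of them (identical atom tables).
#' @param align_sel `Selection`/indices used for the fit.
#' @param tol convergence tolerance on the mean structure (Angstrom).
#' @param max_iter iteration cap.
#' @return list with `xyz` (pooled aligned frames x 3N), `mean` (3N vector),
#'   `atoms`, `n_iter`, `frame_origin` (trajectory index per pooled frame).
#' @export
pool_align <- function(ensemble, align_sel = NULL, tol = 1e-6,
                       max_iter = 50L) {
  trajs <- .as_ensemble(ensemble)
  .check_same_atoms(trajs)
  idx <- .sel_idx(trajs[[1L]], align_sel)
  xyz <- do.call(rbind, lapply(trajs, function(tr) tr$xyz))
  origin <- rep(seq_along(trajs), vapply(trajs, n_frames, integer(1)))
  natoms <- nrow(trajs[[1L]]$atoms)

  ref <- matrix(xyz[1L, ], ncol = 3L, byrow = TRUE)
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    for (t in seq_len(nrow(xyz))) {
      fr <- matrix(xyz[t, ], ncol = 3L, byrow = TRUE)
      fit <- superpose(fr, ref, sel = idx)
      xyz[t, ] <- .flatten_coords(apply_transform(fr, fit))
    }
    new_mean <- matrix(colMeans(xyz), ncol = 3L, byrow = TRUE)
    shift <- max(abs(new_mean - ref))
    ref <- new_mean
    if (shift < tol || n_iter >= max_iter) break
  }
  list(xyz = xyz, mean = .flatten_coords(ref),
       atoms = trajs[[1L]]$atoms, n_iter = n_iter, frame_origin = origin,
       frame_spacing = trajs[[1L]]$frame_spacing)
}
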