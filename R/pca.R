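#' Principal component analysis of C-alpha fluctuations
#'
#' Pools and aligns the ensemble to its iterated mean (see [pool_align()]),
#' then eigendecomposes the population covariance of the 3N-dimensional
#' coordinate vector of the selection.  Eigenvalues are in Angstrom^2 and
#' sum to the total mean-squared fluctuation of the aligned ensemble; the
#' sign of each eigenvector is fixed by making its largest-magnitude
#' component positive.
#'
#' @param ensemble a `Trajectory` or list of replicates.
#' @param sel `Selection` of atoms entering the covariance (typically the
#'   C-alpha set); also used as the alignment fit selection.
#' @return An object of class `PCAModel`: list with `values` (eigenvalues,
#'   descending), `vectors` (3n x 3n orthonormal columns), `mean` (3n
#'   vector), `cumulative` (cumulative variance ratios), `sel_idx`,
#'   `atoms`, `n_frames`.
#' @export
fit_pca <- function(ensemble, sel = NULL) {
  trajs <- .as_ensemble(ensemble)
  if (sum(vapply(trajs, n_frames, integer(1))) < 2L)
    stop("data error: PCA needs at least 2 frames")
  pooled <- pool_align(trajs, align_sel = sel)
  idx <- if (is.null(sel)) seq_len(nrow(pooled$atoms)) else
    if (inherits(sel, "Selection")) sel$indices else as.integer(sel)
  cols <- .xyz_cols(idx)
  x <- pooled$xyz[, cols, drop = FALSE]
  mu <- pooled$mean[cols]
  xc <- sweep(x, 2L, mu)
  cv <- crossprod(xc) / nrow(xc)            # population covariance
  eig <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs))) {          # reproducible sign convention
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(values = vals, vectors = vecs, mean = mu,
                 cumulative = cumulative_variance(vals),
                 sel_idx = idx, atoms = pooled$atoms[idx, , drop = FALSE],
                 n_frames = nrow(x)),
            class = "PCAModel")
}

#' @export
print.PCAModel <- function(x, ...) {
  k <- min(5L, length(x$values))
  cat("PCAModel:", length(x$values), "modes from", x$n_frames, "frames\n")
  cat("  cumulative variance PC1-PC", k, ": ",
      sprintf("%.1f%%", 100 * x$cumulative[k]), "\n", sep = "")
  invisible(x)
}

#' Cumulative variance ratios of an eigenvalue spectrum
#'
#' `PCA_c = sum(lambda[1:c]) / sum(lambda)`, the fraction of total variance
#' captured by the top `c` modes.
#'
#' @param values eigenvalues, non-negative, descending.
#' @return numeric vector of cumulative ratios; the last entry is 1.
#' @export
cumulative_variance <- function(values) {
  if (any(values < 0)) stop("eigenvalues must be non-negative")
  cumsum(values) / sum(values)
}

#' Project a trajectory onto a principal component
#'
#' Frames are superposed onto the model's mean structure over the model's
#' selection, mean-centered with the model's mean, and dotted with the
#' chosen eigenvector.
#'
#' @param traj a `Trajectory` sharing the model's atom table, or a pooled
#'   alignment from [pool_align()] (used as-is, no re-alignment).
#' @param model a `PCAModel`.
#' @param mode_index 1-based mode number.
#' @return An object of class `ProjectionSeries`: list with `values`
#'   (per-frame projections, Angstrom), `mean` and `mode_index`.
#' @export
project_pc <- function(traj, model, mode_index = 1L) {
  if (mode_index < 1L || mode_index > length(model$values))
    stop("model error: mode index out of range")
  xc <- .centered_coords(traj, model)
  p <- as.vector(xc %*% model$vectors[, mode_index])
  structure(list(values = p, mean = mean(p), mode_index = mode_index),
            class = "ProjectionSeries")
}

## frames x 3n selection coordinates aligned to and centered on the model mean
.centered_coords <- function(traj, model) {
  n3 <- length(model$mean)
  if (is.list(traj) && !inherits(traj, "Trajectory") && !is.null(traj$xyz) &&
      !is.null(traj$mean)) {
    x <- traj$xyz[, .xyz_cols(model$sel_idx), drop = FALSE]
  } else {
    traj <- if (inherits(traj, "Trajectory")) traj else
      stop("model error: expected a Trajectory or pool_align() result")
    if (3L * n_atoms(traj) < max(.xyz_cols(model$sel_idx)))
      stop("model error: trajectory dimension does not match the model")
    ref_full <- matrix(NA_real_, n_atoms(traj), 3L)
    ref_full[model$sel_idx, ] <- matrix(model$mean, ncol = 3L, byrow = TRUE)
    x <- matrix(0, n_frames(traj), n3)
    for (t in seq_len(n_frames(traj))) {
      fr <- frame_coords(traj, t)
      fit <- superpose(fr[model$sel_idx, , drop = FALSE],
                       ref_full[model$sel_idx, , drop = FALSE])
      x[t, ] <- .flatten_coords(apply_transform(
        fr[model$sel_idx, , drop = FALSE], fit))
    }
  }
  if (ncol(x) != n3) stop("model error: dimension mismatch")
  sweep(x, 2L, model$mean)
}

#' RMSF along a principal component
#'
#' The scalar fluctuation of the projection,
#' `sqrt(mean_t (P_t - <P>)^2)`, plus the per-residue RMSF profile of the
#' rank-1 reconstructed trajectory `<x> + P_t * U_mode` (each residue's
#' contribution to the mode's motion).
#'
#' @inheritParams project_pc
#' @return list with `scalar` (Angstrom), `profile` (data.frame: `chain`,
#'   `res_id`, `res_name`, `rmsf`), and `projection` (the
#'   `ProjectionSeries`).
#' @export
rmsf_along_pc <- function(traj, model, mode_index = 1L) {
  proj <- project_pc(traj, model, mode_index)
  p <- proj$values
  scalar <- sqrt(mean((p - mean(p))^2))
  u <- model$vectors[, mode_index]
  per_atom_norm <- sqrt(u[c(TRUE, FALSE, FALSE)]^2 +
                        u[c(FALSE, TRUE, FALSE)]^2 +
                        u[c(FALSE, FALSE, TRUE)]^2)
  at <- model$atoms
  profile <- data.frame(chain = at$chain, res_id = at$res_id,
                        res_name = at$res_name,
                        rmsf = scalar * per_atom_norm,
                        stringsAsFactors = FALSE)
  list(scalar = scalar, profile = profile, projection = proj)
}

#' Root-mean-square inner product of two PC subspaces
#'
#' `RMSIP = sqrt( (1/k) * sum_{i<=k} sum_{j<=k} (U_a,i . U_b,j)^2 )`,
#' the standard overlap of the leading essential subspaces; 1 means
#' identical dominant motions, 0 means orthogonal.
#'
#' @param model_a,model_b `PCAModel`s of equal dimension.
#' @param k number of leading modes to compare (default 5).
#' @return An object of class `SubspaceOverlap`: list with `rmsip` and `k`.
#' @export
rmsip <- function(model_a, model_b, k = 5L) {
  if (k > length(model_a$values) || k > length(model_b$values))
    stop("configuration error: k exceeds available modes")
  ua <- model_a$vectors[, seq_len(k), drop = FALSE]
  ub <- model_b$vectors[, seq_len(k), drop = FALSE]
  if (nrow(ua) != nrow(ub)) stop("model error: dimension mismatch")
  val <- sqrt(sum((crossprod(ua, ub))^2) / k)
  structure(list(rmsip = val, k = k), class = "SubspaceOverlap")
}

#' @export
print.SubspaceOverlap <- function(x, ...) {
  cat(sprintf("RMSIP over first %d modes: %.3f\n", x$k, x$rmsip))
  invisible(x)
}
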