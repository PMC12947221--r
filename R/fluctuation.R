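#' Per-frame RMSD time series
#'
#' Every frame is superposed on the chosen reference frame over
#' `align_sel`; RMSD is then measured over `measure_sel`.  This is the
#' standard "All / Core / ICL3" style deviation trace: align on a stable
#' selection, measure on the region of interest.
#'
#' @param traj a `Trajectory`.
#' @param align_sel `Selection` used for the superposition fit.
#' @param measure_sel `Selection` over which RMSD is evaluated
#'   (default: the alignment selection).
#' @param reference_frame 1-based index of the reference frame (default 1).
#' @param label region label stored with the series.
#' @return An object of class `RMSDSeries`: list with `values` (Angstrom,
#'   one per frame), `time_ns`, `label`, `align_label`.
#' @export
rmsd_series <- function(traj, align_sel = NULL, measure_sel = align_sel,
                        reference_frame = 1L, label = "All") {
  if (reference_frame < 1L || reference_frame > n_frames(traj))
    stop("index error: reference frame ", reference_frame,
         " out of range [1, ", n_frames(traj), "]")
  ai <- .sel_idx(traj, align_sel)
  mi <- .sel_idx(traj, measure_sel)
  ref <- frame_coords(traj, reference_frame)
  vals <- vapply(seq_len(n_frames(traj)), function(t) {
    fr <- frame_coords(traj, t)
    fit <- superpose(fr, ref, sel = ai)
    fitted <- apply_transform(fr, fit)
    .raw_rmsd(fitted[mi, , drop = FALSE], ref[mi, , drop = FALSE])
  }, numeric(1))
  structure(list(values = vals,
                 time_ns = (seq_len(n_frames(traj)) - 1L) * traj$frame_spacing,
                 label = label,
                 align_label = if (inherits(align_sel, "Selection"))
                   align_sel$label else "all"),
            class = "RMSDSeries")
}

#' @export
print.RMSDSeries <- function(x, ...) {
  cat(sprintf("RMSDSeries [%s]: %d frames, mean %.2f A, max %.2f A\n",
              x$label, length(x$values), mean(x$values), max(x$values)))
  invisible(x)
}

#' Per-residue RMSF profile of a pooled ensemble
#'
#' Frames from all replicates are pooled and aligned to the iterated pooled
#' mean (see [pool_align()]); `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)`
#' for each selected atom.
#'
#' @param ensemble a `Trajectory` or list of replicates sharing one atom
#'   table.
#' @param sel `Selection` of atoms to report (typically the C-alpha set).
#' @param align_sel selection used for the alignment fit (default `sel`).
#' @return An object of class `RMSFProfile`: data.frame with `chain`,
#'   `res_id`, `res_name`, `atom`, `rmsf` plus attributes `n_frames`,
#'   `n_replicates`, `window` (NULL here).
#' @export
rmsf_profile <- function(ensemble, sel = NULL, align_sel = sel) {
  pooled <- pool_align(ensemble, align_sel = align_sel)
  .rmsf_from_pooled(pooled, sel)
}

.rmsf_from_pooled <- function(pooled, sel, window = NULL) {
  idx <- if (is.null(sel)) seq_len(nrow(pooled$atoms)) else
    if (inherits(sel, "Selection")) sel$indices else as.integer(sel)
  dev2 <- sweep(pooled$xyz, 2L, pooled$mean)^2
  msf3 <- colMeans(dev2)                      # per-coordinate mean squares
  msf <- msf3[c(TRUE, FALSE, FALSE)] + msf3[c(FALSE, TRUE, FALSE)] +
    msf3[c(FALSE, FALSE, TRUE)]               # per-atom
  at <- pooled$atoms[idx, , drop = FALSE]
  out <- data.frame(chain = at$chain, res_id = at$res_id,
                    res_name = at$res_name, atom = at$name,
                    rmsf = sqrt(msf[idx]), stringsAsFactors = FALSE)
  attr(out, "n_frames") <- nrow(pooled$xyz)
  attr(out, "n_replicates") <- length(unique(pooled$frame_origin))
  attr(out, "window") <- window
  class(out) <- c("RMSFProfile", "data.frame")
  out
}

#' Windowed RMSF profiles for convergence QC
#'
#' Splits each replicate into non-overlapping consecutive windows of
#' `window_ns` (a positive multiple of the frame spacing; the trailing
#' partial window is dropped) and computes one pooled [rmsf_profile()] per
#' window.  The summary table reports, per residue, the across-window mean
#' and standard deviation of RMSF, the usual stationarity diagnostic.
#'
#' @param ensemble a `Trajectory` or list of replicates.
#' @param sel `Selection` of atoms to profile.
#' @param window_ns window duration in ns (e.g. 25).
#' @return list with `profiles` (one `RMSFProfile` per window, with window
#'   bounds in the `window` attribute) and `summary` (data.frame with
#'   per-residue across-window mean/sd of RMSF).
#' @export
windowed_rmsf <- function(ensemble, sel = NULL, window_ns) {
  trajs <- .as_ensemble(ensemble)
  spacing <- trajs[[1L]]$frame_spacing
  ratio <- window_ns / spacing
  if (window_ns <= 0 || abs(ratio - round(ratio)) > 1e-9)
    stop("configuration error: window_ns must be a positive multiple of the frame spacing")
  wlen <- as.integer(round(ratio))
  if (wlen < 2L)
    stop("configuration error: window shorter than 2 frames")
  nf <- min(vapply(trajs, n_frames, integer(1)))
  nwin <- nf %/% wlen
  if (nwin < 1L) stop("configuration error: no complete window fits")

  profiles <- vector("list", nwin)
  for (w in seq_len(nwin)) {
    fr <- ((w - 1L) * wlen + 1L):(w * wlen)
    sub <- lapply(trajs, function(tr)
      trajectory(tr$atoms, tr$xyz[fr, , drop = FALSE], spacing))
    prof <- rmsf_profile(sub, sel = sel)
    attr(prof, "window") <- c(start_ns = (fr[1L] - 1L) * spacing,
                              end_ns = fr[length(fr)] * spacing)
    profiles[[w]] <- prof
  }
  mat <- vapply(profiles, function(p) p$rmsf, numeric(nrow(profiles[[1L]])))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  summ <- data.frame(profiles[[1L]][, c("chain", "res_id", "res_name")],
                     mean_rmsf = rowMeans(mat),
                     sd_rmsf = apply(mat, 1L, stats::sd),
                     stringsAsFactors = FALSE)
  list(profiles = profiles, summary = summ)
}

#' Difference between two RMSF profiles
#'
#' `delta = a - b` per residue, with the maximum absolute difference per
#' named region when `regions` is supplied.
#'
#' @param profile_a,profile_b `RMSFProfile` objects on identical residue
#'   lists (e.g. a perturbed condition and its control).
#' @param regions optional named list of residue-id vectors; the result
#'   then carries a `region_max` attribute with `max |delta|` per region.
#' @return data.frame with `chain`, `res_id`, `res_name`, `delta_rmsf`.
#' @export
delta_rmsf <- function(profile_a, profile_b, regions = NULL) {
  if (nrow(profile_a) != nrow(profile_b) ||
      !all(profile_a$res_id == profile_b$res_id &
           profile_a$chain == profile_b$chain))
    stop("alignment error: profiles cover different residues")
  out <- data.frame(profile_a[, c("chain", "res_id", "res_name")],
                    delta_rmsf = profile_a$rmsf - profile_b$rmsf,
                    stringsAsFactors = FALSE)
  if (!is.null(regions)) {
    attr(out, "region_max") <- vapply(regions, function(rr)
      max(abs(out$delta_rmsf[out$res_id %in% rr])), numeric(1))
  }
  out
}

#' Scalar fluctuation series per residue
#'
#' For each selected atom, `deltaR_i(t) = |r_i(t) - <r_i>|`, the norm of
#' the displacement from the ensemble-mean position after alignment.  These
#' scalar series are the inputs of the adaptive-binning entropy and mutual
#' information estimators.
#'
#' @param pooled result of [pool_align()].
#' @param sel `Selection` of atoms (typically C-alpha, one per residue).
#' @return numeric matrix, pooled frames x selected atoms, with residue ids
#'   as column names; class `FluctuationSeries`.
#' @export
fluctuation_series <- function(pooled, sel = NULL) {
  idx <- if (is.null(sel)) seq_len(nrow(pooled$atoms)) else
    if (inherits(sel, "Selection")) sel$indices else as.integer(sel)
  dev <- sweep(pooled$xyz, 2L, pooled$mean)
  out <- matrix(0, nrow(pooled$xyz), length(idx))
  for (k in seq_along(idx)) {
    cols <- (3L * idx[k] - 2L):(3L * idx[k])
    out[, k] <- sqrt(rowSums(dev[, cols, drop = FALSE]^2))
  }
  colnames(out) <- paste0(pooled$atoms$chain[idx], pooled$atoms$res_id[idx])
  attr(out, "res_id") <- pooled$atoms$res_id[idx]
  attr(out, "chain") <- pooled$atoms$chain[idx]
  attr(out, "res_name") <- pooled$atoms$res_name[idx]
  class(out) <- c("FluctuationSeries", "matrix", "array")
  out
}
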