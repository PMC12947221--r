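#' Optimize the number of histogram bins for a fluctuation series
#'
#' Scans `N_bins = 2, 3, ...` over equal-width bins spanning the series
#' range and returns the smallest bin count whose relative entropy gain
#' satisfies `(H(N+1) - H(N)) / H(N) <= tol`.  The scan is capped at
#' `sqrt(N_c)` bins so small samples cannot chase noise.  A constant
#' series yields a single-bin spec flagged `constant` with `H = 0`.
#'
#' @param series numeric vector (e.g. one residue's scalar fluctuations).
#' @param tol convergence tolerance on the relative entropy gain
#'   (default 0.02).
#' @param cap maximum bin count (default `floor(sqrt(length(series)))`).
#' @return list of class `BinSpec`: `n_bins`, `width`, `range`,
#'   `constant`, `capped`, and `trace` (data.frame of the scanned
#'   `n_bins`/`H` values in bits).
#' @export
optimize_bins <- function(series, tol = 0.02, cap = NULL) {
  n_c <- length(series)
  if (n_c < 2L) stop("data error: need at least 2 samples")
  rng <- range(series)
  if (rng[1L] == rng[2L]) {
    return(structure(list(n_bins = 1L, width = 0, range = rng,
                          constant = TRUE, capped = FALSE,
                          trace = data.frame(n_bins = 1L, H = 0)),
                     class = "BinSpec"))
  }
  if (is.null(cap)) cap <- max(2L, as.integer(floor(sqrt(n_c))))
  h_of <- function(nb) .entropy_counts(.bin_counts(series, rng, nb))$H
  trace_n <- integer(0); trace_h <- numeric(0)
  h_prev <- h_of(2L)
  trace_n <- 2L; trace_h <- h_prev
  chosen <- NA_integer_
  nb <- 2L
  while (nb < cap) {
    h_next <- h_of(nb + 1L)
    trace_n <- c(trace_n, nb + 1L); trace_h <- c(trace_h, h_next)
    if (h_prev > 0 && (h_next - h_prev) / h_prev <= tol) {
      chosen <- nb
      break
    }
    h_prev <- h_next
    nb <- nb + 1L
  }
  capped <- is.na(chosen)
  if (capped) chosen <- cap
  structure(list(n_bins = chosen, width = diff(rng) / chosen, range = rng,
                 constant = FALSE, capped = capped,
                 trace = data.frame(n_bins = trace_n, H = trace_h)),
            class = "BinSpec")
}

#' @export
print.BinSpec <- function(x, ...) {
  cat("BinSpec:", x$n_bins, "bins, width", format(x$width, digits = 4),
      if (x$constant) "(constant series)" else "",
      if (x$capped) "(capped)" else "", "\n")
  invisible(x)
}

## equal-width bin assignment over a fixed range; the maximum falls in the
## last bin (half-open bins, closed on the right edge of the range)
.discretize <- function(series, binspec) {
  if (binspec$constant || binspec$n_bins == 1L)
    return(rep(1L, length(series)))
  rng <- binspec$range
  b <- floor((series - rng[1L]) / binspec$width) + 1L
  pmin(pmax(as.integer(b), 1L), binspec$n_bins)
}

.bin_counts <- function(series, rng, nb) {
  w <- diff(rng) / nb
  b <- pmin(pmax(as.integer(floor((series - rng[1L]) / w)) + 1L, 1L), nb)
  tabulate(b, nbins = nb)
}

## Shannon entropy (bits) of a count vector, with occupied-bin count
.entropy_counts <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0L] / n
  list(H = -sum(p * log2(p)), n_occupied = length(p), n = n)
}

#' Finite-sample-corrected entropy of a binned series
#'
#' Observed Shannon entropy `H = -sum p log2 p` over occupied bins, plus
#' the finite-sampling correction `(N_b - 1) / N_c` added as printed,
#' where `N_b` is the occupied-bin count and `N_c` the sample count.
#'
#' @param series numeric vector, or integer state vector when `binspec`
#'   is omitted (categorical mode).
#' @param binspec a [optimize_bins()] result (omit for categorical input).
#' @return list of class `EntropyEstimate`: `H` (observed, bits),
#'   `H_corrected`, `n_occupied`, `n_samples`, `correction`.
#' @export
entropy_estimate <- function(series, binspec = NULL) {
  counts <- if (is.null(binspec)) tabulate(as.integer(series))
            else tabulate(.discretize(series, binspec),
                          nbins = binspec$n_bins)
  e <- .entropy_counts(counts)
  corr <- (e$n_occupied - 1) / e$n
  structure(list(H = e$H, H_corrected = e$H + corr,
                 n_occupied = e$n_occupied, n_samples = e$n,
                 correction = corr),
            class = "EntropyEstimate")
}

#' @export
print.EntropyEstimate <- function(x, ...) {
  cat(sprintf("EntropyEstimate: H = %.4f bits (corrected %.4f; N_b = %d, N_c = %d)\n",
              x$H, x$H_corrected, x$n_occupied, x$n_samples))
  invisible(x)
}

## corrected MI between two integer-coded series (the shared engine for
## the continuous-fluctuation and categorical-rotamer paths).
## correction = (N_b(i,j) - N_b(i) - N_b(j) + 1) / (2 N_c), subtracted;
## negative corrected values are finite-sample artifacts, floored at 0.
.mi_discrete <- function(di, dj, ni, nj) {
  n_c <- length(di)
  joint <- tabulate((di - 1L) * nj + dj, nbins = ni * nj)
  ci <- tabulate(di, nbins = ni)
  cj <- tabulate(dj, nbins = nj)
  pj <- joint / n_c
  occ <- which(joint > 0L)
  rows <- ((occ - 1L) %/% nj) + 1L
  cols <- ((occ - 1L) %% nj) + 1L
  mi_obs <- sum(pj[occ] * log2(pj[occ] /
                               ((ci[rows] / n_c) * (cj[cols] / n_c))))
  nb_ij <- length(occ)
  nb_i <- sum(ci > 0L)
  nb_j <- sum(cj > 0L)
  correction <- (nb_ij - nb_i - nb_j + 1) / (2 * n_c)
  corrected <- mi_obs - correction
  list(mi = max(0, corrected), mi_observed = mi_obs,
       correction = correction, floored = corrected < 0,
       nb_i = nb_i, nb_j = nb_j, nb_ij = nb_ij, n_c = n_c)
}

#' Finite-sample-corrected mutual information of two fluctuation series
#'
#' Builds the 2-D joint histogram of the two binned scalar series, computes
#' the observed MI in bits, and subtracts the finite-sampling correction
#' `(N_b(i,j) - N_b(i) - N_b(j) + 1) / (2 N_c)` derived from the entropy
#' correction applied to `MI = H_i + H_j - H_ij`.  Negative corrected
#' values are floored at 0 and flagged.
#'
#' @param series_i,series_j numeric vectors of equal length.
#' @param binspec_i,binspec_j [optimize_bins()] results for each series
#'   (computed on the fly when omitted).
#' @param details return the full detail list instead of the scalar.
#' @return corrected MI in bits, with the detail list (observed MI,
#'   correction, occupied-bin counts, floor flag) as attribute `"detail"`;
#'   or the detail list itself when `details = TRUE`.
#' @export
mi_calpha <- function(series_i, series_j, binspec_i = NULL,
                      binspec_j = NULL, details = FALSE) {
  if (length(series_i) != length(series_j))
    stop("data error: series lengths differ")
  if (is.null(binspec_i)) binspec_i <- optimize_bins(series_i)
  if (is.null(binspec_j)) binspec_j <- optimize_bins(series_j)
  d <- .mi_discrete(.discretize(series_i, binspec_i),
                    .discretize(series_j, binspec_j),
                    binspec_i$n_bins, binspec_j$n_bins)
  if (details) return(d)
  structure(d$mi, detail = d)
}

#' Residue-pair MI matrix from C-alpha fluctuations
#'
#' Pools and aligns the ensemble (see [pool_align()]), builds each
#' residue's scalar fluctuation series `|r_i(t) - <r_i>|`, optimizes its
#' binning, and fills the symmetric corrected-MI matrix over all residue
#' pairs.  The diagonal holds each residue's corrected entropy.
#'
#' @param ensemble a `Trajectory` or list of replicates.
#' @param sel `Selection` of one atom per residue (typically C-alpha);
#'   default: all `CA` atoms.
#' @param bin_tol convergence tolerance passed to [optimize_bins()].
#' @param min_sep sequence-separation default recorded for downstream
#'   distant-pair summaries (6 for the C-alpha network convention).
#' @return An object of class `MIMatrix`: list with `matrix` (bits),
#'   `residues`, `mode = "calpha"`, `n_c`, `binspecs`, `n_floored`,
#'   `min_sep`.
#' @export
mi_matrix_calpha <- function(ensemble, sel = NULL, bin_tol = 0.02,
                             min_sep = 6L) {
  trajs <- .as_ensemble(ensemble)
  if (is.null(sel)) sel <- select_atoms(trajs[[1L]], name = "CA")
  pooled <- pool_align(trajs, align_sel = sel)
  fl <- fluctuation_series(pooled, sel)
  n_res <- ncol(fl)
  binspecs <- lapply(seq_len(n_res), function(k) optimize_bins(fl[, k], tol = bin_tol))
  disc <- vapply(seq_len(n_res), function(k) .discretize(fl[, k], binspecs[[k]]),
                 integer(nrow(fl)))
  m <- matrix(0, n_res, n_res)
  n_floored <- 0L
  for (i in seq_len(n_res)) {
    ei <- entropy_estimate(disc[, i])
    m[i, i] <- ei$H_corrected
    if (i < n_res) for (j in (i + 1L):n_res) {
      d <- .mi_discrete(disc[, i], disc[, j],
                        binspecs[[i]]$n_bins, binspecs[[j]]$n_bins)
      m[i, j] <- m[j, i] <- d$mi
      if (d$floored) n_floored <- n_floored + 1L
    }
  }
  residues <- data.frame(chain = attr(fl, "chain"),
                         res_id = attr(fl, "res_id"),
                         res_name = attr(fl, "res_name"),
                         stringsAsFactors = FALSE)
  lab <- paste0(residues$chain, residues$res_id)
  dimnames(m) <- list(lab, lab)
  structure(list(matrix = m, residues = residues, mode = "calpha",
                 n_c = nrow(fl), binspecs = binspecs,
                 n_floored = n_floored, min_sep = min_sep),
            class = "MIMatrix")
}

#' @export
print.MIMatrix <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  cat("MIMatrix [", x$mode, "]: ", nrow(x$matrix), " residues, N_c = ",
      x$n_c, ", mean off-diagonal MI = ",
      sprintf("%.4f bits", mean(off, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' Corrected mutual information between two residues' rotamer states
#'
#' For every dihedral pair (one from each residue) the categorical MI of
#' the two state series is computed with the same finite-sampling
#' correction as the continuous path, using occupied-state counts.  The
#' residue-pair value aggregates the per-pair values.
#'
#' @param states_i,states_j `RotamerStateSeries` matrices from
#'   [assign_rotamer_states()] (frames x dihedrals; zero columns means the
#'   residue has no usable dihedral).
#' @param aggregate `"sum"` (default), `"max"` or `"mean"` over dihedral
#'   pairs.
#' @return aggregated corrected MI in bits with attribute `pairs` (the
#'   per-dihedral-pair detail data.frame), or `NA` flagged with attribute
#'   `absent = TRUE` when no usable dihedral pair exists.
#' @export
mi_dihedral <- function(states_i, states_j,
                        aggregate = c("sum", "max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.null(dim(states_i))) states_i <- matrix(states_i, ncol = 1L)
  if (is.null(dim(states_j))) states_j <- matrix(states_j, ncol = 1L)
  if (ncol(states_i) == 0L || ncol(states_j) == 0L)
    return(structure(NA_real_, absent = TRUE))
  if (nrow(states_i) != nrow(states_j))
    stop("data error: state series lengths differ")
  rows <- list()
  for (a in seq_len(ncol(states_i))) for (b in seq_len(ncol(states_j))) {
    di <- states_i[, a]; dj <- states_j[, b]
    d <- .mi_discrete(di, dj, max(di), max(dj))
    rows[[length(rows) + 1L]] <- data.frame(
      dihedral_i = colnames(states_i)[a] %||% a,
      dihedral_j = colnames(states_j)[b] %||% b,
      mi = d$mi, mi_observed = d$mi_observed, floored = d$floored,
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  val <- switch(aggregate, sum = sum(pairs$mi), max = max(pairs$mi),
                mean = mean(pairs$mi))
  structure(val, pairs = pairs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Residue-pair MI matrix from dihedral rotamer states
#'
#' Computes [mi_dihedral()] for residue pairs more than `min_sep` apart in
#' sequence (author numbering); closer pairs and the diagonal are `NA`
#' (excluded, not zero).
#'
#' @param states_list named list of `RotamerStateSeries`, one per residue,
#'   in sequence order.
#' @param residues data.frame with `chain`, `res_id`, `res_name` matching
#'   `states_list`.
#' @param min_sep minimum sequence separation (default 5: distant-pair
#'   summaries use `|i - j| > 5`).
#' @param aggregate dihedral-pair reduction passed to [mi_dihedral()].
#' @return An `MIMatrix` with `mode = "dihedral"`.
#' @export
mi_matrix_dihedral <- function(states_list, residues, min_sep = 5L,
                               aggregate = "sum") {
  n <- length(states_list)
  if (n != nrow(residues)) stop("residues table does not match states list")
  m <- matrix(NA_real_, n, n)
  n_c <- NA_integer_
  for (i in seq_len(n)) {
    if (!is.null(dim(states_list[[i]])) && ncol(states_list[[i]]) > 0L)
      n_c <- nrow(states_list[[i]])
    if (i >= n) break
    for (j in (i + 1L):n) {
      if (abs(residues$res_id[i] - residues$res_id[j]) <= min_sep) next
      v <- mi_dihedral(states_list[[i]], states_list[[j]],
                       aggregate = aggregate)
      m[i, j] <- m[j, i] <- as.numeric(v)
    }
  }
  lab <- paste0(residues$chain, residues$res_id)
  dimnames(m) <- list(lab, lab)
  structure(list(matrix = m, residues = residues, mode = "dihedral",
                 n_c = n_c, binspecs = NULL, n_floored = NA_integer_,
                 min_sep = min_sep, aggregate = aggregate),
            class = "MIMatrix")
}
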