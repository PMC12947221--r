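#' Geometric hydrogen-bond criteria
#'
#' A donor--hydrogen--acceptor triple is counted when the H--acceptor
#' distance is at most `dist_max` and the D-H-A angle is at least
#' `angle_min`.  Bonds seen in fewer than `min_freq` of the pooled frames
#' are discarded as rare stochastic contacts.
#'
#' @param angle_min minimum D-H-A angle in degrees (default 120).
#' @param dist_max maximum H--acceptor distance in Angstrom (default 2.5).
#' @param min_freq minimum fraction of frames (default 0.001).
#' @return list of class `HBondCriteria`.
#' @export
hbond_criteria <- function(angle_min = 120, dist_max = 2.5,
                           min_freq = 0.001) {
  if (angle_min <= 0 || angle_min > 180) stop("angle_min must be in (0, 180]")
  if (dist_max <= 0) stop("dist_max must be positive")
  if (min_freq < 0 || min_freq > 1) stop("min_freq must be in [0, 1]")
  structure(list(angle_min = angle_min, dist_max = dist_max,
                 min_freq = min_freq), class = "HBondCriteria")
}

## donor table: N/O heavy atoms with a covalently bonded hydrogen, the bond
## inferred by an H within `bond_max` Angstrom in the same residue.  The
## geometry is taken from one frame; covalent topology is frame-invariant.
.donor_table <- function(traj, frame = 1L, bond_max = 1.2) {
  at <- traj$atoms
  h_idx <- which(at$element == "H")
  if (length(h_idx) == 0L)
    stop("no hydrogens: hydrogen-bond detection requires explicit H atoms")
  heavy_no <- which(at$element %in% c("N", "O"))
  co <- frame_coords(traj, frame)
  res_key <- paste(at$chain, at$res_id)
  pairs <- NULL
  for (h in h_idx) {
    cand <- heavy_no[res_key[heavy_no] == res_key[h]]
    if (length(cand) == 0L) next
    d <- sqrt(colSums((t(co[cand, , drop = FALSE]) - co[h, ])^2))
    j <- which(d <= bond_max)
    if (length(j) == 0L) next
    pairs <- rbind(pairs, c(donor = cand[which.min(d)], h = h))
  }
  if (is.null(pairs))
    stop("no hydrogens: no N/O-bound hydrogen found (H within 1.2 A)")
  as.data.frame(pairs)
}

#' Detect hydrogen bonds in one frame
#'
#' Donors are N/O atoms with a covalently bonded hydrogen (H within 1.2 A
#' in the same residue); acceptors are all O and N atoms.  A triple is
#' emitted iff the H--acceptor distance and the D-H-A angle satisfy
#' `criteria`.  Triples whose donor and acceptor share a residue are
#' flagged `intra_residue`.
#'
#' @param traj a `Trajectory` with hydrogens.
#' @param frame 1-based frame index.
#' @param criteria an [hbond_criteria()] object.
#' @param donors optional precomputed donor table (internal reuse).
#' @return data.frame with atom indices `donor`, `h`, `acceptor`, the
#'   geometric `dist` and `angle`, and `intra_residue`.
#' @export
detect_hbonds_frame <- function(traj, frame = 1L,
                                criteria = hbond_criteria(),
                                donors = NULL) {
  at <- traj$atoms
  if (is.null(donors)) donors <- .donor_table(traj)
  acc_idx <- which(at$element %in% c("N", "O"))
  co <- frame_coords(traj, frame)
  out <- vector("list", nrow(donors))
  for (r in seq_len(nrow(donors))) {
    d <- donors$donor[r]; h <- donors$h[r]
    acc <- acc_idx[acc_idx != d]
    ha <- sweep(co[acc, , drop = FALSE], 2L, co[h, ])
    dist <- sqrt(rowSums(ha^2))
    ok <- dist <= criteria$dist_max
    if (!any(ok)) next
    acc <- acc[ok]; ha <- ha[ok, , drop = FALSE]; dist <- dist[ok]
    hd <- co[d, ] - co[h, ]
    cosang <- (ha %*% hd) / (dist * sqrt(sum(hd^2)))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    ok2 <- ang >= criteria$angle_min
    if (!any(ok2)) next
    out[[r]] <- data.frame(donor = d, h = h, acceptor = acc[ok2],
                           dist = dist[ok2], angle = ang[ok2])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(donor = integer(), h = integer(), acceptor = integer(),
                      dist = numeric(), angle = numeric())
  res$intra_residue <- paste(at$chain[res$donor], at$res_id[res$donor]) ==
    paste(at$chain[res$acceptor], at$res_id[res$acceptor])
  res
}

#' Hydrogen-bond occupancy table for an ensemble
#'
#' Detects bonds in every frame of every trajectory, pools the counts
#' across the condition's replicates, and keeps triples whose occupancy
#' (frames containing the triple / total pooled frames) reaches
#' `criteria$min_freq`.  Hydrogens of a multi-H donor (e.g. a lysine
#' ammonium) give distinct records.
#'
#' @param ensemble a `Trajectory` or list of replicates with hydrogens.
#' @param criteria an [hbond_criteria()] object.
#' @return An object of class `HBondTable`: list with
#'   \describe{
#'     \item{records}{per-bond data.frame: donor/H/acceptor atom keys,
#'       `occupancy`, `n_frames`, per-replicate occupancies.}
#'     \item{by_residue}{per-residue aggregates: records as donor, records
#'       as acceptor, occupancy-weighted sums, `unique_acceptors` (distinct
#'       partner residues as donor), and `persistence` (mean occupancy of
#'       the residue's surviving bonds, either role).}
#'     \item{n_frames_total}{pooled frame count.}
#'   }
#' @export
hbond_table <- function(ensemble, criteria = hbond_criteria()) {
  trajs <- .as_ensemble(ensemble)
  if (length(trajs) == 0L || sum(vapply(trajs, n_frames, integer(1))) == 0L)
    stop("data error: empty ensemble")
  .check_same_atoms(trajs)
  at <- trajs[[1L]]$atoms
  donors <- .donor_table(trajs[[1L]])

  counts <- new.env(parent = emptyenv())
  per_rep <- list()
  total <- 0L
  for (k in seq_along(trajs)) {
    rep_counts <- new.env(parent = emptyenv())
    tr <- trajs[[k]]
    for (t in seq_len(n_frames(tr))) {
      hits <- detect_hbonds_frame(tr, t, criteria, donors = donors)
      if (nrow(hits) == 0L) next
      keys <- paste(hits$donor, hits$h, hits$acceptor, sep = "|")
      for (key in keys) {
        counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
        rep_counts[[key]] <- (if (is.null(rep_counts[[key]])) 0L
                              else rep_counts[[key]]) + 1L
      }
    }
    per_rep[[k]] <- rep_counts
    total <- total + n_frames(tr)
  }

  keys <- ls(counts)
  if (length(keys) > 0L) {
    n <- vapply(keys, function(k) counts[[k]], integer(1))
    occ <- n / total
    keep <- occ >= criteria$min_freq
    keys <- keys[keep]; n <- n[keep]; occ <- occ[keep]
  }
  if (length(keys) == 0L) {
    records <- data.frame(
      donor_chain = character(), donor_res = integer(),
      donor_res_name = character(), donor_atom = character(),
      h_atom = character(), acceptor_chain = character(),
      acceptor_res = integer(), acceptor_res_name = character(),
      acceptor_atom = character(), occupancy = numeric(),
      n_frames = integer(), stringsAsFactors = FALSE)
  } else {
    idx <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    storage.mode(idx) <- "integer"
    records <- data.frame(
      donor_chain = at$chain[idx[, 1L]], donor_res = at$res_id[idx[, 1L]],
      donor_res_name = at$res_name[idx[, 1L]],
      donor_atom = at$name[idx[, 1L]], h_atom = at$name[idx[, 2L]],
      acceptor_chain = at$chain[idx[, 3L]],
      acceptor_res = at$res_id[idx[, 3L]],
      acceptor_res_name = at$res_name[idx[, 3L]],
      acceptor_atom = at$name[idx[, 3L]],
      occupancy = occ, n_frames = n,
      stringsAsFactors = FALSE
    )
    for (k in seq_along(trajs)) {
      nk <- vapply(keys, function(key) {
        v <- per_rep[[k]][[key]]; if (is.null(v)) 0L else v
      }, integer(1))
      records[[paste0("occ_rep", k)]] <- nk / n_frames(trajs[[k]])
    }
    rownames(records) <- NULL
    records <- records[order(records$donor_res, records$acceptor_res), ]
  }

  structure(list(records = records,
                 by_residue = .hbond_residue_aggregates(records, at),
                 n_frames_total = total,
                 criteria = criteria),
            class = "HBondTable")
}

.hbond_residue_aggregates <- function(records, at) {
  res <- unique(data.frame(chain = at$chain, res_id = at$res_id,
                           res_name = at$res_name, stringsAsFactors = FALSE))
  res <- res[order(res$chain, res$res_id), ]
  key <- function(ch, id) paste(ch, id)
  rk <- key(res$chain, res$res_id)
  agg <- data.frame(res,
                    n_as_donor = 0L, n_as_acceptor = 0L,
                    occ_as_donor = 0, occ_as_acceptor = 0,
                    unique_acceptors = 0L, persistence = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(records) == 0L) return(agg)
  dk <- key(records$donor_chain, records$donor_res)
  ak <- key(records$acceptor_chain, records$acceptor_res)
  for (i in seq_len(nrow(agg))) {
    as_d <- dk == rk[i]; as_a <- ak == rk[i]
    agg$n_as_donor[i] <- sum(as_d)
    agg$n_as_acceptor[i] <- sum(as_a)
    agg$occ_as_donor[i] <- sum(records$occupancy[as_d])
    agg$occ_as_acceptor[i] <- sum(records$occupancy[as_a])
    agg$unique_acceptors[i] <- length(unique(ak[as_d]))
    occ_any <- records$occupancy[as_d | as_a]
    agg$persistence[i] <- if (length(occ_any)) mean(occ_any) else NA_real_
  }
  agg
}

#' @export
print.HBondTable <- function(x, ...) {
  cat("HBondTable:", nrow(x$records), "surviving bonds over",
      x$n_frames_total, "pooled frames\n")
  invisible(x)
}
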