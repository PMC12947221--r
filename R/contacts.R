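#' Persistent heavy-atom contact map
#'
#' Two residues are in contact in a frame iff at least one pair of heavy
#' atoms (C, N, O, S; one from each residue) lies within `cutoff` Angstrom.
#' A contact is persistent iff its per-frame contact fraction over the
#' pooled ensemble reaches `persistence`.
#'
#' @param ensemble a `Trajectory` or list of replicates.
#' @param cutoff heavy-atom distance cutoff R_c in Angstrom (default 6.0).
#' @param persistence minimum frame fraction for a persistent contact
#'   (default 0.75).
#' @param res_id optional residue-id filter.
#' @return An object of class `ContactMap`: list with `contact` (logical
#'   residue x residue matrix, diagonal `FALSE`), `fraction` (per-pair
#'   contact fraction), `residues`, `cutoff`, `persistence`, `n_frames`.
#' @export
contact_map <- function(ensemble, cutoff = 6.0, persistence = 0.75,
                        res_id = NULL) {
  trajs <- .as_ensemble(ensemble)
  .check_same_atoms(trajs)
  at <- trajs[[1L]]$atoms
  heavy <- at$element %in% c("C", "N", "O", "S")
  if (!is.null(res_id)) heavy <- heavy & at$res_id %in% res_id
  if (!any(heavy)) stop("data error: no heavy atoms in selection")
  hidx <- which(heavy)
  rkey <- paste(at$chain[hidx], at$res_id[hidx])
  rlev <- unique(rkey)
  nres <- length(rlev)
  rfac <- match(rkey, rlev)
  atom_of_res <- split(seq_along(hidx), rfac)

  count <- matrix(0L, nres, nres)
  total <- 0L
  for (tr in trajs) {
    for (t in seq_len(n_frames(tr))) {
      co <- frame_coords(tr, t)[hidx, , drop = FALSE]
      dm <- as.matrix(stats::dist(co))
      for (i in seq_len(nres - 1L)) {
        ai <- atom_of_res[[i]]
        for (j in (i + 1L):nres) {
          if (min(dm[ai, atom_of_res[[j]]]) <= cutoff)
            count[i, j] <- count[i, j] + 1L
        }
      }
      total <- total + 1L
    }
  }
  frac <- (count + t(count)) / total
  contact <- frac >= persistence
  diag(contact) <- FALSE
  first_atom <- vapply(atom_of_res, function(v) hidx[v[1L]], integer(1))
  residues <- data.frame(chain = at$chain[first_atom],
                         res_id = at$res_id[first_atom],
                         res_name = at$res_name[first_atom],
                         stringsAsFactors = FALSE)
  lab <- paste0(residues$chain, residues$res_id)
  dimnames(contact) <- dimnames(frac) <- list(lab, lab)
  structure(list(contact = contact, fraction = frac, residues = residues,
                 cutoff = cutoff, persistence = persistence,
                 n_frames = total),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat("ContactMap:", nrow(x$contact), "residues,",
      sum(x$contact[upper.tri(x$contact)]), "persistent contacts",
      sprintf("(R_c %.1f A, persistence %.2f, %d frames)\n",
              x$cutoff, x$persistence, x$n_frames))
  invisible(x)
}

#' Persistent contacts as a pair list
#' @param cm a `ContactMap`.
#' @return data.frame with `res_i`, `res_j`, `fraction`.
#' @export
contact_pairs <- function(cm) {
  idx <- which(cm$contact & upper.tri(cm$contact), arr.ind = TRUE)
  data.frame(res_i = cm$residues$res_id[idx[, 1L]],
             res_j = cm$residues$res_id[idx[, 2L]],
             fraction = cm$fraction[idx],
             stringsAsFactors = FALSE)
}
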