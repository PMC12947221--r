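#' Define a microswitch metric
#'
#' A microswitch is either an atom-pair distance or a motif RMSD against a
#' reference (inactive-state) structure, optionally with an inactive-state
#' rule `value <comparator> threshold` in Angstrom.
#'
#' @param name metric name.
#' @param kind `"distance"` or `"rmsd"`.
#' @param atom1,atom2 for `kind = "distance"`: lists `list(res_id=, name=)`
#'   (optionally `chain=`) naming the two atoms.
#' @param residues for `kind = "rmsd"`: residue ids of the motif; its heavy
#'   atoms are used for both alignment and measurement.
#' @param comparator `"<"`, `">"` or `NA` (metric reported without a
#'   verdict).
#' @param threshold inactive-state threshold in Angstrom (`NA` if none).
#' @return list of class `MicroswitchDefinition`.
#' @export
microswitch <- function(name, kind = c("distance", "rmsd"),
                        atom1 = NULL, atom2 = NULL, residues = NULL,
                        comparator = NA_character_, threshold = NA_real_) {
  kind <- match.arg(kind)
  if (kind == "distance" && (is.null(atom1) || is.null(atom2)))
    stop("definition error: distance microswitch needs atom1 and atom2")
  if (kind == "rmsd" && (is.null(residues) || length(residues) == 0L))
    stop("definition error: rmsd microswitch needs a non-empty residue set")
  if (!is.na(threshold) && threshold <= 0)
    stop("definition error: threshold must be positive")
  structure(list(name = name, kind = kind, atom1 = atom1, atom2 = atom2,
                 residues = residues, comparator = comparator,
                 threshold = threshold),
            class = "MicroswitchDefinition")
}

#' Default beta2AR microswitch panel definitions
#'
#' The five canonical class-A GPCR microswitches plus the ECL2 disulfide
#' distance, with author residue numbers for beta2AR (Ballesteros--Weinstein
#' labels in comments).  Residue ids are plain arguments so the panel ports
#' to other receptors via a config table.
#'
#' @param ionic_lock,yy_gate,npxxy,pif,toggle,disulfide residue/atom ids
#'   overriding the beta2AR defaults.
#' @return list of [microswitch()] definitions.
#' @export
default_microswitches <- function(
    ionic_lock = list(res1 = 131, atom1 = "NH1", res2 = 268, atom2 = "OE2",
                      threshold = 10.5),               # R3.50 - E6.30
    yy_gate = list(res1 = 219, atom1 = "CZ", res2 = 326, atom2 = "CZ",
                   threshold = 14.6),                  # Y5.58 - Y7.53
    npxxy = list(residues = 322:327, threshold = 2.0), # N7.49 - C7.54
    pif = list(residues = c(121, 282), threshold = 2.2), # I3.40 + F6.44
    toggle = list(residues = c(286, 290)),             # W6.48 + F6.52
    disulfide = list(res1 = 106, atom1 = "CA", res2 = 191, atom2 = "CA")) {
  list(
    microswitch("ionic_lock", "distance",
                atom1 = list(res_id = ionic_lock$res1, name = ionic_lock$atom1),
                atom2 = list(res_id = ionic_lock$res2, name = ionic_lock$atom2),
                comparator = "<", threshold = ionic_lock$threshold),
    microswitch("yy_gate", "distance",
                atom1 = list(res_id = yy_gate$res1, name = yy_gate$atom1),
                atom2 = list(res_id = yy_gate$res2, name = yy_gate$atom2),
                comparator = ">", threshold = yy_gate$threshold),
    microswitch("npxxy", "rmsd", residues = npxxy$residues,
                comparator = "<", threshold = npxxy$threshold),
    microswitch("pif", "rmsd", residues = pif$residues,
                comparator = "<", threshold = pif$threshold),
    microswitch("toggle", "rmsd", residues = toggle$residues),
    microswitch("disulfide", "distance",
                atom1 = list(res_id = disulfide$res1, name = disulfide$atom1),
                atom2 = list(res_id = disulfide$res2, name = disulfide$atom2))
  )
}

.resolve_atom <- function(traj, spec, what) {
  at <- traj$atoms
  hit <- at$res_id == spec$res_id & at$name == spec$name
  if (!is.null(spec$chain)) hit <- hit & at$chain == spec$chain
  w <- which(hit)
  if (length(w) != 1L)
    stop("atom missing: ", what, " (res ", spec$res_id, ", atom ",
         spec$name, ") resolved to ", length(w), " atoms")
  w
}

#' Atom-pair distance series
#'
#' Plain Euclidean distance per frame, no alignment (distances are
#' rigid-motion invariant).
#'
#' @param traj a `Trajectory`.
#' @param def a `MicroswitchDefinition` of kind `"distance"`.
#' @return numeric vector, one distance (Angstrom) per frame.
#' @export
atom_pair_series <- function(traj, def) {
  if (def$kind != "distance") stop("definition error: not a distance switch")
  i <- .resolve_atom(traj, def$atom1, paste0(def$name, " atom1"))
  j <- .resolve_atom(traj, def$atom2, paste0(def$name, " atom2"))
  dx <- traj$xyz[, 3L * i - 2L] - traj$xyz[, 3L * j - 2L]
  dy <- traj$xyz[, 3L * i - 1L] - traj$xyz[, 3L * j - 1L]
  dz <- traj$xyz[, 3L * i] - traj$xyz[, 3L * j]
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Motif RMSD series against a reference structure
#'
#' Per frame, the motif's heavy atoms are superposed on the same atoms of
#' the reference and the RMSD is measured over the identical set
#' (alignment selection = measurement selection), the minimal reading of
#' "RMSD after alignment" for local-motif switches.
#'
#' @param traj a `Trajectory`.
#' @param def a `MicroswitchDefinition` of kind `"rmsd"`.
#' @param reference a one-frame `Trajectory` (the inactive structure);
#'   motif atoms are matched by `(chain, res_id, name)`.
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
motif_rmsd_series <- function(traj, def, reference) {
  if (def$kind != "rmsd") stop("definition error: not an rmsd switch")
  at <- traj$atoms
  sel_t <- which(at$res_id %in% def$residues &
                 at$element %in% c("C", "N", "O", "S"))
  if (length(sel_t) < 3L)
    stop("definition error: motif '", def$name, "' unresolvable in trajectory")
  ra <- reference$atoms
  key_t <- paste(at$chain[sel_t], at$res_id[sel_t], at$name[sel_t])
  key_r <- paste(ra$chain, ra$res_id, ra$name)
  m <- match(key_t, key_r)
  if (anyNA(m))
    stop("definition error: motif '", def$name,
         "' atoms missing in reference: ",
         paste(key_t[is.na(m)], collapse = ", "))
  ref_co <- frame_coords(reference, 1L)[m, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(t) {
    superpose(frame_coords(traj, t)[sel_t, , drop = FALSE], ref_co)$rmsd
  }, numeric(1))
}

#' Compute a microswitch panel over an ensemble
#'
#' Evaluates every definition on every trajectory, returning per-frame
#' series, per-trajectory median and IQR, and the inactive-state fraction
#' (fraction of pooled frames satisfying the definition's rule; `NA` for
#' report-only metrics).
#'
#' @param ensemble a `Trajectory` or list of replicates.
#' @param definitions list of [microswitch()] definitions
#'   (default [default_microswitches()]).
#' @param reference one-frame `Trajectory`, required by rmsd switches.
#' @return An object of class `MicroswitchPanel`: list with `series`
#'   (list: definition -> list of per-trajectory value vectors) and
#'   `summary` (data.frame: name, trajectory, median, iqr,
#'   inactive_fraction; plus a pooled row per definition).
#' @export
microswitch_panel <- function(ensemble, definitions = default_microswitches(),
                              reference = NULL) {
  trajs <- .as_ensemble(ensemble)
  if (length(definitions) == 0L)
    return(structure(list(series = list(),
                          summary = data.frame()),
                     class = "MicroswitchPanel"))
  series <- list()
  rows <- list()
  for (def in definitions) {
    per_traj <- lapply(trajs, function(tr) {
      if (def$kind == "distance") atom_pair_series(tr, def)
      else {
        if (is.null(reference))
          stop("definition error: rmsd switch '", def$name,
               "' needs a reference structure")
        motif_rmsd_series(tr, def, reference)
      }
    })
    series[[def$name]] <- per_traj
    verdict <- function(v) {
      if (is.na(def$comparator) || is.na(def$threshold)) return(NA_real_)
      if (def$comparator == "<") mean(v < def$threshold)
      else mean(v > def$threshold)
    }
    for (k in seq_along(per_traj)) {
      v <- per_traj[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        name = def$name, trajectory = k,
        median = stats::median(v), iqr = stats::IQR(v),
        inactive_fraction = verdict(v), stringsAsFactors = FALSE)
    }
    pooled <- unlist(per_traj)
    rows[[length(rows) + 1L]] <- data.frame(
      name = def$name, trajectory = NA_integer_,
      median = stats::median(pooled), iqr = stats::IQR(pooled),
      inactive_fraction = verdict(pooled), stringsAsFactors = FALSE)
  }
  structure(list(series = series, summary = do.call(rbind, rows)),
            class = "MicroswitchPanel")
}

#' @export
print.MicroswitchPanel <- function(x, ...) {
  cat("MicroswitchPanel:", length(x$series), "metrics\n")
  if (nrow(x$summary)) {
    pooled <- x$summary[is.na(x$summary$trajectory), ]
    print(pooled[, c("name", "median", "iqr", "inactive_fraction")],
          row.names = FALSE)
  }
  invisible(x)
}
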