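#' Signed torsion angle from four points
#'
#' Standard atan2 construction; degrees in (-180, 180].  Vectorized over
#' frames: each argument is a frames x 3 matrix.
#' @noRd
.torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2); y <- rowSums(cross(n1, n2) * b2n)
  ang <- atan2(y, x) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360   # (-180, 180]
  ang
}

## side-chain dihedral atom-name quadruples per residue type
.chi_atoms <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"),
             c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  PRO = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1")),
  ALA = list(), GLY = list()
)

#' Shipped rotamer-state library
#'
#' Maps each residue type's chi dihedrals to a discretization rule:
#' `"sp3"` = three states (g+/t/g-) with sector boundaries at 0 and
#' +/-120 degrees; `"sp2"` = two states for terminal planar dihedrals
#' (|theta| <= 90 vs > 90), used for the Asp/Asn, Glu/Gln, Phe/Tyr, His
#' and Trp terminal dihedrals.  Backbone phi/psi always use three equal
#' 120-degree sectors anchored at -180.  Override entries to change state
#' counts per residue type.
#'
#' @return named list: residue type -> character vector of per-chi rules.
#' @export
default_rotamer_library <- function() {
  list(
    ARG = c("sp3", "sp3", "sp3", "sp3"),
    ASN = c("sp3", "sp2"), ASP = c("sp3", "sp2"),
    CYS = "sp3",
    GLN = c("sp3", "sp3", "sp2"), GLU = c("sp3", "sp3", "sp2"),
    HIS = c("sp3", "sp2"),
    ILE = c("sp3", "sp3"), LEU = c("sp3", "sp3"),
    LYS = c("sp3", "sp3", "sp3", "sp3"),
    MET = c("sp3", "sp3", "sp3"),
    PHE = c("sp3", "sp2"), PRO = c("sp3", "sp3"),
    SER = "sp3", THR = "sp3",
    TRP = c("sp3", "sp2"), TYR = c("sp3", "sp2"),
    VAL = "sp3",
    ALA = character(0), GLY = character(0)
  )
}

#' Extract backbone and side-chain dihedral series for one residue
#'
#' Computes phi, psi and chi1..chi4 (as defined for the residue type) per
#' frame; angles in degrees, (-180, 180].  A dihedral whose defining atoms
#' are missing (chain termini, absent side-chain atoms) is marked absent
#' rather than zero-filled.
#'
#' @param traj a `Trajectory`.
#' @param res_id author residue number.
#' @param chain chain identifier (default `"A"`).
#' @return An object of class `DihedralSeries`: numeric matrix frames x
#'   present dihedrals with column names among `phi`, `psi`, `chi1..4`,
#'   and attributes `absent` (names of missing dihedrals) and `res_name`.
#' @export
extract_dihedrals <- function(traj, res_id, chain = "A") {
  at <- traj$atoms
  find <- function(rid, nm) {
    w <- which(at$chain == chain & at$res_id == rid & at$name == nm)
    if (length(w) == 1L) w else NA_integer_
  }
  rn <- at$res_name[at$chain == chain & at$res_id == res_id][1L]
  if (is.na(rn)) stop("residue ", chain, res_id, " not found")
  coords_of <- function(idx) {
    cols <- c(3L * idx - 2L, 3L * idx - 1L, 3L * idx)
    matrix(traj$xyz[, cols], ncol = 3L)
  }
  defs <- list(
    phi = list(c(res_id - 1L, "C"), c(res_id, "N"), c(res_id, "CA"),
               c(res_id, "C")),
    psi = list(c(res_id, "N"), c(res_id, "CA"), c(res_id, "C"),
               c(res_id + 1L, "N"))
  )
  chis <- .chi_atoms[[rn]]
  if (!is.null(chis) && length(chis) > 0L)
    for (k in seq_along(chis))
      defs[[paste0("chi", k)]] <- lapply(chis[[k]], function(nm)
        c(res_id, nm))
  series <- list(); absent <- character(0)
  for (nm in names(defs)) {
    idx <- vapply(defs[[nm]], function(spec)
      find(as.integer(spec[1L]), spec[2L]), integer(1))
    if (anyNA(idx)) { absent <- c(absent, nm); next }
    series[[nm]] <- .torsion(coords_of(idx[1L]), coords_of(idx[2L]),
                             coords_of(idx[3L]), coords_of(idx[4L]))
  }
  out <- if (length(series)) do.call(cbind, series) else
    matrix(numeric(0), nrow = n_frames(traj), ncol = 0L)
  attr(out, "absent") <- absent
  attr(out, "res_name") <- rn
  class(out) <- c("DihedralSeries", "matrix", "array")
  out
}

## state assignment rules; angles in (-180, 180], boundaries belong to the
## lower sector's closed edge
.assign_states <- function(theta, rule) {
  th <- theta
  th[th >= 180] <- -180            # wrap the shared endpoint downward
  if (rule == "backbone3") {
    pmax(1L, as.integer(ceiling((th + 180) / 120)))
  } else if (rule == "sp3") {
    ## 1 = g+ (0, 120], 2 = t (120, 180] U [-180, -120], 3 = g- (-120, 0]
    s <- integer(length(theta))
    gp <- theta > 0 & theta <= 120
    gm <- theta > -120 & theta <= 0
    s[gp] <- 1L; s[gm] <- 3L; s[!gp & !gm] <- 2L
    s
  } else if (rule == "sp2") {
    ifelse(abs(theta) <= 90, 1L, 2L)
  } else if (grepl("^[0-9]+$", rule)) {
    nb <- as.integer(rule)         # generic n equal sectors anchored at -180
    pmax(1L, as.integer(ceiling((th + 180) / (360 / nb))))
  } else stop("library error: unknown rule '", rule, "'")
}

.rule_states <- function(rule) {
  switch(rule, backbone3 = 3L, sp3 = 3L, sp2 = 2L,
         as.integer(rule))
}

#' Assign rotamer states to a dihedral series
#'
#' Backbone phi/psi are discretized into three equal 120-degree sectors
#' anchored at -180 (a boundary angle belongs to the lower sector's closed
#' edge); side-chain dihedrals follow the residue type's entry in the
#' rotamer library (`"sp3"` g+/t/g- or `"sp2"` two-state).
#'
#' @param dihedrals a `DihedralSeries` from [extract_dihedrals()].
#' @param res_name 3-letter residue type (default: the series' attribute).
#' @param library rotamer library (default [default_rotamer_library()]).
#' @return An object of class `RotamerStateSeries`: integer matrix frames x
#'   dihedrals with attribute `n_states` per column.
#' @export
assign_rotamer_states <- function(dihedrals, res_name = NULL,
                                  library = default_rotamer_library()) {
  if (is.null(res_name)) res_name <- attr(dihedrals, "res_name")
  if (is.null(res_name) || !res_name %in% names(library))
    stop("library error: no rotamer entry for residue type '",
         res_name, "'")
  rules <- library[[res_name]]
  nm <- colnames(dihedrals)
  out <- matrix(NA_integer_, nrow(dihedrals), ncol(dihedrals),
                dimnames = list(NULL, nm))
  n_states <- integer(ncol(dihedrals))
  for (k in seq_along(nm)) {
    rule <- if (nm[k] %in% c("phi", "psi")) "backbone3" else {
      ci <- as.integer(sub("chi", "", nm[k]))
      if (ci > length(rules))
        stop("library error: ", res_name, " has no ", nm[k], " entry")
      rules[ci]
    }
    out[, k] <- .assign_states(dihedrals[, k], rule)
    n_states[k] <- .rule_states(rule)
  }
  attr(out, "n_states") <- n_states
  attr(out, "res_name") <- res_name
  class(out) <- c("RotamerStateSeries", "matrix", "array")
  out
}

#' Rotamer states for every residue of a trajectory
#'
#' Convenience wrapper: extracts dihedrals and assigns states per residue.
#'
#' @param traj a `Trajectory`.
#' @param library rotamer library.
#' @return list with `states` (named list of `RotamerStateSeries` in
#'   residue order) and `residues` (data.frame), directly usable by
#'   [mi_matrix_dihedral()].
#' @export
rotamer_states_all <- function(traj, library = default_rotamer_library()) {
  res <- residue_table(traj)
  states <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    dh <- extract_dihedrals(traj, res$res_id[i], chain = res$chain[i])
    states[[i]] <- if (ncol(dh) > 0L)
      assign_rotamer_states(dh, library = library)
    else structure(matrix(integer(0), nrow = n_frames(traj), ncol = 0L),
                   class = c("RotamerStateSeries", "matrix", "array"))
  }
  names(states) <- paste0(res$chain, res$res_id)
  list(states = states, residues = res)
}

#' Residue-type classification table
#'
#' Chemical classes (basic, acidic, amide, polar, hydrophobic) and the
#' number of side-chain chi dihedrals per standard residue type, used by
#' the MI aggregation schemes.
#'
#' @return data.frame with `res_name`, `class`, `n_chi`; class
#'   `ClassTable`.
#' @export
residue_class_table <- function() {
  tab <- data.frame(
    res_name = c("LYS", "ARG", "HIS", "ASP", "GLU", "ASN", "GLN",
                 "SER", "THR", "TYR", "CYS",
                 "ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO",
                 "GLY"),
    class = c("basic", "basic", "basic", "acidic", "acidic", "amide",
              "amide", "polar", "polar", "polar", "polar",
              "hydrophobic", "hydrophobic", "hydrophobic", "hydrophobic",
              "hydrophobic", "hydrophobic", "hydrophobic", "hydrophobic",
              "hydrophobic"),
    stringsAsFactors = FALSE
  )
  tab$n_chi <- vapply(tab$res_name, function(rn)
    length(.chi_atoms[[rn]]), integer(1))
  class(tab) <- c("ClassTable", "data.frame")
  tab
}
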