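#' Read a multi-model PDB trajectory
#'
#' Parses a PDB file whose MODEL/ENDMDL blocks hold the frames of a
#' trajectory (a single bare ATOM block is read as a one-frame trajectory).
#' Parsing is delegated to [bio3d::read.pdb()]; this wrapper adds the
#' contracts the pipeline relies on: every model must contain the same
#' number of ATOM/HETATM records (violations name the offending model),
#' alternate locations other than `' '`/`'A'` are dropped, the element
#' symbol is taken from PDB columns 77-78 and, where blank, inferred from
#' the leading letters of the atom name, and hydrogen availability is
#' reported via a message at load time.
#'
#' @param path path to a PDB file.
#' @param frame_spacing ns per frame stored on the result (default 0.04).
#' @param quiet suppress the hydrogen-availability message.
#' @return A [trajectory()] object; frames in file order.
#' @export
read_pdb_trajectory <- function(path, frame_spacing = 0.04, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("empty input: no ATOM records in ", path)

  ## pre-scan model structure so inconsistent frames fail with a useful error
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 0L) {
    model_of <- findInterval(which(is_atom), model_starts)
    ends <- which(startsWith(lines, "ENDMDL"))
    if (length(ends) > 0L) {
      ## ATOM lines after the last ENDMDL but before any MODEL are malformed;
      ## bio3d tolerates them, counts per declared model are what we check
    }
    counts <- tabulate(model_of[model_of > 0L], nbins = length(model_starts))
    if (length(unique(counts[counts > 0L])) > 1L) {
      bad <- which(counts != counts[which(counts > 0L)[1L]] & counts > 0L)[1L]
      stop("parse error: model ", bad, " has ", counts[bad],
           " atoms but model 1 has ", counts[which(counts > 0L)[1L]])
    }
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)

  element <- at$elesy
  blank <- is.na(element) | trimws(element) == ""
  if (any(blank))
    element[blank] <- .element_from_name(at$elety[blank])
  element <- trimws(element)
  if (any(element == ""))
    stop("parse error: element could not be inferred for atom(s) ",
         paste(at$eleno[element == ""], collapse = ", "))

  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    element = element,
    res_name = at$resid,
    res_id = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    stringsAsFactors = FALSE
  )
  traj <- trajectory(atoms, xyz, frame_spacing = frame_spacing)
  if (!quiet)
    message("read ", n_frames(traj), " frame(s) x ", n_atoms(traj),
            " atoms; hydrogens ",
            ifelse(has_hydrogens(traj), "present", "absent"))
  traj
}

## element inference fallback: leading letters of the atom name.
## PDB convention right-justifies the element in the first two columns of
## the name; names beginning with a digit (e.g. "1HB") are hydrogens.
.element_from_name <- function(name) {
  vapply(name, function(nm) {
    nm <- trimws(nm)
    if (nm == "") return("")
    if (grepl("^[0-9]", nm)) return("H")
    letters_only <- gsub("[^A-Za-z]", "", nm)
    if (letters_only == "") return("")
    toupper(substr(letters_only, 1L, 1L))
  }, character(1), USE.NAMES = FALSE)
}

#' Write a Trajectory as a multi-model PDB file
#'
#' Emits MODEL records numbered from 1 with fixed-column ATOM records
#' (coordinates at the format's 3-decimal precision), via
#' [bio3d::write.pdb()].
#'
#' @param traj a [trajectory()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path) {
  at <- traj$atoms
  bio3d::write.pdb(
    file = path,
    xyz = traj$xyz,
    type = rep("ATOM", nrow(at)),
    eleno = at$serial,
    elety = at$name,
    resid = at$res_name,
    chain = at$chain,
    resno = at$res_id,
    elesy = at$element
  )
  invisible(path)
}
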