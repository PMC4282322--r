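## Structure and Trajectory containers plus fixed-column PDB I/O.
##
## A Structure is a list with an `atoms` data.frame (one row per atom, stable
## order) and a free-text `title`.  A Trajectory is a list of coordinate
## matrices (n_atoms x 3), all conforming to the same parent Structure.

ATOM_COLS <- c("name", "element", "resname", "resid", "icode", "chain",
               "x", "y", "z", "charge", "mass", "pb_radius",
               "lj_rmin_half", "lj_epsilon")

#' Construct a Structure
#'
#' @param atoms data.frame with at least columns name, element, resname,
#'   resid, chain, x, y, z. Missing parameter columns (charge, mass,
#'   pb_radius, lj_rmin_half, lj_epsilon) are filled with NA; icode with "".
#' @param title free-text title.
#' @return object of class `Structure`.
#' @export
new_structure <- function(atoms, title = "") {
  if (!is.data.frame(atoms) || nrow(atoms) == 0L)
    stop("Structure must contain at least one atom")
  if (!"icode" %in% names(atoms)) atoms$icode <- ""
  for (col in c("charge", "mass", "pb_radius", "lj_rmin_half", "lj_epsilon"))
    if (!col %in% names(atoms)) atoms[[col]] <- NA_real_
  atoms <- atoms[, ATOM_COLS]
  atoms$resid <- as.integer(atoms$resid)
  for (col in c("x", "y", "z")) atoms[[col]] <- as.numeric(atoms[[col]])
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  key <- paste(atoms$chain, atoms$resid, atoms$icode, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resid, name) atom identifiers: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues, chains [%s]%s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              paste(unique(x$atoms$chain), collapse = ","),
              if (nzchar(x$title)) paste0(" - ", x$title) else ""))
  invisible(x)
}

#' Number of atoms in a Structure
#' @param structure a Structure
#' @return integer atom count
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Coordinates of a Structure as a matrix
#' @param structure a Structure
#' @return n x 3 numeric matrix (Angstrom)
#' @export
coords <- function(structure) {
  m <- as.matrix(structure$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace coordinates of a Structure
#' @param structure a Structure
#' @param xyz n x 3 matrix
#' @return updated Structure
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == n_atoms(structure), ncol(xyz) == 3L)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Construct a Trajectory
#'
#' @param frames list of n_atoms x 3 coordinate matrices (model order kept).
#' @param frame_interval optional time between frames (ns), metadata only.
#' @return object of class `Trajectory`.
#' @export
new_trajectory <- function(frames, frame_interval = NA_real_) {
  if (length(frames) < 1L) stop("Trajectory needs at least one frame")
  n <- nrow(frames[[1]])
  for (f in frames)
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3L)
      stop("all frames must be n_atoms x 3 matrices with a common atom count")
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms\n",
              length(x$frames), nrow(x$frames[[1]])))
  invisible(x)
}

#' Number of frames
#' @param trajectory a Trajectory
#' @return integer
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

## ---- PDB reading ----------------------------------------------------------

parse_pdb_atom_lines <- function(lines) {
  ## fixed-column PDB: columns per the wwPDB format v3.3
  sub_f <- function(l, a, b) substr(l, a, b)
  data.frame(
    serial  = suppressWarnings(as.integer(sub_f(lines, 7, 11))),
    name    = trimws(sub_f(lines, 13, 16)),
    altloc  = sub_f(lines, 17, 17),
    resname = trimws(sub_f(lines, 18, 21)),
    chain   = trimws(sub_f(lines, 22, 22)),
    resid   = suppressWarnings(as.integer(sub_f(lines, 23, 26))),
    icode   = trimws(sub_f(lines, 27, 27)),
    x = as.numeric(sub_f(lines, 31, 38)),
    y = as.numeric(sub_f(lines, 39, 46)),
    z = as.numeric(sub_f(lines, 47, 54)),
    occ = suppressWarnings(as.numeric(sub_f(lines, 55, 60))),
    element = trimws(sub_f(lines, 77, 78)),
    stringsAsFactors = FALSE
  )
}

guess_element <- function(name) {
  ## first alphabetic character of the atom name, two-letter cases handled
  ## for the common protein/ion set
  up <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", name)))
  two <- substr(up, 1, 2)
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "CA") &
           nchar(up) == 2 & !grepl("^C[A-Z]$", two) | two %in% c("CL", "BR"),
         two, substr(up, 1, 1))
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records of a fixed-column PDB file. Multi-model files
#' (two or more MODEL blocks) additionally yield a Trajectory whose frames
#' preserve model order. Alternate locations keep the highest-occupancy
#' conformer (ties resolve to the first listed); insertion codes are kept.
#'
#' @param path path to a PDB file.
#' @param resid_offset integer added to every residue number on input, for
#'   depositions whose numbering is shifted relative to the mature protein.
#' @return list with elements `structure` (Structure) and `trajectory`
#'   (Trajectory or NULL when the file holds a single model).
#' @export
read_pdb <- function(path, resid_offset = 0L) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  title <- trimws(paste(substr(lines[startsWith(lines, "TITLE")], 11, 80),
                        collapse = " "))
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  is_model <- startsWith(lines, "MODEL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  atom_idx <- which(is_atom)
  atoms_all <- parse_pdb_atom_lines(lines[atom_idx])
  atoms_all$model <- model_id[atom_idx]
  atoms_all$model[atoms_all$model == 0L] <- 1L
  models <- split(seq_len(nrow(atoms_all)), atoms_all$model)

  first <- atoms_all[models[[1]], , drop = FALSE]
  ## altloc policy: highest occupancy, tie -> first listed
  if (any(first$altloc != " " & first$altloc != "")) {
    key <- paste(first$chain, first$resid, first$icode, first$name)
    keep <- unlist(lapply(split(seq_len(nrow(first)), key), function(ii) {
      if (length(ii) == 1L) return(ii)
      occ <- first$occ[ii]
      occ[is.na(occ)] <- 0
      ii[which.max(occ)]   # ties -> first listed (which.max is first max)
    }), use.names = FALSE)
    keep <- sort(keep)
  } else keep <- seq_len(nrow(first))
  first <- first[keep, , drop = FALSE]

  elem <- ifelse(nzchar(first$element), first$element,
                 guess_element(first$name))
  st <- new_structure(data.frame(
    name = first$name, element = elem, resname = first$resname,
    resid = first$resid + as.integer(resid_offset), icode = first$icode,
    chain = first$chain, x = first$x, y = first$y, z = first$z,
    stringsAsFactors = FALSE), title = title)

  traj <- NULL
  if (length(models) >= 2L) {
    n1 <- length(models[[1]])
    frames <- lapply(models, function(ii) {
      if (length(ii) != n1)
        stop("models have inconsistent atom counts (",
             length(ii), " vs ", n1, ")")
      mm <- atoms_all[ii[keep], , drop = FALSE]
      unname(as.matrix(mm[, c("x", "y", "z")]))
    })
    names(frames) <- NULL
    traj <- new_trajectory(frames)
  }
  list(structure = st, trajectory = traj)
}

## ---- PDB writing ----------------------------------------------------------

format_pdb_atom <- function(atoms, serial) {
  name <- atoms$name
  ## atom-name column convention: start in column 14 unless 4 chars
  namef <- ifelse(nchar(name) >= 4, substr(name, 1, 4),
                  paste0(" ", formatC(name, width = -3)))
  sprintf("ATOM  %5d %-4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, namef, " ", atoms$resname, atoms$chain, atoms$resid,
          ifelse(nzchar(atoms$icode), atoms$icode, " "),
          atoms$x, atoms$y, atoms$z, 1.00, 0.00,
          formatC(atoms$element, width = 2))
}

#' Write a Structure or Trajectory to a PDB file
#'
#' Multi-frame output wraps each frame in MODEL/ENDMDL records. Residue
#' numbers beyond the 4-column PDB capacity raise an error rather than
#' silently wrapping.
#'
#' @param x a Structure, or a Trajectory (in which case `structure` supplies
#'   the atom identities).
#' @param path output file path.
#' @param structure parent Structure when `x` is a Trajectory.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, structure = NULL) {
  if (inherits(x, "Trajectory")) {
    if (is.null(structure)) stop("writing a Trajectory requires its Structure")
    at <- structure$atoms
    check_pdb_capacity(at)
    con <- file(path, "w")
    on.exit(close(con))
    if (nzchar(structure$title))
      writeLines(sprintf("TITLE     %s", structure$title), con)
    for (i in seq_along(x$frames)) {
      writeLines(sprintf("MODEL     %4d", i), con)
      ai <- at
      ai$x <- x$frames[[i]][, 1]; ai$y <- x$frames[[i]][, 2]
      ai$z <- x$frames[[i]][, 3]
      writeLines(format_pdb_atom(ai, seq_len(nrow(ai))), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    return(invisible(path))
  }
  if (!inherits(x, "Structure")) stop("x must be a Structure or Trajectory")
  at <- x$atoms
  check_pdb_capacity(at)
  out <- c(if (nzchar(x$title)) sprintf("TITLE     %s", x$title),
           format_pdb_atom(at, seq_len(nrow(at))), "END")
  writeLines(out, path)
  invisible(path)
}

check_pdb_capacity <- function(at) {
  if (any(at$resid > 9999L | at$resid < -999L))
    stop("residue number outside 4-column PDB capacity: ",
         paste(unique(at$resid[at$resid > 9999L | at$resid < -999L]),
               collapse = ", "))
}
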