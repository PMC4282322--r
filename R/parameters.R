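## Plain-text force-field parameter format and Topology construction.
##
## File format (whitespace-separated, '#' comments):
##   TYPE     <resname> <atomname> <element> <charge> <mass> <pb_radius>
##            <lj_rmin_half> <lj_epsilon>
##   BOND     <ref> <ref> <k kcal/mol/A^2> <b0 A>
##   ANGLE    <ref> <ref> <ref> <k kcal/mol/rad^2> <theta0 deg>
##   DIHEDRAL <ref> <ref> <ref> <ref> <k kcal/mol> <multiplicity> <delta deg>
##   IMPROPER <ref> <ref> <ref> <ref> <k kcal/mol/rad^2> <psi0 deg>
## where <ref> is "chain:resid:atomname" (e.g. A:12:CA). Harmonic terms use
## the k*(x-x0)^2 convention (no 1/2); dihedrals k*(1+cos(n*phi-delta)).
## 1-2 and 1-3 pairs are excluded from nonbonded sums; 1-4 pairs are flagged
## and scaled by a configurable factor (default 1 = full strength).

atom_ref_index <- function(refs, atoms) {
  key <- paste(atoms$chain, atoms$resid, toupper(atoms$name), sep = ":")
  parts <- strsplit(refs, ":", fixed = TRUE)
  idx <- vapply(parts, function(p) {
    if (length(p) != 3L) stop("malformed atom reference: ",
                              paste(p, collapse = ":"))
    i <- match(paste(p[1], as.integer(p[2]), toupper(p[3]), sep = ":"), key)
    if (is.na(i)) stop("atom reference not found in structure: ",
                       paste(p, collapse = ":"))
    i
  }, integer(1))
  idx
}

#' Construct a Topology
#'
#' @param n_atoms atom count of the parent structure.
#' @param bonds data.frame(i, j, k, b0); every bond listed once.
#' @param angles data.frame(i, j, k, kth, th0) with th0 in degrees.
#' @param dihedrals data.frame(i, j, k, l, kphi, n, delta), delta in degrees.
#' @param impropers data.frame(i, j, k, l, kpsi, psi0), psi0 in degrees.
#' @return object of class `Topology` with exclusion lists (`excl12`,
#'   `excl13` 2-column index matrices, `pairs14` flagged 1-4 pairs) derived
#'   from the bond graph.
#' @export
new_topology <- function(n_atoms, bonds = NULL, angles = NULL,
                         dihedrals = NULL, impropers = NULL) {
  empty <- function(cols) as.data.frame(setNames(rep(list(numeric(0)),
                                                     length(cols)), cols))
  if (is.null(bonds)) bonds <- empty(c("i", "j", "k", "b0"))
  if (is.null(angles)) angles <- empty(c("i", "j", "k", "kth", "th0"))
  if (is.null(dihedrals))
    dihedrals <- empty(c("i", "j", "k", "l", "kphi", "n", "delta"))
  if (is.null(impropers))
    impropers <- empty(c("i", "j", "k", "l", "kpsi", "psi0"))
  idx <- c(bonds$i, bonds$j, angles$i, angles$j, angles$k,
           dihedrals$i, dihedrals$j, dihedrals$k, dihedrals$l,
           impropers$i, impropers$j, impropers$k, impropers$l)
  if (length(idx) && (min(idx) < 1 || max(idx) > n_atoms))
    stop("topology index out of range")
  if (nrow(bonds)) {
    bk <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(bk)) stop("duplicate bond in topology: ",
                                bk[duplicated(bk)][1])
  }
  excl <- build_exclusions(bonds, n_atoms)
  structure(list(n_atoms = n_atoms, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, impropers = impropers,
                 excl12 = excl$excl12, excl13 = excl$excl13,
                 pairs14 = excl$pairs14),
            class = "Topology")
}

#' Exclusion lists from a bond graph
#'
#' Computes 1-2 and 1-3 excluded pairs and flagged 1-4 pairs by shortest
#' bond-path length (a pair is 1-3 only if it is not also 1-2, etc.).
#'
#' @param bonds data.frame with columns i, j.
#' @param n_atoms atom count.
#' @return list of 2-column matrices `excl12`, `excl13`, `pairs14` (i < j).
#' @export
build_exclusions <- function(bonds, n_atoms) {
  mkmat <- function(p) {
    if (length(p) == 0L)
      return(matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("i", "j"))))
    m <- do.call(rbind, p)
    m <- unique(m)
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  if (is.null(bonds) || nrow(bonds) == 0L)
    return(list(excl12 = mkmat(list()), excl13 = mkmat(list()),
                pairs14 = mkmat(list())))
  adj <- vector("list", n_atoms)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  p12 <- list(); p13 <- list(); p14 <- list()
  for (a in seq_len(n_atoms)) {
    n1 <- unique(adj[[a]])
    n2 <- setdiff(unique(unlist(adj[n1])), c(a, n1))
    n3 <- setdiff(unique(unlist(adj[n2])), c(a, n1, n2))
    for (b in n1[n1 > a]) p12[[length(p12) + 1L]] <- c(i = a, j = b)
    for (b in n2[n2 > a]) p13[[length(p13) + 1L]] <- c(i = a, j = b)
    for (b in n3[n3 > a]) p14[[length(p14) + 1L]] <- c(i = a, j = b)
  }
  list(excl12 = mkmat(p12), excl13 = mkmat(p13), pairs14 = mkmat(p14))
}

#' Read a parameter/topology file and assign atomic parameters
#'
#' Assigns charge, mass, PB radius and Lennard-Jones parameters to every
#' atom of `structure` by (resname, atomname) lookup and builds the bonded
#' Topology from explicit BOND/ANGLE/DIHEDRAL/IMPROPER records. See the
#' format notes at the top of the vignette.
#'
#' @param path parameter file path.
#' @param structure a Structure to parameterize.
#' @return list with `structure` (parameterized copy) and `topology`.
#' @export
read_parameters <- function(path, structure) {
  if (!file.exists(path)) stop("cannot read parameter file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")

  atoms <- structure$atoms
  types <- list()
  bonds <- list(); angles <- list(); dihedrals <- list(); impropers <- list()
  for (tk in toks) {
    rec <- toupper(tk[1])
    if (rec == "TYPE") {
      if (length(tk) != 9L) stop("TYPE record needs 8 fields: ",
                                 paste(tk, collapse = " "))
      key <- paste(toupper(tk[2]), toupper(tk[3]))
      if (!is.null(types[[key]]))
        stop("duplicate parameter for (", tk[2], ", ", tk[3], ")")
      types[[key]] <- list(element = tk[4],
                           vals = as.numeric(tk[5:9]))
    } else if (rec == "BOND") {
      ij <- atom_ref_index(tk[2:3], atoms)
      bonds[[length(bonds) + 1L]] <-
        data.frame(i = ij[1], j = ij[2], k = as.numeric(tk[4]),
                   b0 = as.numeric(tk[5]))
    } else if (rec == "ANGLE") {
      ijk <- atom_ref_index(tk[2:4], atoms)
      angles[[length(angles) + 1L]] <-
        data.frame(i = ijk[1], j = ijk[2], k = ijk[3],
                   kth = as.numeric(tk[5]), th0 = as.numeric(tk[6]))
    } else if (rec == "DIHEDRAL") {
      q <- atom_ref_index(tk[2:5], atoms)
      dihedrals[[length(dihedrals) + 1L]] <-
        data.frame(i = q[1], j = q[2], k = q[3], l = q[4],
                   kphi = as.numeric(tk[6]), n = as.numeric(tk[7]),
                   delta = as.numeric(tk[8]))
    } else if (rec == "IMPROPER") {
      q <- atom_ref_index(tk[2:5], atoms)
      impropers[[length(impropers) + 1L]] <-
        data.frame(i = q[1], j = q[2], k = q[3], l = q[4],
                   kpsi = as.numeric(tk[6]), psi0 = as.numeric(tk[7]))
    } else stop("unknown record type '", tk[1], "' in ", path)
  }

  key <- paste(toupper(atoms$resname), toupper(atoms$name))
  missing <- !(key %in% names(types))
  if (any(missing)) {
    first <- which(missing)[1]
    stop("no parameters for atom (", atoms$resname[first], ", ",
         atoms$name[first], ")")
  }
  tv <- do.call(rbind, lapply(types[key], `[[`, "vals"))
  atoms$charge <- tv[, 1]
  atoms$mass <- tv[, 2]
  atoms$pb_radius <- tv[, 3]
  atoms$lj_rmin_half <- tv[, 4]
  atoms$lj_epsilon <- tv[, 5]
  if (any(atoms$mass <= 0)) stop("non-positive mass in parameter file")
  if (any(atoms$pb_radius < 0)) stop("negative PB radius in parameter file")

  st <- structure
  st$atoms <- atoms
  st$param_types <- types
  topo <- new_topology(nrow(atoms),
                       bonds = if (length(bonds)) do.call(rbind, bonds),
                       angles = if (length(angles)) do.call(rbind, angles),
                       dihedrals = if (length(dihedrals))
                         do.call(rbind, dihedrals),
                       impropers = if (length(impropers))
                         do.call(rbind, impropers))
  list(structure = st, topology = topo)
}

#' Restrict a Topology to an atom subset
#'
#' Keeps only bonded terms whose atoms all lie in `idx` and re-indexes them
#' to the subset's 1..n numbering. Exclusion lists are rebuilt.
#'
#' @param topology a Topology.
#' @param idx ascending atom indices of the subset.
#' @return Topology for the subset.
#' @export
subset_topology <- function(topology, idx) {
  map <- integer(topology$n_atoms)
  map[idx] <- seq_along(idx)
  keep_terms <- function(df, cols) {
    if (nrow(df) == 0L) return(df)
    inside <- rowSums(sapply(cols, function(cl) map[df[[cl]]] > 0)) ==
      length(cols)
    df <- df[inside, , drop = FALSE]
    for (cl in cols) df[[cl]] <- map[df[[cl]]]
    rownames(df) <- NULL
    df
  }
  new_topology(length(idx),
               bonds = keep_terms(topology$bonds, c("i", "j")),
               angles = keep_terms(topology$angles, c("i", "j", "k")),
               dihedrals = keep_terms(topology$dihedrals,
                                      c("i", "j", "k", "l")),
               impropers = keep_terms(topology$impropers,
                                      c("i", "j", "k", "l")))
}
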