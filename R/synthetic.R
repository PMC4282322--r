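## Seeded synthetic-data generators. Every generator is a pure function of
## its arguments (including the seed) and produces fully parameterized
## systems that pass the whole pipeline: a two-domain receptor with an
## engineered disulfide-rich domain and a 3-residue ligand bound to it,
## hinge-bending ensembles with prescribed angle distributions, module
## chains on circular arcs of known curvature, and Born ions with their
## analytic solvation energy.

## mini heavy-atom residue templates: local offsets from the residue origin
TOY_TEMPLATES <- list(
  GLY = list(names = c("N", "CA", "C"),
             elements = c("N", "C", "C"),
             offsets = rbind(c(0, 0, 0), c(1.2, 0.9, 0), c(2.4, 0, 0)),
             charges = c(-0.3, 0.1, 0.2)),
  ALA = list(names = c("N", "CA", "C", "CB"),
             elements = c("N", "C", "C", "C"),
             offsets = rbind(c(0, 0, 0), c(1.2, 0.9, 0), c(2.4, 0, 0),
                             c(1.2, 1.9, 1.0)),
             charges = c(-0.3, 0.1, 0.2, 0.0)),
  LEU = list(names = c("N", "CA", "C", "CB", "CG"),
             elements = c("N", "C", "C", "C", "C"),
             offsets = rbind(c(0, 0, 0), c(1.2, 0.9, 0), c(2.4, 0, 0),
                             c(1.2, 1.9, 1.0), c(1.8, 2.9, 1.8)),
             charges = c(-0.3, 0.1, 0.2, 0.0, 0.0)),
  LYS = list(names = c("N", "CA", "C", "CB", "NZ"),
             elements = c("N", "C", "C", "C", "N"),
             offsets = rbind(c(0, 0, 0), c(1.2, 0.9, 0), c(2.4, 0, 0),
                             c(1.2, 1.9, 1.0), c(1.8, 2.9, 1.8)),
             charges = c(-0.3, 0.1, 0.2, 0.0, 1.0)),
  ASP = list(names = c("N", "CA", "C", "CB", "OD"),
             elements = c("N", "C", "C", "C", "O"),
             offsets = rbind(c(0, 0, 0), c(1.2, 0.9, 0), c(2.4, 0, 0),
                             c(1.2, 1.9, 1.0), c(1.8, 2.9, 1.8)),
             charges = c(-0.3, 0.1, 0.2, 0.0, -1.0)),
  CYS = list(names = c("N", "CA", "C", "CB", "SG"),
             elements = c("N", "C", "C", "C", "S"),
             offsets = rbind(c(0, 0, 0), c(1.2, 0.9, 0), c(2.4, 0, 0),
                             c(1.2, 1.9, 1.0), c(1.2, 2.9, 1.6)),
             charges = c(-0.3, 0.1, 0.2, 0.05, -0.05)))

TOY_ELEMENT_PARAMS <- data.frame(
  element = c("N", "C", "O", "S"),
  mass = c(14.007, 12.011, 15.999, 32.06),
  pb_radius = c(1.6, 2.0, 1.5, 1.9),
  lj_rmin_half = c(1.85, 2.0, 1.7, 2.0),
  lj_epsilon = c(0.20, 0.10, 0.12, 0.45))

RESIDUE_PITCH <- 3.6

rot_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * outer(a, a)
}

seeded_rotation <- function(seed) {
  set.seed(seed)
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Toy receptor-ligand complex specification
#'
#' The default receptor (chain A) has a 10-residue domain with two
#' engineered adjacent-cysteine disulfide bridges and a charged aspartate, a
#' 2-glycine hinge and an 8-residue second domain; the ligand (chain B) is a
#' Lys-Ala-Leu tripeptide whose lysine forms a salt bridge with the
#' receptor aspartate (the only charged interface contact).
#'
#' @param seed deterministic jitter seed.
#' @param jitter coordinate jitter RMS in Angstrom (breaks symmetry;
#'   bonded equilibrium values are measured after jitter so the built
#'   geometry has zero internal strain).
#' @return list of class `ToyComplexSpec`.
#' @export
toy_complex_spec <- function(seed = 1L, jitter = 0.02) {
  structure(list(
    seed = seed, jitter = jitter,
    receptor = c("GLY", "CYS", "CYS", "ALA", "ASP", "CYS", "CYS", "LEU",
                 "ALA", "GLY", "GLY", "GLY", "ALA", "LEU", "GLY", "ALA",
                 "LEU", "GLY", "ALA", "GLY"),
    ligand = c("LYS", "ALA", "LEU"),
    cys_pairs = list(c(2L, 3L), c(6L, 7L)),
    domain1 = c(1L, 10L), hinge = c(11L, 12L), domain2 = c(13L, 20L),
    ligand_origin = c(14.4 + 1.2, 8.4, 0)), class = "ToyComplexSpec")
}

build_toy_atoms <- function(spec) {
  place_chain <- function(resnames, chain, origin, mirror_y = FALSE) {
    rows <- list()
    for (i in seq_along(resnames)) {
      rn <- resnames[i]
      tpl <- TOY_TEMPLATES[[rn]]
      off <- tpl$offsets
      if (mirror_y) off[, 2] <- -off[, 2]
      pos <- sweep(off, 2, origin + c(RESIDUE_PITCH * (i - 1), 0, 0), `+`)
      rows[[i]] <- data.frame(
        name = tpl$names, element = tpl$elements, resname = rn,
        resid = i, chain = chain,
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  at <- rbind(place_chain(spec$receptor, "A", c(0, 0, 0)),
              place_chain(spec$ligand, "B", spec$ligand_origin,
                          mirror_y = TRUE))
  ## engineered disulfides: point the paired SG atoms at each other
  for (pr in spec$cys_pairs) {
    i1 <- which(at$chain == "A" & at$resid == pr[1] & at$name == "SG")
    i2 <- which(at$chain == "A" & at$resid == pr[2] & at$name == "SG")
    cb1 <- which(at$chain == "A" & at$resid == pr[1] & at$name == "CB")
    cb2 <- which(at$chain == "A" & at$resid == pr[2] & at$name == "CB")
    at[i1, c("x", "y", "z")] <- at[cb1, c("x", "y", "z")] +
      c(0.85, 1.0, 0.6)
    at[i2, c("x", "y", "z")] <- at[cb2, c("x", "y", "z")] +
      c(-0.85, 1.0, 0.6)
  }
  if (spec$jitter > 0) {
    set.seed(spec$seed)
    at$x <- at$x + stats::rnorm(nrow(at), 0, spec$jitter)
    at$y <- at$y + stats::rnorm(nrow(at), 0, spec$jitter)
    at$z <- at$z + stats::rnorm(nrow(at), 0, spec$jitter)
  }
  at
}

toy_parameter_text <- function(spec, st) {
  at <- st$atoms
  lines <- c("# flexpbsa toy mini force field (generated)",
             "# TYPE resname atomname element charge mass pb_radius rmin/2 epsilon")
  seen <- character(0)
  for (rn in unique(at$resname)) {
    tpl <- TOY_TEMPLATES[[rn]]
    for (k in seq_along(tpl$names)) {
      key <- paste(rn, tpl$names[k])
      if (key %in% seen) next
      seen <- c(seen, key)
      ep <- TOY_ELEMENT_PARAMS[TOY_ELEMENT_PARAMS$element ==
                                 tpl$elements[k], ]
      lines <- c(lines, sprintf(
        "TYPE %s %s %s %.4f %.4f %.3f %.3f %.3f", rn, tpl$names[k],
        tpl$elements[k], tpl$charges[k], ep$mass, ep$pb_radius,
        ep$lj_rmin_half, ep$lj_epsilon))
    }
  }
  ref <- function(i) sprintf("%s:%d:%s", at$chain[i], at$resid[i],
                             at$name[i])
  xyz <- coords(st)
  dist_ij <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  find <- function(chain, resid, name)
    which(at$chain == chain & at$resid == resid & at$name == name)

  ## bonds: backbone, side chains, disulfides; b0 = built length
  bonds <- list()
  add_bond <- function(i, j, k = 300)
    bonds[[length(bonds) + 1L]] <<- c(i, j, k)
  for (ch in unique(at$chain)) {
    resids <- sort(unique(at$resid[at$chain == ch]))
    for (r in resids) {
      rn <- at$resname[find(ch, r, "N")]
      add_bond(find(ch, r, "N"), find(ch, r, "CA"))
      add_bond(find(ch, r, "CA"), find(ch, r, "C"))
      if (r < max(resids)) add_bond(find(ch, r, "C"), find(ch, r + 1, "N"))
      nm <- at$name[at$chain == ch & at$resid == r]
      if ("CB" %in% nm) add_bond(find(ch, r, "CA"), find(ch, r, "CB"))
      for (tip in intersect(nm, c("CG", "NZ", "OD", "SG")))
        add_bond(find(ch, r, "CB"), find(ch, r, tip))
    }
  }
  for (pr in spec$cys_pairs)
    add_bond(find("A", pr[1], "SG"), find("A", pr[2], "SG"), k = 250)
  bond_mat <- do.call(rbind, bonds)
  lines <- c(lines, vapply(seq_len(nrow(bond_mat)), function(r)
    sprintf("BOND %s %s %.1f %.6f", ref(bond_mat[r, 1]),
            ref(bond_mat[r, 2]), bond_mat[r, 3],
            dist_ij(bond_mat[r, 1], bond_mat[r, 2])), character(1)))

  ## angles: every bonded-neighbour pair at every centre; th0 = built angle
  adj <- vector("list", nrow(at))
  for (r in seq_len(nrow(bond_mat))) {
    i <- bond_mat[r, 1]; j <- bond_mat[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  for (j in seq_len(nrow(at))) {
    nb <- adj[[j]]
    if (length(nb) < 2L) next
    cmb <- utils::combn(sort(nb), 2)
    for (cc in seq_len(ncol(cmb))) {
      i <- cmb[1, cc]; k <- cmb[2, cc]
      th <- bend_angle(xyz, i, j, k) * 180 / pi
      lines <- c(lines, sprintf("ANGLE %s %s %s %.1f %.6f",
                                ref(i), ref(j), ref(k), 50, th))
    }
  }

  ## backbone dihedrals N-CA-C-N(next), minimum at the built geometry
  for (ch in unique(at$chain)) {
    resids <- sort(unique(at$resid[at$chain == ch]))
    for (r in resids[-length(resids)]) {
      q <- c(find(ch, r, "N"), find(ch, r, "CA"), find(ch, r, "C"),
             find(ch, r + 1, "N"))
      phi <- dihedral_angle(xyz, q[1], q[2], q[3], q[4]) * 180 / pi
      delta <- (3 * phi - 180) %% 360
      lines <- c(lines, sprintf("DIHEDRAL %s %s %s %s %.2f %d %.6f",
                                ref(q[1]), ref(q[2]), ref(q[3]), ref(q[4]),
                                0.5, 3L, delta))
    }
  }

  ## one improper per C-beta branch, psi0 = built value
  for (i in which(at$name == "CB")) {
    ch <- at$chain[i]; r <- at$resid[i]
    q <- c(find(ch, r, "N"), find(ch, r, "C"), find(ch, r, "CA"), i)
    psi <- dihedral_angle(xyz, q[1], q[2], q[3], q[4]) * 180 / pi
    lines <- c(lines, sprintf("IMPROPER %s %s %s %s %.1f %.6f",
                              ref(q[1]), ref(q[2]), ref(q[3]), ref(q[4]),
                              20, psi))
  }
  lines
}

#' Build the toy receptor-ligand complex
#'
#' Deterministic for a given spec (same seed gives byte-identical outputs).
#' The parameter file is written to `param_file` and re-read through
#' [read_parameters()], so the returned structure/topology exercise the
#' production I/O path; every atom is parameterized and the total charge is
#' an integer.
#'
#' @param spec a [toy_complex_spec()].
#' @param param_file where to write the generated parameter file.
#' @return list with `structure`, `topology`, `param_file`,
#'   `receptor_selection`, `ligand_selection`, `anchors` (AnchorPair of the
#'   two domains), `hinge_resid`, `domain1`, `domain2`, `spec`.
#' @export
make_toy_complex <- function(spec = toy_complex_spec(),
                             param_file = tempfile(fileext = ".prm")) {
  at <- build_toy_atoms(spec)
  st0 <- new_structure(at, title = "flexpbsa toy receptor-ligand complex")
  writeLines(toy_parameter_text(spec, st0), param_file)
  pr <- read_parameters(param_file, st0)
  list(structure = pr$structure, topology = pr$topology,
       param_file = param_file,
       receptor_selection = "chain A", ligand_selection = "chain B",
       anchors = anchor_pair(chain = "A",
                             v1_from = spec$domain1[1],
                             v1_to = spec$domain1[2],
                             v2_from = spec$domain2[1],
                             v2_to = spec$domain2[2]),
       hinge_resid = spec$hinge[2], domain1 = spec$domain1,
       domain2 = spec$domain2, spec = spec)
}

#' Hinge-bending trajectory with a prescribed angle distribution
#'
#' Per frame, the second domain (and nothing else) is rigidly rotated about
#' the hinge pivot so the anchor angle equals a draw from
#' N(mean_angle, sd); isotropic Gaussian noise of RMS `thermal_noise_rms`
#' per coordinate is then added. Ground-truth per-frame target angles are
#' returned as a sidecar table.
#'
#' @param toy a [make_toy_complex()] result.
#' @param mean_angle,sd degrees.
#' @param n_frames frame count.
#' @param thermal_noise_rms Angstrom (default 0).
#' @param seed RNG seed.
#' @return list with `trajectory` and `sidecar`
#'   (data.frame frame, target_angle).
#' @export
make_hinge_trajectory <- function(toy, mean_angle = 110, sd = 5,
                                  n_frames = 100L, thermal_noise_rms = 0,
                                  seed = 1L) {
  stopifnot(n_frames >= 2L, sd >= 0)
  st <- toy$structure
  at <- st$atoms
  xyz0 <- coords(st)
  dom2 <- which(at$chain == "A" & at$resid >= toy$domain2[1])
  pivot_i <- which(at$chain == "A" & at$resid == toy$hinge_resid &
                     at$name == "CA")
  pivot <- xyz0[pivot_i, ]
  v <- anchor_coords(st, toy$anchors)
  ## exact construction: rotate V2 within the span(V1, V2) plane so the
  ## anchor angle equals the target exactly
  e1 <- v$v1 / sqrt(sum(v$v1^2))
  w <- v$v2 - sum(v$v2 * e1) * e1
  if (sqrt(sum(w * w)) < 1e-9) w <- c(-e1[2], e1[1], 0)  # degenerate case
  e2 <- w / sqrt(sum(w * w))
  v2h <- v$v2 / sqrt(sum(v$v2^2))
  rot_to_target <- function(th_deg) {
    th <- th_deg * pi / 180
    tgt <- cos(th) * e1 + sin(th) * e2
    ax <- cross3(v2h, tgt)
    s <- sqrt(sum(ax * ax))
    c_ <- sum(v2h * tgt)
    if (s < 1e-12) {
      if (c_ > 0) return(diag(3))
      ax <- e2 - sum(e2 * v2h) * v2h   # any axis perpendicular to v2
      ax <- ax / sqrt(sum(ax * ax))
      return(rot_about_axis(ax, 180))
    }
    rot_about_axis(ax / s, atan2(s, c_) * 180 / pi)
  }

  set.seed(seed)
  targets <- stats::rnorm(n_frames, mean_angle, sd)
  targets <- pmin(pmax(targets, 0), 180)
  frames <- lapply(targets, function(th) {
    Rm <- rot_to_target(th)
    x <- xyz0
    x[dom2, ] <- sweep(sweep(x[dom2, , drop = FALSE], 2, pivot) %*% t(Rm),
                       2, pivot, `+`)
    if (thermal_noise_rms > 0)
      x <- x + matrix(stats::rnorm(length(x), 0, thermal_noise_rms),
                      ncol = 3)
    x
  })
  list(trajectory = new_trajectory(frames),
       sidecar = data.frame(frame = seq_len(n_frames),
                            target_angle = targets))
}

#' Module chain on a circular arc of known curvature
#'
#' Points are placed on a circular arc of curvature kappa (a shallow arc, so
#' a quadratic fit recovers kappa at the vertex), rotated into a seeded
#' random 3-D orientation, translated, and optionally perturbed by noise.
#' kappa = 0 gives collinear points. The per-segment chord is capped so the
#' arc stays shallow (total turn <= ~0.7 rad); requesting a larger chord
#' than the curvature admits is an error.
#'
#' @param target_curvature kappa in 1/Angstrom (>= 0).
#' @param n_modules number of points (default 7).
#' @param chord_length spacing between consecutive points (Angstrom;
#'   default: shallow-arc spacing 0.1/kappa, or 3 A when kappa = 0).
#' @param noise_rms coordinate noise RMS (Angstrom).
#' @param seed orientation/noise seed.
#' @return list with `points` (n x 3), `true_curvature`.
#' @export
make_module_chain <- function(target_curvature, n_modules = 7L,
                              chord_length = NULL, noise_rms = 0,
                              seed = 1L) {
  stopifnot(target_curvature >= 0, n_modules >= 3L)
  k <- target_curvature
  if (is.null(chord_length))
    chord_length <- if (k > 0) 0.05 / k else 3
  if (k == 0) {
    pts <- cbind(seq_len(n_modules) * chord_length, 0, 0)
  } else {
    R <- 1 / k
    dalpha <- 2 * asin(min(1, k * chord_length / 2))
    if (dalpha * (n_modules - 1) > 0.7)
      stop("chord_length too large for a shallow arc at this curvature")
    alpha <- (seq_len(n_modules) - (n_modules + 1) / 2) * dalpha
    pts <- cbind(R * sin(alpha), R * (1 - cos(alpha)), 0)
  }
  Q <- seeded_rotation(seed)
  pts <- pts %*% t(Q)
  set.seed(seed + 1L)
  pts <- sweep(pts, 2, stats::runif(3, -20, 20), `+`)
  if (noise_rms > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), 0, noise_rms), ncol = 3)
  list(points = pts, true_curvature = k)
}

#' Born ion system with its analytic solvation energy
#'
#' A single spherical ion; the analytic polar solvation free energy
#' -k_e/2 * q^2/r * (1/eps_in - 1/eps_out) is returned as a sidecar for
#' validating the PB solver.
#'
#' @param charge e.
#' @param radius Angstrom.
#' @param eps_in,eps_out dielectrics used for the sidecar value.
#' @return list with `structure` (parameterized single atom) and
#'   `analytic_g_pb` (kcal/mol).
#' @export
make_born_system <- function(charge = 1, radius = 2, eps_in = 1,
                             eps_out = 80) {
  stopifnot(radius > 0)
  st <- new_structure(data.frame(
    name = "ION", element = "X", resname = "ION", resid = 1L, chain = "A",
    x = 0, y = 0, z = 0, charge = charge, mass = 22.99,
    pb_radius = radius, lj_rmin_half = radius, lj_epsilon = 0.1,
    stringsAsFactors = FALSE), title = "Born ion")
  list(structure = st,
       analytic_g_pb = -kCOUL / 2 * charge^2 / radius *
         (1 / eps_in - 1 / eps_out))
}

#' Complex / receptor / ligand ensembles for the binding estimators
#'
#' Complex frames are the toy reference plus seeded Gaussian fluctuations.
#' Free receptor and ligand frames are generated independently; an optional
#' prescribed stretch of the ligand's terminal Leu CB-CG bond in the
#' complex frames creates a reorganization free energy and a nonzero
#' three-trajectory Delta E_int of known sign and magnitude
#' (k * stretch^2).
#'
#' @param toy a [make_toy_complex()] result.
#' @param n_frames frames per ensemble.
#' @param fluctuation_rms Gaussian atomic fluctuation RMS (A).
#' @param seed RNG seed.
#' @param ligand_strain stretch of the ligand CB-CG bond in the complex
#'   ensemble (A; default 0).
#' @return list with species lists (`complex`, `receptor`, `ligand`, each
#'   holding structure/topology/trajectory), the selections, and
#'   `strain_energy` (kcal/mol, k * stretch^2).
#' @export
make_ensemble <- function(toy, n_frames = 8L, fluctuation_rms = 0.02,
                          seed = 1L, ligand_strain = 0) {
  st <- toy$structure; topo <- toy$topology
  xyz0 <- coords(st)
  ridx <- select_atoms(st, toy$receptor_selection)
  lidx <- select_atoms(st, toy$ligand_selection)
  at <- st$atoms

  ## strained complex conformation: displace the ligand Leu CG along CB->CG
  xyz_c <- xyz0
  strain_energy <- 0
  if (ligand_strain != 0) {
    lig_res <- max(at$resid[lidx])
    icg <- which(at$chain == "B" & at$resid == lig_res & at$name == "CG")
    icb <- which(at$chain == "B" & at$resid == lig_res & at$name == "CB")
    if (length(icg) != 1L) stop("toy ligand lacks the Leu CG atom")
    u <- xyz0[icg, ] - xyz0[icb, ]
    u <- u / sqrt(sum(u^2))
    xyz_c[icg, ] <- xyz_c[icg, ] + ligand_strain * u
    bk <- topo$bonds$k[(topo$bonds$i == icg & topo$bonds$j == icb) |
                         (topo$bonds$i == icb & topo$bonds$j == icg)]
    strain_energy <- bk * ligand_strain^2
  }

  noise_frames <- function(base, n, seed_off)
    lapply(seq_len(n), function(f) {
      set.seed(seed + seed_off + f)
      base + if (fluctuation_rms > 0)
        matrix(stats::rnorm(length(base), 0, fluctuation_rms), ncol = 3)
      else 0
    })

  complex_frames <- noise_frames(xyz_c, n_frames, 0L)
  receptor_frames <- lapply(noise_frames(xyz0, n_frames, 1000L),
                            function(f) f[ridx, , drop = FALSE])
  ligand_frames <- lapply(noise_frames(xyz0, n_frames, 2000L),
                          function(f) f[lidx, , drop = FALSE])

  rstr <- subset_structure(st, ridx)
  rstr$param_types <- st$param_types
  lstr <- subset_structure(st, lidx)
  lstr$param_types <- st$param_types
  list(complex = list(structure = st, topology = topo,
                      trajectory = new_trajectory(complex_frames)),
       receptor = list(structure = rstr,
                       topology = subset_topology(topo, ridx),
                       trajectory = new_trajectory(receptor_frames)),
       ligand = list(structure = lstr,
                     topology = subset_topology(topo, lidx),
                     trajectory = new_trajectory(ligand_frames)),
       receptor_selection = toy$receptor_selection,
       ligand_selection = toy$ligand_selection,
       receptor_idx = ridx, ligand_idx = lidx,
       strain_energy = strain_energy)
}
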