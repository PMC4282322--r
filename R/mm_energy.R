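## Gas-phase molecular-mechanics energies, computed without any nonbonded
## cutoff, plus analytic gradients (used by the minimizer and the
## finite-difference Hessian).
##
## Conventions: harmonic terms k*(x-x0)^2 (no 1/2), dihedrals
## k*(1+cos(n*phi-delta)), LJ eps*[(rmin/r)^12 - 2(rmin/r)^6] with
## Lorentz-Berthelot-style combining (rmin arithmetic from rmin/2 halves,
## epsilon geometric). 1-2/1-3 pairs are excluded; 1-4 pairs are included
## at a configurable scale (default full strength).

#' Nonbonded/bookkeeping options for MM energies
#' @param ele_scale14,vdw_scale14 scale factors applied to flagged 1-4
#'   pairs (default 1 = full strength).
#' @return list of options.
#' @export
mm_options <- function(ele_scale14 = 1, vdw_scale14 = 1) {
  list(ele_scale14 = ele_scale14, vdw_scale14 = vdw_scale14)
}

## pair scale matrix: 0 for excluded (1-2, 1-3), `scale14` for 1-4, 1 else
pair_scale_matrix <- function(n, topology, scale14) {
  S <- matrix(1, n, n)
  diag(S) <- 0
  if (!is.null(topology)) {
    put <- function(m, val) {
      if (nrow(m)) {
        S[m] <<- val
        S[m[, c(2, 1), drop = FALSE]] <<- val
      }
    }
    put(topology$excl12, 0)
    put(topology$excl13, 0)
    put(topology$pairs14, scale14)
  }
  S
}

pair_dist_matrix <- function(xyz) {
  D <- as.matrix(dist(xyz))
  if (any(D[upper.tri(D)] < 1e-6))
    stop("overlapping atoms (pair distance < 1e-6 A)")
  D
}

#' Coulomb energy without cutoff
#'
#' k * sum_{i<j} s_ij q_i q_j / r_ij with k = 332.0716 kcal A/(mol e^2);
#' s_ij = 0 for 1-2/1-3 pairs, the 1-4 scale for flagged pairs, else 1.
#'
#' @param xyz n x 3 coordinates (Angstrom).
#' @param charges partial charges (e).
#' @param topology optional Topology supplying exclusions.
#' @param options [mm_options()].
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(xyz, charges, topology = NULL,
                           options = mm_options()) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n < 2L) return(0)
  D <- pair_dist_matrix(xyz)
  S <- pair_scale_matrix(n, topology, options$ele_scale14)
  Q <- outer(charges, charges)
  E <- kCOUL * Q * S / D
  diag(E) <- 0
  sum(E[upper.tri(E)])
}

#' Lennard-Jones energy without cutoff
#'
#' sum_{i<j} s_ij eps_ij [(rmin_ij/r)^12 - 2 (rmin_ij/r)^6] with
#' rmin_ij = rmin_half_i + rmin_half_j and eps_ij = sqrt(eps_i eps_j).
#'
#' @param xyz n x 3 coordinates.
#' @param rmin_half per-atom rmin/2 (Angstrom).
#' @param epsilon per-atom well depths (kcal/mol, non-negative).
#' @param topology optional Topology supplying exclusions.
#' @param options [mm_options()].
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(xyz, rmin_half, epsilon, topology = NULL,
                      options = mm_options()) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n < 2L) return(0)
  D <- pair_dist_matrix(xyz)
  S <- pair_scale_matrix(n, topology, options$vdw_scale14)
  RM <- outer(rmin_half, rmin_half, `+`)
  EPS <- sqrt(outer(abs(epsilon), abs(epsilon)))
  diag(D) <- 1
  sr6 <- (RM / D)^6
  E <- S * EPS * (sr6^2 - 2 * sr6)
  diag(E) <- 0
  sum(E[upper.tri(E)])
}

## internal geometry helpers ------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

bend_angle <- function(xyz, i, j, k) {
  u <- xyz[i, ] - xyz[j, ]; v <- xyz[k, ] - xyz[j, ]
  nu <- vnorm(u); nv <- vnorm(v)
  ct <- sum(u * v) / (nu * nv)
  if (abs(ct) > 1 - 1e-10)
    stop("undefined (collinear) angle for atoms ", i, "-", j, "-", k)
  acos(ct)
}

dihedral_angle <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, ] - xyz[i, ]; b2 <- xyz[k, ] - xyz[j, ]
  b3 <- xyz[l, ] - xyz[k, ]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  atan2(sum(cross3(n1, n2) * b2) / vnorm(b2), sum(n1 * n2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Bonded (internal) energy
#'
#' Harmonic bonds and angles, cosine dihedrals, harmonic impropers, with a
#' per-term breakdown.
#'
#' @param topology a Topology.
#' @param xyz n x 3 coordinates.
#' @return list with `bond`, `angle`, `dihedral`, `improper`, `total`
#'   (kcal/mol).
#' @export
bonded_energy <- function(topology, xyz) {
  xyz <- as.matrix(xyz)
  e_bond <- 0; e_angle <- 0; e_dihedral <- 0; e_improper <- 0
  bd <- topology$bonds
  if (nrow(bd)) {
    b <- sqrt(rowSums((xyz[bd$i, , drop = FALSE] -
                         xyz[bd$j, , drop = FALSE])^2))
    e_bond <- sum(bd$k * (b - bd$b0)^2)
  }
  an <- topology$angles
  if (nrow(an)) {
    th <- vapply(seq_len(nrow(an)), function(r)
      bend_angle(xyz, an$i[r], an$j[r], an$k[r]), numeric(1))
    e_angle <- sum(an$kth * (th - an$th0 * pi / 180)^2)
  }
  dh <- topology$dihedrals
  if (nrow(dh)) {
    ph <- vapply(seq_len(nrow(dh)), function(r)
      dihedral_angle(xyz, dh$i[r], dh$j[r], dh$k[r], dh$l[r]), numeric(1))
    e_dihedral <- sum(dh$kphi * (1 + cos(dh$n * ph - dh$delta * pi / 180)))
  }
  im <- topology$impropers
  if (nrow(im)) {
    ps <- vapply(seq_len(nrow(im)), function(r)
      dihedral_angle(xyz, im$i[r], im$j[r], im$k[r], im$l[r]), numeric(1))
    dpsi <- ps - im$psi0 * pi / 180
    dpsi <- atan2(sin(dpsi), cos(dpsi))   # wrap to (-pi, pi]
    e_improper <- sum(im$kpsi * dpsi^2)
  }
  list(bond = e_bond, angle = e_angle, dihedral = e_dihedral,
       improper = e_improper,
       total = e_bond + e_angle + e_dihedral + e_improper)
}

#' Full molecular-mechanics energy of a parameterized structure
#'
#' @param structure parameterized Structure (charges, LJ assigned).
#' @param topology a Topology.
#' @param xyz optional coordinates overriding the structure's.
#' @param options [mm_options()].
#' @return list of class `EnergyComponents` with e_ele, e_vdw, e_int
#'   (bond+angle+dihedral+improper) and e_mm = e_ele + e_vdw + e_int,
#'   all kcal/mol.
#' @export
mm_energy <- function(structure, topology, xyz = NULL,
                      options = mm_options()) {
  at <- structure$atoms
  if (anyNA(at$charge) || anyNA(at$lj_rmin_half))
    stop("structure is not fully parameterized")
  if (is.null(xyz)) xyz <- coords(structure)
  e_ele <- coulomb_energy(xyz, at$charge, topology, options)
  e_vdw <- lj_energy(xyz, at$lj_rmin_half, at$lj_epsilon, topology, options)
  e_int <- bonded_energy(topology, xyz)$total
  structure(list(e_ele = e_ele, e_vdw = e_vdw, e_int = e_int,
                 e_mm = e_ele + e_vdw + e_int),
            class = "EnergyComponents")
}

#' Analytic gradient of the MM energy
#'
#' @inheritParams mm_energy
#' @return n x 3 matrix of dE/dxyz (kcal/mol/A).
#' @export
mm_gradient <- function(structure, topology, xyz = NULL,
                        options = mm_options()) {
  at <- structure$atoms
  if (is.null(xyz)) xyz <- coords(structure)
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  G <- matrix(0, n, 3)

  ## nonbonded: pairwise loops over the scale matrices
  D <- pair_dist_matrix(xyz)
  diag(D) <- Inf
  Sele <- pair_scale_matrix(n, topology, options$ele_scale14)
  Svdw <- pair_scale_matrix(n, topology, options$vdw_scale14)
  q <- at$charge
  RM <- outer(at$lj_rmin_half, at$lj_rmin_half, `+`)
  EPS <- sqrt(outer(abs(at$lj_epsilon), abs(at$lj_epsilon)))
  ## dE/dr for each pair
  dE_ele <- -kCOUL * outer(q, q) * Sele / D^2
  sr6 <- (RM / D)^6
  dE_vdw <- Svdw * EPS * 12 * (-sr6^2 + sr6) / D
  dEdr <- dE_ele + dE_vdw
  for (d in 1:3) {
    DIF <- outer(xyz[, d], xyz[, d], `-`)   # x_i - x_j
    G[, d] <- G[, d] + rowSums(dEdr * DIF / D)
  }

  add <- function(i, g) G[i, ] <<- G[i, ] + g

  bd <- topology$bonds
  if (nrow(bd)) for (r in seq_len(nrow(bd))) {
    i <- bd$i[r]; j <- bd$j[r]
    dv <- xyz[i, ] - xyz[j, ]
    b <- vnorm(dv)
    f <- 2 * bd$k[r] * (b - bd$b0[r]) / b
    add(i, f * dv); add(j, -f * dv)
  }

  an <- topology$angles
  if (nrow(an)) for (r in seq_len(nrow(an))) {
    i <- an$i[r]; j <- an$j[r]; k <- an$k[r]
    u <- xyz[i, ] - xyz[j, ]; v <- xyz[k, ] - xyz[j, ]
    nu <- vnorm(u); nv <- vnorm(v)
    uh <- u / nu; vh <- v / nv
    ct <- sum(uh * vh); st <- sqrt(max(1 - ct^2, 1e-12))
    th <- acos(max(-1, min(1, ct)))
    dV <- 2 * an$kth[r] * (th - an$th0[r] * pi / 180)
    di <- (ct * uh - vh) / (nu * st)
    dk <- (ct * vh - uh) / (nv * st)
    add(i, dV * di); add(k, dV * dk); add(j, -dV * (di + dk))
  }

  tors <- function(df, dVdphi_fun) {
    for (r in seq_len(nrow(df))) {
      i <- df$i[r]; j <- df$j[r]; k <- df$k[r]; l <- df$l[r]
      b1 <- xyz[j, ] - xyz[i, ]; b2 <- xyz[k, ] - xyz[j, ]
      b3 <- xyz[l, ] - xyz[k, ]
      n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
      nb2 <- vnorm(b2)
      phi <- atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2))
      dV <- dVdphi_fun(r, phi)
      p <- -(nb2 / sum(n1 * n1)) * n1
      qv <- (nb2 / sum(n2 * n2)) * n2
      s1 <- sum(b1 * b2) / nb2^2
      s2 <- sum(b3 * b2) / nb2^2
      add(i, dV * p)
      add(l, dV * qv)
      add(j, dV * (-p - s1 * p + s2 * qv))
      add(k, dV * (-qv + s1 * p - s2 * qv))
    }
  }
  dh <- topology$dihedrals
  if (nrow(dh)) tors(dh, function(r, phi)
    -dh$kphi[r] * dh$n[r] * sin(dh$n[r] * phi - dh$delta[r] * pi / 180))
  im <- topology$impropers
  if (nrow(im)) tors(im, function(r, phi) {
    dpsi <- phi - im$psi0[r] * pi / 180
    dpsi <- atan2(sin(dpsi), cos(dpsi))
    2 * im$kpsi[r] * dpsi
  })

  G
}
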