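## Deterministic solvent-accessible surface area (Shrake-Rupley style with
## a fixed golden-spiral point set; no randomness).

golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area
#'
#' Shrake-Rupley sampling on a deterministic golden-spiral point set: for
#' each atom, the fraction of points on the sphere of radius
#' (radius + probe) lying outside all neighbouring expanded spheres scales
#' the sphere's area. Zero-radius atoms are excluded with a warning.
#'
#' @param xyz n x 3 coordinates (Angstrom).
#' @param radii per-atom radii (Angstrom).
#' @param probe probe radius (default 1.4 A).
#' @param n_points sphere sampling points per atom (default 960).
#' @return list of class `SurfaceResult` with `per_atom` (A^2, zero for
#'   excluded atoms), `total` (A^2), `probe`, `n_points`.
#' @export
surface_area <- function(xyz, radii, probe = 1.4, n_points = 960L) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(length(radii) == n)
  if (any(radii <= 0)) {
    warning(sum(radii <= 0), " atom(s) with zero radius excluded from SASA")
  }
  active <- which(radii > 0)
  pts <- golden_spiral_points(n_points)
  per_atom <- numeric(n)
  R <- radii + probe
  for (ii in active) {
    ri <- R[ii]
    sphere <- sweep(pts * ri, 2, xyz[ii, ], `+`)
    ## neighbours whose expanded sphere can clip this one
    d2 <- rowSums(sweep(xyz[active, , drop = FALSE], 2, xyz[ii, ])^2)
    nb <- active[d2 < (ri + R[active])^2 & active != ii]
    acc <- rep(TRUE, n_points)
    for (jj in nb) {
      if (!any(acc)) break
      dd <- rowSums(sweep(sphere[acc, , drop = FALSE], 2, xyz[jj, ])^2)
      acc[acc] <- dd >= R[jj]^2
    }
    per_atom[ii] <- 4 * pi * ri^2 * mean(acc)
  }
  structure(list(per_atom = per_atom, total = sum(per_atom),
                 probe = probe, n_points = n_points),
            class = "SurfaceResult")
}

#' Nonpolar solvation parameters
#'
#' Linear surface-area model G_nonpolar = gamma * A + beta with the CHARMM
#' surface-module coefficients as defaults.
#'
#' @param gamma surface tension coefficient, kcal/mol/A^2 (default 0.00542).
#' @param beta intercept, kcal/mol (default 0.92).
#' @return list of class `NonpolarParams`.
#' @export
nonpolar_params <- function(gamma = 0.00542, beta = 0.92) {
  stopifnot(is.finite(gamma), is.finite(beta))
  structure(list(gamma = gamma, beta = beta), class = "NonpolarParams")
}

#' Nonpolar solvation free energy from a surface area
#'
#' @param area surface area in A^2 (or a SurfaceResult).
#' @param params [nonpolar_params()].
#' @return gamma * A + beta in kcal/mol.
#' @export
nonpolar_solvation <- function(area, params = nonpolar_params()) {
  if (inherits(area, "SurfaceResult")) area <- area$total
  stopifnot(area >= 0)
  params$gamma * area + params$beta
}
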