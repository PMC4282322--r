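## Rotational/translational entropies, reduced-region normal-mode analysis
## and the quantum harmonic-oscillator vibrational entropy.

#' Classical rotational/translational energy
#'
#' 3RT for the six rigid-body degrees of freedom (1.79 kcal/mol at 300 K).
#' This term cancels in relative binding free energies.
#'
#' @param temperature Kelvin.
#' @return energy in kcal/mol.
#' @export
classical_rt_energy <- function(temperature) {
  stopifnot(temperature >= 0)
  3 * kR * temperature
}

#' Translational entropy (Sackur-Tetrode)
#'
#' Ideal-gas translational entropy at a configurable standard
#' concentration (default 1 mol/L, the solution binding convention).
#'
#' @param total_mass amu.
#' @param temperature Kelvin.
#' @param standard_concentration mol/L (use 1/24.465... for the 1 atm,
#'   298 K gas standard state, i.e. molar volume 24.465 L).
#' @return entropy in kcal/mol/K.
#' @export
translational_entropy <- function(total_mass, temperature,
                                  standard_concentration = 1) {
  stopifnot(total_mass > 0, temperature > 0, standard_concentration > 0)
  cst <- flexpbsa_constants
  m <- total_mass * cst$amu_kg
  lambda <- cst$h_J / sqrt(2 * pi * m * cst$kB_J * temperature)  # m
  v_per_molecule <- 1e-3 / (standard_concentration * cst$avogadro) # m^3
  kR * (log(v_per_molecule / lambda^3) + 2.5)
}

#' Rotational entropy (classical rigid rotor)
#'
#' From the principal moments of inertia of the mass-weighted structure.
#' Linear (collinear) structures are refused; a linear-rotor branch is out
#' of scope.
#'
#' @param structure parameterized Structure (masses assigned), or an n x 3
#'   matrix with `masses` supplied.
#' @param temperature Kelvin.
#' @param symmetry_number rotational symmetry number (default 1).
#' @param masses amu, required when `structure` is a bare matrix.
#' @return entropy in kcal/mol/K.
#' @export
rotational_entropy <- function(structure, temperature, symmetry_number = 1,
                               masses = NULL) {
  if (inherits(structure, "Structure")) {
    xyz <- coords(structure)
    masses <- structure$atoms$mass
  } else xyz <- as.matrix(structure)
  stopifnot(!is.null(masses), nrow(xyz) >= 3L, temperature > 0)
  ctr <- colSums(xyz * masses) / sum(masses)
  X <- sweep(xyz, 2, ctr)
  I <- matrix(0, 3, 3)
  for (a in seq_len(nrow(X))) {
    r <- X[a, ]
    I <- I + masses[a] * (sum(r^2) * diag(3) - outer(r, r))
  }
  mom <- sort(eigen(I, symmetric = TRUE)$values, decreasing = TRUE)
  if (mom[3] / mom[1] < 1e-8)
    stop("linear/collinear structure: linear-rotor entropy not implemented")
  cst <- flexpbsa_constants
  ## I in amu A^2 -> kg m^2
  mom_si <- mom * cst$amu_kg * 1e-20
  theta <- 8 * pi^2 * cst$kB_J * temperature / cst$h_J^2
  z <- sqrt(pi) / symmetry_number * sqrt(prod(theta * mom_si))
  kR * (log(z) + 1.5)
}

#' Partition a complex into flexible and buffer regions
#'
#' The flexible region is the ligand plus every whole receptor residue
#' having any atom within `cutoff` of any ligand atom; the buffer is every
#' further whole residue within `buffer_width` beyond that (its atoms stay
#' fixed during minimization and contribute no Hessian rows); the remainder
#' is discarded. Residue inclusion is all-or-none.
#'
#' @param structure the complex Structure.
#' @param ligand_selection selection expression for the ligand.
#' @param cutoff flexible-region cutoff in Angstrom (default 8).
#' @param buffer_width extra buffer shell in Angstrom (default 4).
#' @return list of class `RegionPartition`: `flexible`, `buffer` (atom
#'   index vectors, disjoint), `cutoff`, `buffer_width`.
#' @export
reduced_region <- function(structure, ligand_selection, cutoff = 8,
                           buffer_width = 4) {
  lidx <- select_atoms(structure, ligand_selection)
  if (length(lidx) == 0L) stop("empty ligand selection")
  at <- structure$atoms
  xyz <- coords(structure)
  reskey <- paste(at$chain, at$resid, at$icode)
  other <- setdiff(seq_len(nrow(at)), lidx)
  mind_to <- function(set_idx, from_idx) {
    ## per atom in from_idx: min distance to set_idx
    vapply(from_idx, function(i)
      sqrt(min(colSums((t(xyz[set_idx, , drop = FALSE]) - xyz[i, ])^2))),
      numeric(1))
  }
  d_lig <- mind_to(lidx, other)
  flex_res <- unique(reskey[other[d_lig <= cutoff]])
  flexible <- sort(c(lidx, other[reskey[other] %in% flex_res]))
  rest <- setdiff(seq_len(nrow(at)), flexible)
  if (length(rest)) {
    d_flex <- mind_to(flexible, rest)
    buf_res <- unique(reskey[rest[d_flex <= buffer_width]])
    buffer <- sort(rest[reskey[rest] %in% buf_res])
  } else buffer <- integer(0)
  structure(list(flexible = flexible, buffer = buffer, cutoff = cutoff,
                 buffer_width = buffer_width),
            class = "RegionPartition")
}

#' Gradient-based energy minimization of a movable atom subset
#'
#' L-BFGS-B on the MM energy with its analytic gradient; only `movable_set`
#' atoms move. Converged when the RMS gradient over movable atoms drops to
#' `tolerance`; deterministic given its inputs.
#'
#' @param structure parameterized Structure.
#' @param topology matching Topology.
#' @param movable_set atom indices allowed to move (default: all).
#' @param tolerance RMS gradient target, kcal/mol/A (default 1e-4).
#' @param max_steps optimizer iteration budget per restart.
#' @param options [mm_options()].
#' @return list with `structure` (minimized), `energy`, `rms_gradient`,
#'   `converged`.
#' @export
minimize_energy <- function(structure, topology,
                            movable_set = seq_len(n_atoms(structure)),
                            tolerance = 1e-4, max_steps = 2000L,
                            options = mm_options()) {
  if (length(movable_set) == 0L) stop("movable set is empty")
  xyz0 <- coords(structure)
  mob <- movable_set
  model <- mm_model(structure, topology, options)
  pack <- function(x) as.numeric(t(x[mob, , drop = FALSE]))
  unpack <- function(p) {
    x <- xyz0
    x[mob, ] <- matrix(p, ncol = 3, byrow = TRUE)
    x
  }
  fn <- function(p) model$energy(unpack(p))
  gr <- function(p)
    as.numeric(t(model$gradient(unpack(p))[mob, , drop = FALSE]))
  p <- pack(xyz0)
  rmsg <- function(p) sqrt(mean(gr(p)^2))
  for (round in 1:6) {
    if (rmsg(p) <= tolerance) break
    opt <- stats::optim(p, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_steps,
                                       factr = 10, pgtol = tolerance / 100))
    p <- opt$par
  }
  final_rms <- rmsg(p)
  if (final_rms > tolerance)
    stop("minimization did not converge: RMS gradient ",
         signif(final_rms, 3), " > ", tolerance)
  x <- unpack(p)
  list(structure = set_coords(structure, x),
       energy = model$energy(x),
       rms_gradient = final_rms, converged = TRUE)
}

#' Normal modes of a flexible region
#'
#' Mass-weighted Hessian over the flexible atoms only (buffer atoms
#' contribute to the potential but get no Hessian rows), built by central
#' finite differences of the analytic gradient (step 1e-4 A), symmetrized,
#' then diagonalized. Frequencies are reported in ascending order;
#' eigenvalues below -1e-6 (imaginary modes) fail validation.
#'
#' @param structure minimized, parameterized Structure.
#' @param topology matching Topology.
#' @param flexible_set atom indices of the flexible region.
#' @param step finite-difference step (A).
#' @param options [mm_options()].
#' @param imaginary_tol eigenvalue threshold for the validation failure.
#' @return list of class `ModeSpectrum`: `frequencies` (cm^-1, ascending),
#'   `eigenvalues` (kcal/mol/A^2/amu), `n_modes`, `n_near_zero`.
#' @export
normal_modes <- function(structure, topology, flexible_set,
                         step = 1e-4, options = mm_options(),
                         imaginary_tol = 1e-6) {
  mob <- flexible_set
  nf <- length(mob)
  if (nf == 0L) stop("empty flexible set")
  xyz0 <- coords(structure)
  model <- mm_model(structure, topology, options)
  grad_flex <- function(x)
    as.numeric(t(model$gradient(x)[mob, , drop = FALSE]))
  H <- matrix(0, 3 * nf, 3 * nf)
  for (a in seq_len(nf)) for (d in 1:3) {
    col <- 3 * (a - 1) + d
    xp <- xyz0; xp[mob[a], d] <- xp[mob[a], d] + step
    xm <- xyz0; xm[mob[a], d] <- xm[mob[a], d] - step
    H[, col] <- (grad_flex(xp) - grad_flex(xm)) / (2 * step)
  }
  H <- (H + t(H)) / 2
  m <- rep(structure$atoms$mass[mob], each = 3)
  Hm <- H / sqrt(outer(m, m))
  ev <- eigen(Hm, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -imaginary_tol))
    stop("imaginary modes present: ", sum(ev < -imaginary_tol),
         " eigenvalue(s) below -", imaginary_tol,
         " (most negative ", signif(min(ev), 3), ")")
  lam <- sort(pmax(ev, 0))
  freq <- flexpbsa_constants$freq_factor * sqrt(lam)
  structure(list(frequencies = freq, eigenvalues = lam,
                 n_modes = length(lam),
                 n_near_zero = sum(freq < 1)),
            class = "ModeSpectrum")
}

#' Vibrational entropy of a mode spectrum
#'
#' Quantum harmonic oscillator: S = R sum_i [x/(e^x - 1) - ln(1 - e^-x)],
#' x = h nu / k_B T. Near-zero frequencies (rigid-body remnants) are
#' skipped with a warning. A classical variant (R sum [1 - ln x]) is
#' available for comparison.
#'
#' @param mode_spectrum a ModeSpectrum (or numeric frequencies, cm^-1).
#' @param temperature Kelvin.
#' @param classical use the classical oscillator entropy.
#' @param zero_tol frequencies below this (cm^-1) are skipped.
#' @return entropy in kcal/mol/K.
#' @export
vibrational_entropy <- function(mode_spectrum, temperature,
                                classical = FALSE, zero_tol = 1e-3) {
  freq <- if (inherits(mode_spectrum, "ModeSpectrum"))
    mode_spectrum$frequencies else as.numeric(mode_spectrum)
  stopifnot(temperature > 0, all(freq >= 0))
  skip <- freq < zero_tol
  if (any(skip))
    warning(sum(skip), " near-zero frequencies skipped in S_vib")
  x <- flexpbsa_constants$hc_over_k * freq[!skip] / temperature
  if (classical) return(kR * sum(1 - log(x)))
  kR * sum(x / (exp(x) - 1) - log(1 - exp(-x)))
}

#' Entropy summary for a bound species
#'
#' Convenience wrapper returning S_trans, S_rot, S_vib and their -T*S
#' values at the stated temperature and standard state.
#'
#' @param structure parameterized Structure (whole species for S_trans and
#'   S_rot).
#' @param mode_spectrum a ModeSpectrum for S_vib (optional).
#' @param temperature Kelvin.
#' @param standard_concentration mol/L for S_trans.
#' @param symmetry_number for S_rot.
#' @return list of class `EntropyResult`.
#' @export
entropy_summary <- function(structure, mode_spectrum = NULL,
                            temperature = 300, standard_concentration = 1,
                            symmetry_number = 1) {
  s_tr <- translational_entropy(sum(structure$atoms$mass), temperature,
                                standard_concentration)
  s_rot <- rotational_entropy(structure, temperature, symmetry_number)
  s_vib <- if (!is.null(mode_spectrum))
    vibrational_entropy(mode_spectrum, temperature) else NA_real_
  structure(list(s_trans = s_tr, s_rot = s_rot, s_vib = s_vib,
                 minus_t_s_trans = -temperature * s_tr,
                 minus_t_s_rot = -temperature * s_rot,
                 minus_t_s_vib = if (is.na(s_vib)) NA_real_
                 else -temperature * s_vib,
                 temperature = temperature,
                 standard_concentration = standard_concentration),
            class = "EntropyResult")
}
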