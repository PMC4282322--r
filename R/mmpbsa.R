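## MM-PBSA assembly: per-snapshot free energies, single- and
## three-trajectory binding estimates, reorganization free energies,
## autocorrelation-aware standard errors, and alanine scanning.

DELTA_COMPONENTS <- c("e_ele", "e_vdw", "e_int", "e_mm", "g_pb", "g_sa",
                      "g_noS")

#' Options for MM-PBSA snapshot energies
#'
#' @param include_pb compute the Poisson-Boltzmann polar term (default TRUE;
#'   disable for fast MM-only bookkeeping).
#' @param include_sa compute the surface-area nonpolar term (default TRUE).
#' @param pb [pb_options()] for the polar term.
#' @param nonpolar [nonpolar_params()] for the nonpolar term.
#' @param mm [mm_options()] for the gas-phase energies.
#' @param probe SASA probe radius (A).
#' @param sasa_points SASA sphere points per atom.
#' @param include_rot_tr add the classical 3RT rotational/translational
#'   energy per species (cancels in relative binding energies; default
#'   FALSE).
#' @param temperature Kelvin (used by the 3RT term and checked when
#'   entropies are assembled).
#' @return list of class `ComputeOptions`.
#' @export
compute_options <- function(include_pb = TRUE, include_sa = TRUE,
                            pb = pb_options(h = 0.8, padding = 6),
                            nonpolar = nonpolar_params(),
                            mm = mm_options(), probe = 1.4,
                            sasa_points = 240L, include_rot_tr = FALSE,
                            temperature = 300) {
  structure(list(include_pb = include_pb, include_sa = include_sa,
                 pb = pb, nonpolar = nonpolar, mm = mm, probe = probe,
                 sasa_points = sasa_points, include_rot_tr = include_rot_tr,
                 temperature = temperature),
            class = "ComputeOptions")
}

#' Free energy of one snapshot
#'
#' G_noS = E_MM + G_PB + G_SA for a single conformation of a fully
#' parameterized species (entropy terms are handled separately by the
#' entropy module).
#'
#' @param structure parameterized Structure.
#' @param topology matching Topology.
#' @param xyz optional coordinates overriding the structure's.
#' @param options [compute_options()].
#' @return list of class `SnapshotEnergies` with e_ele, e_vdw, e_int,
#'   e_mm, area, g_sa, g_pb, g_noS (kcal/mol).
#' @export
snapshot_free_energy <- function(structure, topology, xyz = NULL,
                                 options = compute_options()) {
  if (is.null(xyz)) xyz <- coords(structure)
  em <- mm_energy(structure, topology, xyz, options$mm)
  area <- 0; g_sa <- 0
  if (options$include_sa) {
    sr <- surface_area(xyz, structure$atoms$pb_radius,
                       probe = options$probe,
                       n_points = options$sasa_points)
    area <- sr$total
    g_sa <- nonpolar_solvation(area, options$nonpolar)
  }
  g_pb <- 0
  if (options$include_pb)
    g_pb <- polar_solvation(set_coords(structure, xyz), options$pb)$g_pb
  e_rt <- if (options$include_rot_tr)
    classical_rt_energy(options$temperature) else 0
  structure(list(e_ele = em$e_ele, e_vdw = em$e_vdw, e_int = em$e_int,
                 e_mm = em$e_mm + e_rt, area = area, g_sa = g_sa,
                 g_pb = g_pb,
                 g_noS = em$e_mm + e_rt + g_pb + g_sa),
            class = "SnapshotEnergies")
}

## per-frame energy table for one species
species_energy_table <- function(structure, topology, frames,
                                 options = compute_options(),
                                 species = "species") {
  rows <- lapply(seq_along(frames), function(f) {
    se <- snapshot_free_energy(structure, topology, frames[[f]], options)
    data.frame(species = species, frame = f, e_ele = se$e_ele,
               e_vdw = se$e_vdw, e_int = se$e_int, e_mm = se$e_mm,
               area = se$area, g_sa = se$g_sa, g_pb = se$g_pb,
               g_noS = se$g_noS)
  })
  do.call(rbind, rows)
}

#' Autocorrelation-aware standard error of a trajectory mean
#'
#' Estimates the statistical inefficiency g = 1 + 2 sum_k (1 - k/N) rho_k
#' (the sum truncated at the first non-positive autocorrelation) and
#' reports se = sd * sqrt(g / N). Means are order-invariant; this error
#' estimate is deliberately order-sensitive through the autocorrelation.
#'
#' @param series numeric vector (length >= 2; constant series give 0).
#' @param frame_interval time between frames (units of the returned
#'   correlation time; default 1 frame).
#' @return list with `se`, `correlation_time` (= (g-1)/2 *
#'   frame_interval), `g` (statistical inefficiency), `n`.
#' @export
standard_error <- function(series, frame_interval = 1) {
  n <- length(series)
  if (n < 2L) return(list(se = NA_real_, correlation_time = NA_real_,
                          g = NA_real_, n = n))
  v <- stats::var(series)
  if (v == 0) return(list(se = 0, correlation_time = 0, g = 1, n = n))
  x <- series - mean(series)
  g <- 1
  for (k in seq_len(n - 1L)) {
    rho <- sum(x[1:(n - k)] * x[(k + 1):n]) / ((n - k) * v)
    if (rho <= 0) break
    g <- g + 2 * (1 - k / n) * rho
  }
  list(se = sqrt(v * g / n), correlation_time = (g - 1) / 2 * frame_interval,
       g = g, n = n)
}

## shared helper: build the Delta table and summaries
make_binding_estimate <- function(mode, per_frame_delta, per_species = NULL,
                                  frame_interval = 1, discard_frames = 0L) {
  comp_summary <- do.call(rbind, lapply(DELTA_COMPONENTS, function(cn) {
    x <- per_frame_delta[[cn]]
    if (!is.null(x)) {
      se <- standard_error(x, frame_interval)
      data.frame(component = cn, mean = mean(x),
                 se = if (length(x) > 1L) se$se else NA_real_,
                 correlation_time = if (length(x) > 1L)
                   se$correlation_time else NA_real_)
    } else NULL
  }))
  rownames(comp_summary) <- NULL
  structure(list(mode = mode, components = comp_summary,
                 per_frame = per_frame_delta, per_species = per_species,
                 n_frames = nrow(per_frame_delta),
                 discard_frames = discard_frames,
                 minus_t_ds_rt = NA_real_, minus_t_ds_v = NA_real_,
                 minus_t_ds_tot = NA_real_, dg_tot = NA_real_),
            class = "BindingEstimate")
}

#' @export
print.BindingEstimate <- function(x, ...) {
  cat(sprintf("MM-PBSA binding estimate (%s-trajectory, %d frames)\n",
              x$mode, x$n_frames))
  cs <- x$components
  for (r in seq_len(nrow(cs)))
    cat(sprintf("  D%-6s %10.3f%s\n", cs$component[r], cs$mean[r],
                if (is.finite(cs$se[r])) sprintf(" +/- %.3f", cs$se[r])
                else ""))
  if (is.finite(x$dg_tot))
    cat(sprintf("  -TdS_tot %8.3f\n  DG_tot  %9.3f\n",
                x$minus_t_ds_tot, x$dg_tot))
  invisible(x)
}

discard_count <- function(trajectory, discard) {
  if (discard <= 0) return(0L)
  fi <- trajectory$frame_interval
  if (is.na(fi)) as.integer(discard) else as.integer(floor(discard / fi))
}

#' Single-trajectory MM-PBSA binding estimate
#'
#' Receptor and ligand coordinates are extracted per frame from the complex
#' trajectory; bonded terms then cancel exactly and Delta E_int is zero by
#' construction (and is set to exactly 0).
#'
#' @param structure parameterized complex Structure.
#' @param topology complex Topology.
#' @param trajectory complex Trajectory.
#' @param receptor_selection,ligand_selection selections that partition the
#'   complex (no overlap, union = all atoms).
#' @param discard initial span to omit, in the trajectory's frame_interval
#'   units (frames when no interval is set).
#' @param options [compute_options()].
#' @return a BindingEstimate.
#' @export
binding_estimate_single <- function(structure, topology, trajectory,
                                    receptor_selection, ligand_selection,
                                    discard = 0, options = compute_options()) {
  ridx <- select_atoms(structure, receptor_selection)
  lidx <- select_atoms(structure, ligand_selection)
  if (length(intersect(ridx, lidx)) > 0L)
    stop("receptor and ligand selections overlap")
  if (length(union(ridx, lidx)) != n_atoms(structure))
    stop("receptor and ligand selections must partition the complex")
  rstr <- subset_structure(structure, ridx)
  rtop <- subset_topology(topology, ridx)
  lstr <- subset_structure(structure, lidx)
  ltop <- subset_topology(topology, lidx)

  nd <- discard_count(trajectory, discard)
  frames <- trajectory$frames[(nd + 1):n_frames(trajectory)]
  if (length(frames) < 1L) stop("no frames left after discard")

  tc <- species_energy_table(structure, topology, frames, options, "complex")
  tr <- species_energy_table(rstr, rtop,
                             lapply(frames, function(f)
                               f[ridx, , drop = FALSE]),
                             options, "receptor")
  tl <- species_energy_table(lstr, ltop,
                             lapply(frames, function(f)
                               f[lidx, , drop = FALSE]),
                             options, "ligand")
  d <- data.frame(frame = tc$frame)
  for (cn in DELTA_COMPONENTS) d[[cn]] <- tc[[cn]] - tr[[cn]] - tl[[cn]]
  ## bonded terms cancel exactly in the extraction scheme
  d$g_noS <- d$g_noS - d$e_int
  d$e_mm <- d$e_mm - d$e_int
  d$e_int <- 0
  fi <- trajectory$frame_interval
  make_binding_estimate("single", d,
                        per_species = rbind(tc, tr, tl),
                        frame_interval = if (is.na(fi)) 1 else fi,
                        discard_frames = nd)
}

#' Three-trajectory MM-PBSA binding estimate
#'
#' Each species' free energy is averaged over its own independent ensemble
#' before differencing; Delta E_int is generally nonzero.
#'
#' @param complex,receptor,ligand each a list with `structure`,
#'   `topology`, `trajectory` for that species.
#' @param discard initial span omitted from every trajectory (same rule as
#'   [binding_estimate_single()]).
#' @param options [compute_options()].
#' @return a BindingEstimate (component se propagated across species as
#'   the root sum of squares).
#' @export
binding_estimate_three <- function(complex, receptor, ligand, discard = 0,
                                   options = compute_options()) {
  species <- list(complex = complex, receptor = receptor, ligand = ligand)
  tabs <- lapply(names(species), function(nm) {
    sp <- species[[nm]]
    nd <- discard_count(sp$trajectory, discard)
    frames <- sp$trajectory$frames[(nd + 1):n_frames(sp$trajectory)]
    if (length(frames) < 1L) stop("no frames left after discard for ", nm)
    species_energy_table(sp$structure, sp$topology, frames, options, nm)
  })
  names(tabs) <- names(species)

  comp_summary <- do.call(rbind, lapply(DELTA_COMPONENTS, function(cn) {
    stats_sp <- lapply(tabs, function(tb) {
      fi <- 1
      list(mean = mean(tb[[cn]]),
           se = standard_error(tb[[cn]], fi)$se)
    })
    data.frame(component = cn,
               mean = stats_sp$complex$mean - stats_sp$receptor$mean -
                 stats_sp$ligand$mean,
               se = sqrt(sum(vapply(stats_sp, function(s)
                 if (is.na(s$se)) 0 else s$se^2, numeric(1)))),
               correlation_time = NA_real_)
  }))
  est <- make_binding_estimate("three",
                               data.frame(frame = integer(0)),
                               per_species = do.call(rbind, tabs))
  est$components <- comp_summary
  est$n_frames <- nrow(tabs$complex)
  est
}

#' Reorganization free energy of one species
#'
#' Mean G_noS over the conformations the species adopts in the complex
#' (computed as the isolated species) minus the mean over its free
#' ensemble. Zero for identical ensembles; antisymmetric under swapping.
#'
#' @param structure parameterized species Structure.
#' @param topology species Topology.
#' @param complex_frames list of species coordinate matrices extracted from
#'   the complex ensemble.
#' @param free_frames list of species coordinate matrices from the free
#'   ensemble.
#' @param options [compute_options()].
#' @return list of class `ReorganizationResult`: `mean_in_complex`,
#'   `mean_free`, `delta`, `se` (root sum of squares of the two ensemble
#'   standard errors).
#' @export
reorganization_energy <- function(structure, topology, complex_frames,
                                  free_frames,
                                  options = compute_options()) {
  if (nrow(structure$atoms) != nrow(complex_frames[[1]]) ||
      nrow(structure$atoms) != nrow(free_frames[[1]]))
    stop("ensemble atom counts do not match the species structure")
  tc <- species_energy_table(structure, topology, complex_frames, options,
                             "in_complex")
  tf <- species_energy_table(structure, topology, free_frames, options,
                             "free")
  se_c <- standard_error(tc$g_noS)$se
  se_f <- standard_error(tf$g_noS)$se
  structure(list(mean_in_complex = mean(tc$g_noS),
                 mean_free = mean(tf$g_noS),
                 delta = mean(tc$g_noS) - mean(tf$g_noS),
                 se = sqrt(sum(c(se_c, se_f)^2, na.rm = TRUE))),
            class = "ReorganizationResult")
}

## ---- alanine scanning -----------------------------------------------------

ALA_BACKBONE <- c("N", "CA", "C", "O", "OXT", "H", "HN", "HA", "HA1", "HA2")

#' Mutate a residue to alanine
#'
#' Side-chain atoms beyond C-beta are deleted, the residue is retyped to
#' alanine (parameters looked up from the structure's parameter table), the
#' backbone and C-beta coordinates are untouched, and the topology is
#' restricted consistently. Alanine beta-hydrogens are rebuilt only when the
#' parameter set defines them; the bundled fixtures are heavy-atom-only, so
#' nothing needs rebuilding there. Glycine (no C-beta) and proline (ring
#' through the backbone) targets are refused.
#'
#' @param structure parameterized Structure (from [read_parameters()]).
#' @param topology matching Topology.
#' @param chain,resid residue to mutate.
#' @return list with `structure`, `topology`, `kept` (indices of retained
#'   atoms in the original numbering).
#' @export
mutate_to_alanine <- function(structure, topology, chain, resid) {
  at <- structure$atoms
  res <- which(at$chain == chain & at$resid == resid)
  if (length(res) == 0L)
    stop("residue ", chain, ":", resid, " not found")
  resname <- unique(at$resname[res])
  if (toupper(resname) == "GLY")
    stop("cannot mutate glycine (no C-beta) to alanine")
  if (toupper(resname) == "PRO")
    stop("cannot mutate proline (backbone ring) to alanine")
  if (!"CB" %in% toupper(at$name[res]))
    stop("residue ", chain, ":", resid, " has no C-beta atom")
  keep_in_res <- res[toupper(at$name[res]) %in% c(ALA_BACKBONE, "CB", "HB1",
                                                  "HB2", "HB3")]
  kept <- sort(c(setdiff(seq_len(nrow(at)), res), keep_in_res))
  st <- structure
  st$atoms <- at[kept, , drop = FALSE]
  st$atoms$resname[st$atoms$chain == chain &
                     st$atoms$resid == resid] <- "ALA"
  rownames(st$atoms) <- NULL
  ## retype the mutated residue from the parameter table
  types <- structure$param_types
  if (!is.null(types)) {
    mut <- which(st$atoms$chain == chain & st$atoms$resid == resid)
    for (i in mut) {
      key <- paste("ALA", toupper(st$atoms$name[i]))
      tp <- types[[key]]
      if (is.null(tp))
        stop("parameter set lacks an ALA entry for atom ",
             st$atoms$name[i])
      st$atoms$charge[i] <- tp$vals[1]
      st$atoms$mass[i] <- tp$vals[2]
      st$atoms$pb_radius[i] <- tp$vals[3]
      st$atoms$lj_rmin_half[i] <- tp$vals[4]
      st$atoms$lj_epsilon[i] <- tp$vals[5]
    }
  }
  list(structure = st, topology = subset_topology(topology, kept),
       kept = kept)
}

parse_mutation_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z])([0-9]+)A$", label))[[1]]
  if (length(m) != 3L)
    stop("mutation label must look like L47A: ", label)
  list(wt = toupper(m[2]), resid = as.integer(m[3]))
}

#' Computational alanine scan
#'
#' For each mutation the complex (and, in three-trajectory mode, the free
#' ligand) ensemble is mutated identically in every frame - conformations
#' are reused from the wild type, no re-simulation - and the full Delta
#' components are recomputed. A null mutation (X -> X rebuild, e.g. A25A)
#' is the control and must give Delta Delta G_noS near zero.
#'
#' @param structure,topology,trajectory the wild-type complex.
#' @param receptor_selection,ligand_selection partition of the complex.
#' @param mutations character vector of labels like "L47A" (resid on the
#'   ligand chain).
#' @param ligand_chain chain label carrying the mutations.
#' @param mode "single" or "three"; in three mode supply `ligand` (free
#'   ligand species list) and optionally `receptor`.
#' @param ligand,receptor species lists for three-trajectory mode.
#' @param discard initial span omitted.
#' @param options [compute_options()].
#' @return data.frame, one row per mutation, with the Delta component
#'   means, dg_noS and ddg_noS relative to the wild type.
#' @export
alanine_scan <- function(structure, topology, trajectory,
                         receptor_selection, ligand_selection, mutations,
                         ligand_chain, mode = c("single", "three"),
                         ligand = NULL, receptor = NULL, discard = 0,
                         options = compute_options()) {
  mode <- match.arg(mode)
  wt <- if (mode == "single")
    binding_estimate_single(structure, topology, trajectory,
                            receptor_selection, ligand_selection,
                            discard, options)
  else binding_estimate_three(list(structure = structure,
                                   topology = topology,
                                   trajectory = trajectory),
                              receptor, ligand, discard, options)
  wt_noS <- wt$components$mean[wt$components$component == "g_noS"]

  rows <- lapply(mutations, function(lab) {
    mut <- parse_mutation_label(lab)
    target <- which(structure$atoms$chain == ligand_chain &
                      structure$atoms$resid == mut$resid)
    if (length(target) == 0L)
      stop("mutation target ", lab, " not found on chain ", ligand_chain)
    null_mut <- toupper(structure$atoms$resname[target[1]]) == "ALA"
    mc <- mutate_to_alanine(structure, topology, ligand_chain, mut$resid)
    traj_mut <- new_trajectory(lapply(trajectory$frames, function(f)
      f[mc$kept, , drop = FALSE]), trajectory$frame_interval)
    est <- if (mode == "single")
      binding_estimate_single(mc$structure, mc$topology, traj_mut,
                              receptor_selection, ligand_selection,
                              discard, options)
    else {
      lig_mut <- mutate_to_alanine(ligand$structure, ligand$topology,
                                   ligand_chain, mut$resid)
      lig_traj <- new_trajectory(lapply(ligand$trajectory$frames,
                                        function(f)
                                          f[lig_mut$kept, , drop = FALSE]),
                                 ligand$trajectory$frame_interval)
      binding_estimate_three(list(structure = mc$structure,
                                  topology = mc$topology,
                                  trajectory = traj_mut),
                             receptor,
                             list(structure = lig_mut$structure,
                                  topology = lig_mut$topology,
                                  trajectory = lig_traj),
                             discard, options)
    }
    cm <- est$components
    g_noS <- cm$mean[cm$component == "g_noS"]
    data.frame(mutation = lab, null_control = null_mut,
               d_e_ele = cm$mean[cm$component == "e_ele"],
               d_e_vdw = cm$mean[cm$component == "e_vdw"],
               d_e_int = cm$mean[cm$component == "e_int"],
               d_g_pb = cm$mean[cm$component == "g_pb"],
               d_g_sa = cm$mean[cm$component == "g_sa"],
               dg_noS = g_noS, ddg_noS = g_noS - wt_noS)
  })
  out <- do.call(rbind, rows)
  attr(out, "wild_type") <- wt
  out
}

#' Attach entropy terms and total binding free energy
#'
#' Implements the bookkeeping -T dS_tot = -T dS_rt - T dS_v and
#' dG_tot = dG_noS + (-T dS_tot), with -T dS entries entering as positive
#' additions to a negative dG_noS.
#'
#' @param binding_estimate a BindingEstimate.
#' @param minus_t_ds_rt,minus_t_ds_v the -T*dS terms (kcal/mol) at
#'   `temperature`.
#' @param temperature Kelvin; must match the estimate's compute
#'   temperature.
#' @param estimate_temperature temperature the estimate was computed at
#'   (default 300).
#' @return the BindingEstimate with minus_t_ds_* and dg_tot filled in.
#' @export
assemble_total <- function(binding_estimate, minus_t_ds_rt = 0,
                           minus_t_ds_v = 0, temperature = 300,
                           estimate_temperature = 300) {
  if (abs(temperature - estimate_temperature) > 1e-9)
    stop("temperature mismatch between entropy terms and binding estimate")
  be <- binding_estimate
  be$minus_t_ds_rt <- minus_t_ds_rt
  be$minus_t_ds_v <- minus_t_ds_v
  be$minus_t_ds_tot <- minus_t_ds_rt + minus_t_ds_v
  g_noS <- be$components$mean[be$components$component == "g_noS"]
  be$dg_tot <- g_noS + be$minus_t_ds_tot
  be
}
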