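# Fast compute options for bookkeeping tests: MM + SA only. The PB term is
# exercised end-to-end in the acceptance suite; estimator identities hold
# for any deterministic per-snapshot energy.
fast_opts <- function(pb = FALSE)
  compute_options(include_pb = pb, pb = pb_options(h = 0.8, padding = 6),
                  sasa_points = 240L)

test_that("snapshot free energy is the sum of its independently computed terms", {
  toy <- toy_fixture()
  st <- toy$structure; topo <- toy$topology
  opts <- fast_opts()
  se <- snapshot_free_energy(st, topo, options = opts)
  em <- mm_energy(st, topo)
  sr <- surface_area(coords(st), st$atoms$pb_radius, n_points = 240L)
  expect_equal(se$e_mm, em$e_mm, tolerance = 1e-10)
  expect_equal(se$g_sa, 0.00542 * sr$total + 0.92, tolerance = 1e-10)
  expect_equal(se$g_noS, se$e_mm + se$g_pb + se$g_sa, tolerance = 1e-10)

  # zero-charge, zero-LJ system at bonded equilibrium -> g_noS = beta
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  st0 <- bare_structure(xyz, charge = 0, rmin_half = 0, epsilon = 0,
                        pb_radius = 0)
  topo0 <- new_topology(2, bonds = data.frame(i = 1, j = 2, k = 300,
                                              b0 = 1.5))
  expect_warning(
    se0 <- snapshot_free_energy(st0, topo0, options = fast_opts()),
    "zero radius")
  expect_equal(se0$g_noS, 0.92, tolerance = 1e-12)

  # determinism
  expect_identical(snapshot_free_energy(st, topo, options = opts)$g_noS,
                   se$g_noS)
})

test_that("single-trajectory estimator forces exact bonded cancellation", {
  toy <- toy_fixture()
  ens <- make_ensemble(toy, n_frames = 5, seed = 3)
  est <- binding_estimate_single(toy$structure, toy$topology,
                                 ens$complex$trajectory,
                                 "chain A", "chain B",
                                 options = fast_opts())
  cm <- est$components
  expect_identical(cm$mean[cm$component == "e_int"], 0)
  expect_true(all(est$per_frame$e_int == 0))
  # bookkeeping: g_noS mean equals the sum of component means
  expect_equal(cm$mean[cm$component == "g_noS"],
               sum(cm$mean[cm$component %in%
                             c("e_ele", "e_vdw", "e_int", "g_pb", "g_sa")]),
               tolerance = 1e-8)
  # overlapping / non-partitioning selections error
  expect_error(binding_estimate_single(toy$structure, toy$topology,
                                       ens$complex$trajectory,
                                       "chain A", "chain A or chain B"),
               "overlap")
  expect_error(binding_estimate_single(toy$structure, toy$topology,
                                       ens$complex$trajectory,
                                       "chain A and resid 1:10", "chain B"),
               "partition")

  # one-frame trajectory: means defined, SE absent
  one <- new_trajectory(ens$complex$trajectory$frames[1])
  est1 <- binding_estimate_single(toy$structure, toy$topology, one,
                                  "chain A", "chain B",
                                  options = fast_opts())
  expect_true(all(is.na(est1$components$se)))
  expect_equal(est1$components$mean[est1$components$component == "g_noS"],
               est$per_frame$g_noS[1] - est$per_frame$e_int[1],
               tolerance = 1e-10)
})

test_that("three-trajectory estimator reproduces single mode on extracted frames", {
  toy <- toy_fixture()
  ens <- make_ensemble(toy, n_frames = 4, seed = 5)
  ridx <- ens$receptor_idx; lidx <- ens$ligand_idx
  opts <- fast_opts(pb = TRUE)   # full energy model, coarse PB

  single <- binding_estimate_single(toy$structure, toy$topology,
                                    ens$complex$trajectory,
                                    "chain A", "chain B", options = opts)
  extract <- function(idx) new_trajectory(lapply(
    ens$complex$trajectory$frames, function(f) f[idx, , drop = FALSE]))
  three <- binding_estimate_three(
    list(structure = toy$structure, topology = toy$topology,
         trajectory = ens$complex$trajectory),
    list(structure = ens$receptor$structure,
         topology = ens$receptor$topology, trajectory = extract(ridx)),
    list(structure = ens$ligand$structure,
         topology = ens$ligand$topology, trajectory = extract(lidx)),
    options = opts)
  for (cn in c("e_ele", "e_vdw", "e_int", "e_mm", "g_pb", "g_sa", "g_noS"))
    expect_equal(three$components$mean[three$components$component == cn],
                 single$components$mean[single$components$component == cn],
                 tolerance = 1e-8, label = cn)
})

test_that("independent strained ensembles give positive internal strain", {
  toy <- toy_fixture()
  ens <- make_ensemble(toy, n_frames = 5, seed = 7, fluctuation_rms = 0,
                       ligand_strain = 0.1)
  three <- binding_estimate_three(ens$complex, ens$receptor, ens$ligand,
                                  options = fast_opts())
  de_int <- three$components$mean[three$components$component == "e_int"]
  expect_gt(de_int, 0)
  expect_equal(de_int, ens$strain_energy, tolerance = 0.1)

  # arithmetic oracle: means computed by hand from the per-species tables
  tabs <- three$per_species
  hand <- mean(tabs$g_noS[tabs$species == "complex"]) -
    mean(tabs$g_noS[tabs$species == "receptor"]) -
    mean(tabs$g_noS[tabs$species == "ligand"])
  expect_equal(three$components$mean[
    three$components$component == "g_noS"], hand, tolerance = 1e-10)
})

test_that("reorganization energy isolates the constructed strain", {
  toy <- toy_fixture()
  ens <- make_ensemble(toy, n_frames = 4, seed = 9, fluctuation_rms = 0,
                       ligand_strain = 0.12)
  lidx <- ens$ligand_idx
  in_complex <- lapply(ens$complex$trajectory$frames,
                       function(f) f[lidx, , drop = FALSE])
  free <- ens$ligand$trajectory$frames
  # identical ensembles -> exactly 0
  same <- reorganization_energy(ens$ligand$structure,
                                ens$ligand$topology, free, free,
                                options = fast_opts())
  expect_identical(same$delta, 0)
  # strain-only construction: MM term carries k * stretch^2
  opt_mm <- compute_options(include_pb = FALSE, include_sa = FALSE)
  ro <- reorganization_energy(ens$ligand$structure, ens$ligand$topology,
                              in_complex, free, options = opt_mm)
  expect_equal(ro$delta, ens$strain_energy, tolerance = 0.1 *
                 ens$strain_energy)
  # antisymmetry under ensemble swap
  ro_swap <- reorganization_energy(ens$ligand$structure,
                                   ens$ligand$topology, free, in_complex,
                                   options = opt_mm)
  expect_equal(ro_swap$delta, -ro$delta, tolerance = 1e-10)
  # full g_noS variant keeps the sign and rough size
  ro_full <- reorganization_energy(ens$ligand$structure,
                                   ens$ligand$topology, in_complex, free,
                                   options = fast_opts())
  expect_gt(ro_full$delta, 0)
})

test_that("standard error estimator matches i.i.d. and AR(1) closed forms", {
  # constant series
  expect_equal(standard_error(rep(2.5, 100))$se, 0)
  expect_equal(standard_error(rep(2.5, 100))$correlation_time, 0)

  set.seed(71)
  x <- rnorm(1e4)
  se <- standard_error(x)
  expect_equal(se$se, 1 / sqrt(1e4), tolerance = 0.15)

  rho <- 0.9
  n <- 1e5
  set.seed(72)
  ar <- as.numeric(stats::arima.sim(list(ar = rho), n = n,
                                    sd = sqrt(1 - rho^2)))
  se_ar <- standard_error(ar)
  closed <- sqrt((1 + rho) / (1 - rho)) / sqrt(n)
  expect_equal(se_ar$se, closed, tolerance = 0.15)
  expect_gt(se_ar$correlation_time, 1)

  # frame ordering: means invariant; the documented order sensitivity of
  # the SE shows up as a larger estimate for the ordered AR(1) series
  perm <- sample(n)
  expect_gt(se_ar$se, standard_error(ar[perm])$se * 0.9)
})

test_that("alanine mutation truncates beyond C-beta and refuses Gly/Pro", {
  toy <- toy_fixture()
  st <- toy$structure; topo <- toy$topology
  # Leu -> Ala on the ligand (chain B resid 3): CG removed, CB kept
  mut <- mutate_to_alanine(st, topo, "B", 3L)
  at0 <- st$atoms; at1 <- mut$structure$atoms
  expect_false(any(at1$chain == "B" & at1$resid == 3 & at1$name == "CG"))
  expect_true(any(at1$chain == "B" & at1$resid == 3 & at1$name == "CB"))
  expect_true(all(at1$resname[at1$chain == "B" & at1$resid == 3] == "ALA"))
  # backbone coordinates identical
  bb0 <- at0[at0$chain == "B" & at0$resid == 3 &
               at0$name %in% c("N", "CA", "C", "CB"), c("x", "y", "z")]
  bb1 <- at1[at1$chain == "B" & at1$resid == 3 &
               at1$name %in% c("N", "CA", "C", "CB"), c("x", "y", "z")]
  expect_equal(unname(as.matrix(bb1)), unname(as.matrix(bb0)))
  # topology consistent: no term references a removed atom
  expect_equal(mut$topology$n_atoms, nrow(at1))
  # glycine refused; absent residue refused
  expect_error(mutate_to_alanine(st, topo, "A", 1L), "glycine")
  expect_error(mutate_to_alanine(st, topo, "B", 99L), "not found")
})

test_that("alanine scan: null control is zero, charged contact dominates", {
  toy <- toy_fixture()
  ens <- make_ensemble(toy, n_frames = 3, seed = 13)
  scan <- alanine_scan(toy$structure, toy$topology,
                       ens$complex$trajectory, "chain A", "chain B",
                       mutations = c("A2A", "K1A", "L3A"),
                       ligand_chain = "B", mode = "single",
                       options = fast_opts())
  expect_equal(nrow(scan), 3L)
  # A -> A rebuild: identical heavy atoms -> essentially zero
  expect_lte(abs(scan$ddg_noS[scan$mutation == "A2A"]), 0.2)
  # K1A removes the only charged interface contact: electrostatics moves
  k1 <- scan[scan$mutation == "K1A", ]
  expect_gt(abs(k1$d_e_ele - attr(scan, "wild_type")$components$mean[
    attr(scan, "wild_type")$components$component == "e_ele"]), 10)
  # direct recomputation oracle for K1A
  mut <- mutate_to_alanine(toy$structure, toy$topology, "B", 1L)
  traj_mut <- new_trajectory(lapply(ens$complex$trajectory$frames,
                                    function(f) f[mut$kept, , drop = FALSE]))
  direct <- binding_estimate_single(mut$structure, mut$topology, traj_mut,
                                    "chain A", "chain B",
                                    options = fast_opts())
  expect_equal(k1$dg_noS,
               direct$components$mean[
                 direct$components$component == "g_noS"],
               tolerance = 1e-10)
  # disjoint mutations are order independent
  scan_rev <- alanine_scan(toy$structure, toy$topology,
                           ens$complex$trajectory, "chain A", "chain B",
                           mutations = c("L3A", "K1A"),
                           ligand_chain = "B", mode = "single",
                           options = fast_opts())
  expect_equal(scan_rev$ddg_noS[scan_rev$mutation == "K1A"],
               scan$ddg_noS[scan$mutation == "K1A"], tolerance = 1e-10)
})

test_that("entropy assembly follows the published bookkeeping", {
  toy <- toy_fixture()
  ens <- make_ensemble(toy, n_frames = 3, seed = 15)
  est <- binding_estimate_single(toy$structure, toy$topology,
                                 ens$complex$trajectory, "chain A",
                                 "chain B", options = fast_opts())
  g_noS <- est$components$mean[est$components$component == "g_noS"]
  # zero entropy -> dg_tot = dg_noS
  expect_equal(assemble_total(est)$dg_tot, g_noS)
  # printed-table arithmetic: -76.1 + 30.9 + 8.5 ~ -36.7 (rounded parts)
  est2 <- est
  est2$components$mean[est2$components$component == "g_noS"] <- -76.1
  tot <- assemble_total(est2, minus_t_ds_rt = 30.9, minus_t_ds_v = 8.5)
  expect_equal(tot$minus_t_ds_tot, 39.4)
  expect_equal(tot$dg_tot, -36.7, tolerance = 0.15)
  # additivity over disjoint entropy parts
  a <- assemble_total(est, minus_t_ds_rt = 10)
  b <- assemble_total(est, minus_t_ds_v = 5)
  ab <- assemble_total(est, minus_t_ds_rt = 10, minus_t_ds_v = 5)
  expect_equal((a$dg_tot - g_noS) + (b$dg_tot - g_noS), ab$dg_tot - g_noS)
  # temperature mismatch errors
  expect_error(assemble_total(est, 1, 1, temperature = 310),
               "temperature mismatch")
})
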