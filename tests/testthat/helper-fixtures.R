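# Shared fixtures, memoized so expensive builds (toy complex, minimized
# reduced region) run once per test session.

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(key, fn) {
  if (!exists(key, envir = .fixture_env))
    assign(key, fn(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

toy_fixture <- function() memo_fixture("toy", function() make_toy_complex())

minimized_fixture <- function() memo_fixture("minimized", function() {
  toy <- toy_fixture()
  rp <- reduced_region(toy$structure, toy$ligand_selection, cutoff = 8)
  mn <- minimize_energy(toy$structure, toy$topology,
                        movable_set = rp$flexible)
  nm <- normal_modes(mn$structure, toy$topology, rp$flexible)
  list(toy = toy, region = rp, minimized = mn, modes = nm)
})

# tiny hand-built parameterized system: n atoms on given coordinates with
# uniform or per-atom parameters, no topology unless supplied
bare_structure <- function(xyz, charge = 0, mass = 12.011,
                           pb_radius = 1.5, rmin_half = 0, epsilon = 0,
                           element = "C") {
  n <- nrow(xyz)
  rep_n <- function(v) if (length(v) == 1L) rep(v, n) else v
  new_structure(data.frame(
    name = paste0("X", seq_len(n)), element = element,
    resname = "XXX", resid = seq_len(n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_n(charge), mass = rep_n(mass),
    pb_radius = rep_n(pb_radius), lj_rmin_half = rep_n(rmin_half),
    lj_epsilon = rep_n(epsilon), stringsAsFactors = FALSE))
}

# a small 3-residue text PDB fixture written on the fly
write_tripeptide_pdb <- function(path) {
  toy <- toy_fixture()
  st <- subset_structure(toy$structure, "chain B")
  write_pdb(st, path)
  path
}

random_rotation <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
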