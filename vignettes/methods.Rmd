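---
title: "Models and numerical choices in flexpbsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in flexpbsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexpbsa)
```

# Scope

`flexpbsa` post-processes conformational ensembles of a multi-domain
receptor ectodomain bound to a peptide ligand. It implements two groups of
methods that are usually run after a molecular-dynamics simulation:

1. **Flexibility and shape descriptors** — rigid-body superposition and
   RMSD series, an interdomain hinge angle defined by two C-alpha anchor
   vectors, the maximum curvature of a quadratic curve through the centres
   of mass of disulfide-bonded sequence modules, the gyration tensor and
   its scalar summaries (radius of gyration, maximum dimension), pair
   distribution functions, principal component analysis, and contact
   persistence.
2. **End-point binding energetics (MM-PBSA)** — per-snapshot free energies
   `G = E_MM + G_PB + G_SA`, averaged over an ensemble and differenced as
   `dG = G(complex) - G(receptor) - G(ligand)`, in single-trajectory mode
   (receptor and ligand extracted from complex frames) and three-trajectory
   mode (independent ensembles per species), plus reorganization free
   energies, computational alanine scanning, autocorrelation-aware standard
   errors, and rotational/translational/vibrational entropy terms.

Running the underlying simulations is out of scope; the package consumes
multi-model PDB files and a plain-text parameter format, and ships seeded
generators that build fully parameterized synthetic systems for testing.

# The interdomain angle

The receptor's first and third subdomains are each spanned by a stable
parallel beta sheet. A vector is drawn between the C-alpha atoms of the
sheet's end residues in each domain (`Val36 -> Glu118` in Subdomain I,
`Ser340 -> Glu431` in Subdomain III by default) and the angle between the
two vectors is `acos(V1.V2 / |V1||V2|)` in `[0, 180]` degrees. Both
vectors run N-terminal to C-terminal anchor; reversing one vector maps an
angle `a` to `180 - a`, so the convention matters and is fixed here. The
angle is invariant under global rigid motion (tested property).

# Subdomain-II curvature

The cysteine-rich second subdomain is a chain of "disulfide modules": the
inclusive residue span closed by one disulfide bridge. Bridges are
detected as SG-SG pairs within 2.5 Angstrom (a cysteine with two partners
inside the cutoff is an error), modules are ordered along the sequence,
and each module's centre of mass is mass-weighted over all atoms of its
member residues.

The module centroids are reduced to 2-D in their least-squares plane
(SVD of the centred points; `u` along the largest in-plane spread, `v`
the second direction) and `v = a u^2 + b u + c` is fitted by least
squares. The curvature `kappa(u) = |2a| / (1 + (2au + b)^2)^{3/2}` is
maximized **within the data's u-range**: it equals `2|a|` when the vertex
lies inside the range, and is otherwise evaluated at the endpoint nearest
the vertex. Two genuinely open choices were resolved as follows:

* *Plane reduction.* A single-parameter quadratic requires a 2-D frame;
  the least-squares plane is the canonical, rotation-invariant choice.
* *Where to take the maximum.* Restricting to the data's extent measures
  the curvature of the physical spine rather than of an extrapolated
  parabola. For the shallow arcs and bent spines of interest the vertex
  falls inside the data range, where both conventions coincide.

The estimator is validated against circular arcs of known curvature (an
independent geometric ground truth, not a parabola): a noiseless shallow
arc of `kappa = 0.25` per Angstrom is recovered within 2%.

# MM energies, surface area, and the nonpolar term

Gas-phase molecular-mechanics energies are computed **without cutoff**:
Coulomb (constant 332.0716 kcal A / mol e^2), 12-6 Lennard-Jones with
arithmetic `rmin/2` and geometric `epsilon` combining, harmonic bonds and
angles in the `k (x - x0)^2` convention, cosine dihedrals
`k (1 + cos(n phi - delta))`, and harmonic impropers. 1-2 and 1-3 pairs
are excluded from the nonbonded sums; 1-4 pairs are flagged and included
at full strength by default (a configurable scale), and this convention is
fixed: 1-4 nonbonded interactions live in `e_ele`/`e_vdw`, never in
`e_int`.

The nonpolar solvation term is `G_SA = gamma A + beta` with
`gamma = 0.00542` kcal/mol/A^2 and `beta = 0.92` kcal/mol. `A` is a
solvent-accessible surface area computed by deterministic Shrake-Rupley
sampling on a golden-spiral point set (960 points per atom by default,
probe 1.4 A). The original protocol used a molecular (contact/re-entrant)
surface from a legacy module; SASA was chosen here because it is
reproducible, cheaply testable against closed forms (isolated sphere;
high-resolution reference sampling), and the term is small relative to the
polar part, while `gamma`/`beta` are kept unchanged.

# The Poisson-Boltzmann solver

The polar solvation term solves the linearized Poisson-Boltzmann equation
`div(eps grad phi) - kappa_bar^2 phi = -4 pi k_e rho` on a cubic grid by a
7-point finite-difference stencil and Jacobi-preconditioned conjugate
gradients (the operator is symmetric positive definite; the iteration is
deterministic).

* **Dielectric boundary**: the van der Waals union of the atomic PB-radius
  spheres, assigned on edge midpoints (`eps_in` inside, `eps_out`
  outside). No re-entrant surface — deterministic, and exact for the
  spherical oracle systems the solver is validated on.
* **Charges** are spread to the eight surrounding nodes with trilinear
  weights (total charge conserved to 1e-10).
* **Salt** enters through `kappa^2 = 8 pi e^2 I N_A / (1000 eps_out k_B
  T)` at nodes outside all radius-plus-Stern spheres (Stern layer 2 A,
  ionic strength 0.1 mol/L by default, matching a physiological NaCl
  bath); the Dirichlet boundary is the Debye-Hueckel screened Coulomb sum
  of all charges.
* **Self-energy cancellation**: `G_PB = 0.5 sum_nodes q_node
  (phi_solvated - phi_reference)`, the reference being a uniform-`eps_in`,
  zero-salt solve on the *identical* grid, so the grid self-energy of the
  point charges cancels. With `eps_out = eps_in` and no salt the result is
  zero to 1e-6 regardless of spacing (tested).
* **Defaults**: interior dielectric 1, exterior 80, padding at least 10 A,
  relative residual 1e-6. All exposed via `pb_options()`.

The Born ion (charge `q`, radius `r`) has the closed form
`-k_e q^2 / (2r) (1/eps_in - 1/eps_out)`; at `h = 0.3` A the solver is
within 3% of the analytic -81.98 kcal/mol for `q = 1, r = 2`, the error
decreases monotonically with spacing over `h = 0.8, 0.4, 0.2`, and the
result moves by under 1% under sub-grid translations. Grid sizes are
bounded (`max_nodes`) and a too-fine spacing errors with advice rather
than exhausting memory; full-protein production grids (tens of millions of
nodes) are intentionally out of scope.

# Binding estimates, reorganization, alanine scanning

**Single vs three trajectories.** In single mode, receptor and ligand
coordinates are extracted from each complex frame; bonded terms then
cancel term-by-term, so `dE_int` is zero *by construction* and the
implementation sets it to exactly zero. In three-trajectory mode each
species is averaged over its own ensemble before differencing, and
`dE_int` is generally nonzero. Feeding the three-trajectory estimator the
complex-extracted component frames must reproduce the single-trajectory
result to 1e-8 on every component — this estimator-equivalence identity is
an acceptance criterion.

**Reorganization free energy** of a species is the mean `G_noS` over the
conformations it adopts in the complex (computed as the isolated species)
minus the mean over its free ensemble: zero for identical ensembles,
antisymmetric under swapping, and equal to a constructed strain energy on
fixtures where the bound ensemble carries a known bond stretch.

**Standard errors.** The per-frame component series are autocorrelated
(correlation times of several ns are typical for these systems), so the
naive `sd/sqrt(N)` underestimates the error. The statistical inefficiency
`g = 1 + 2 sum_k (1 - k/N) rho_k` is estimated with the autocorrelation
sum truncated at the first non-positive term, and `se = sd sqrt(g/N)`.
The estimator is validated against the i.i.d. (`sigma/sqrt(N)`) and AR(1)
(`sigma sqrt((1+rho)/(1-rho))/sqrt(N)`) closed forms within 15%. Means are
frame-order invariant; the error estimate is deliberately order-sensitive
through the autocorrelation.

**Alanine scanning** truncates a residue's side chain beyond C-beta,
retypes the residue to alanine from the parameter table, and re-evaluates
every frame of the wild-type ensembles — conformations are reused, no
re-simulation, which is the method's stated assumption. Glycine (no
C-beta) and proline (backbone ring) are refused. The null mutation
(X -> X rebuild) is the control and must give `|ddG_noS| <= 0.2` kcal/mol;
on the heavy-atom fixtures it is exact because nothing is rebuilt.
Beta-hydrogens would be rebuilt at idealized geometry when the parameter
set defines them; the bundled fixtures are heavy-atom-only.

**Totals.** `-T dS_tot = -T dS_rt - T dS_v` and `dG_tot = dG_noS +
(-T dS_tot)`, with the `-T dS` entries entering as positive additions, as
in the published tables. The classical rigid-body energy `E_rot/tr = 3RT`
(1.79 kcal/mol at 300 K) cancels in relative binding energies and is
excluded by default behind a flag.

# Entropies

Translational entropy is Sackur-Tetrode at a configurable standard
concentration (default 1 mol/L — the solution-binding convention; the gas
1-atm state is available by passing the corresponding concentration).
Rotational entropy is the classical rigid rotor from the principal moments
of inertia; linear rotors are refused rather than silently mishandled.

Vibrational entropy uses a reduced normal-mode system: the flexible region
is the ligand plus every whole receptor residue with any atom within 8 A
of the ligand; a buffer of whole residues within a further 4 A contributes
to the potential but is fixed during minimization and excluded from the
Hessian (this prevents distortions at the truncation boundary and avoids
uncapped-residue artifacts); the remainder is discarded. Residue inclusion
is all-or-none. The buffer width of 4 A is this package's choice — the
method description it follows states only that a fixed buffer exists.

Minimization is L-BFGS-B on the analytic MM gradient, moving only the
flexible atoms, to an RMS gradient of 1e-4 kcal/mol/A. The Hessian over
flexible atoms is built by central finite differences of the analytic
gradient (step 1e-4 A), symmetrized as `(H + H^T)/2`, mass-weighted and
diagonalized; eigenvalues below -1e-6 fail validation as imaginary modes.
The diatomic oscillator closed form is reproduced to 0.1%, which gates the
finite-difference quality. Entropy per mode is the quantum harmonic
oscillator `S = R [x/(e^x - 1) - ln(1 - e^-x)]`, `x = h nu / k_B T`
(a classical variant exists behind a flag); near-zero frequencies are
skipped with a warning.

# The synthetic world

The generators emulate the *statistical structure* the analysis assumes,
not protein realism:

* `make_toy_complex()` builds a 20-residue receptor — a 10-residue domain
  with two engineered adjacent-cysteine disulfide bridges and one charged
  aspartate, a 2-glycine hinge, an 8-residue second domain — plus a
  Lys-Ala-Leu ligand whose lysine forms the only charged interface contact
  (a salt bridge at about 2.9 A). Residues are heavy-atom mini-templates
  (3-5 atoms); every bonded equilibrium value is set to the as-built
  geometry after a small seeded jitter (0.02 A RMS), so the reference
  conformation has zero internal strain and minimization starts from a
  sensible point. The bundled mini force field is self-contained and is
  written/re-read through the production parameter parser on every build.
* `make_hinge_trajectory()` rotates the second domain rigidly about the
  hinge so the anchor angle equals a draw from `N(mean, sd)` *exactly*
  (the rotation is constructed in the plane spanned by the two anchor
  vectors), then adds optional isotropic noise; the target angles are
  returned as a sidecar ground truth.
* `make_module_chain()` places points on a circular arc of prescribed
  curvature — an independent ground truth for the quadratic-fit estimator.
  The default per-segment chord keeps the total turn of the arc at about
  0.3 rad: shallow enough that the parabola-vs-arc bias stays inside the
  2% recovery bound, and the feasibility limit (`chord < 2/kappa`) is
  enforced with an error. A published example pairing `kappa = 0.25` with
  a 10 A chord is geometrically impossible for a circular arc
  (`2/kappa = 8` A) and was treated as illustrative prose, not a contract.
* `make_born_system()` emits the single-ion PB oracle with its analytic
  solvation energy.
* `make_ensemble()` produces complex/receptor/ligand trajectories with
  seeded Gaussian fluctuations and an optional prescribed stretch of the
  ligand's terminal Leu CB-CG bond in the bound ensemble, giving a
  reorganization energy and three-trajectory `dE_int` of known magnitude
  `k dx^2` (the stretched atom is charge-free and its 1-2/1-3 environment
  is excluded, so the bond term dominates).

What a green test does **not** establish: agreement with the published
per-complex energy components for the real receptor. Those require the
original 150-ns trajectories, which do not exist here; the published
values are instead covered by bookkeeping identities (component sums,
estimator equivalence, the total-assembly arithmetic) and by closed-form
oracles for every numerical kernel. The crystal-structure angle and
curvature checks run whenever the deposited PDB entries are present under
`scratch/pdb/`; in an offline environment they report their absence
honestly instead of substituting a tuned stand-in.

# Degenerate inputs and tie-breaks

* Alternate locations: highest occupancy wins, ties to the first listed;
  insertion codes are preserved; residue numbers beyond the 4-column PDB
  capacity error rather than wrap.
* Superposition requires 3+ non-collinear points and always returns a
  proper rotation (reflections are corrected through the SVD determinant).
* Collinear module centroids give `a = 0` and curvature exactly 0; fully
  coincident points are an error.
* A constant energy series has `se = 0` and correlation time 0; a
  one-frame ensemble reports its mean with the standard error absent.
* Zero-radius atoms are excluded from SASA with a warning; zero-charge
  structures short-circuit the PB solve to exactly 0.

# Known limitations

* The dielectric boundary is the vdW union, not a molecular surface;
  absolute `G_PB` for a real protein will differ from solvers using
  re-entrant surfaces, though differences largely cancel in `dG`.
* Nonbonded energies are dense `O(N^2)`; the package targets fixtures and
  single structures, not long production trajectories of large proteins.
* The linear-rotor entropy branch and conformational entropy beyond the
  harmonic approximation are not implemented.
* Single-model crystal structures carry no hydrogens; geometry descriptors
  only need heavy atoms, but energy operations require fully parameterized
  inputs.
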