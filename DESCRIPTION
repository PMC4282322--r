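Package: flexpbsa
Title: Domain Flexibility Descriptors and MM-PBSA Binding Energetics for
    Receptor-Ligand Ensembles
Version: 0.1.0
Authors@R:
    person("flexpbsa", "developers", email = "flexpbsa@example.org",
           role = c("aut", "cre"))
Description: Post-simulation analysis toolkit for multi-domain receptor
    ectodomains and their peptide ligands. Reads single- and multi-model PDB
    files together with a plain-text force-field parameter format, and
    provides flexibility and shape descriptors (rigid-body superposition and
    RMSD series, interdomain hinge angles from C-alpha anchor vectors,
    maximum curvature of the quadratic fit through disulfide-module
    centroids, gyration tensor, radius of gyration, maximum dimension, pair
    distribution functions, principal component analysis, contact
    persistence), gas-phase molecular-mechanics energies without cutoffs, a
    deterministic solvent-accessible surface area, a finite-difference
    linearized Poisson-Boltzmann solver, MM-PBSA binding free energy
    estimates in single- and three-trajectory modes with
    autocorrelation-aware standard errors, reorganization free energies,
    computational alanine scanning, and rotational/translational plus
    reduced-region normal-mode vibrational entropies. Seeded synthetic-data
    generators supply fully parameterized toy complexes, hinge ensembles,
    curved module chains and Born ions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
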