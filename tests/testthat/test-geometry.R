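test_that("superposition recovers constructed rigid transforms", {
  set.seed(21)
  A <- matrix(rnorm(15, sd = 3), 5, 3)
  # identical sets
  sp <- superpose(A, A)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)
  # known proper rotation + translation is inverted exactly
  R <- random_rotation(3)
  B <- sweep(A %*% t(R), 2, c(1, -2, 5), `+`)
  sp <- superpose(B, A)
  expect_equal(sp$rmsd, 0, tolerance = 1e-8)
  expect_equal(sp$transform(B), A, tolerance = 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
  # errors
  expect_error(superpose(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:4, 0, 0)
  expect_error(superpose(line, line + 1), "collinear|degenerate")
})

test_that("superposition matches a hierarchical rotation-grid search", {
  set.seed(22)
  A <- matrix(rnorm(15, sd = 2), 5, 3)
  B <- matrix(rnorm(15, sd = 2), 5, 3)
  fit <- superpose(A, B)

  # oracle: centred coordinates, exhaustive Euler-angle grid refined twice
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  rot <- function(a, b, c) {
    Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
    Rz(a) %*% Ry(b) %*% Rz(c)
  }
  obj <- function(p) sqrt(mean(rowSums(
    (Ac %*% t(rot(p[1], p[2], p[3])) - Bc)^2)))
  best <- c(0, 0, 0); bval <- obj(best)
  step <- pi / 12
  grid1 <- as.matrix(expand.grid(a = seq(-pi, pi, by = step),
                                 b = seq(0, pi, by = step),
                                 c = seq(-pi, pi, by = step)))
  vals <- apply(grid1, 1, obj)
  best <- grid1[which.min(vals), ]; bval <- min(vals)
  for (step in c(pi / 60, pi / 360, pi / 3600)) {
    loc <- as.matrix(expand.grid(a = best[1] + step * (-6:6),
                                 b = best[2] + step * (-6:6),
                                 c = best[3] + step * (-6:6)))
    vals <- apply(loc, 1, obj)
    best <- loc[which.min(vals), ]; bval <- min(vals)
  }
  expect_equal(fit$rmsd, bval, tolerance = 1e-3)
  expect_lte(fit$rmsd, bval + 1e-6)  # Kabsch is the true minimum
})

test_that("rmsd_series removes fitted motion and reports the rest", {
  toy <- toy_fixture()
  st <- toy$structure
  ref <- coords(st)
  # copies of the reference -> all zeros; rigid translations -> zeros
  frames <- list(ref, ref + 3, sweep(ref %*% t(random_rotation(5)), 2,
                                     c(1, 2, 3), `+`))
  tr <- new_trajectory(frames)
  out <- rmsd_series(tr, st, "name CA and chain A")
  expect_equal(out, rep(0, 3), tolerance = 1e-8)

  # hinge fixture: fit on domain 1, measure domain 2; matches the direct
  # per-frame computation
  hinge <- make_hinge_trajectory(toy, 130, 8, n_frames = 5, seed = 9)
  fit_sel <- sprintf("chain A and resid %d:%d and name CA",
                     toy$domain1[1], toy$domain1[2])
  ms_sel <- sprintf("chain A and resid %d:%d and name CA",
                    toy$domain2[1], toy$domain2[2])
  out <- rmsd_series(hinge$trajectory, st, fit_sel, ms_sel)
  fit_idx <- select_atoms(st, fit_sel)
  ms_idx <- select_atoms(st, ms_sel)
  direct <- vapply(hinge$trajectory$frames, function(fr) {
    sp <- superpose(fr[fit_idx, ], ref[fit_idx, ])
    sqrt(mean(rowSums((sp$transform(fr[ms_idx, ]) - ref[ms_idx, ])^2)))
  }, numeric(1))
  expect_equal(out, direct, tolerance = 1e-10)
  expect_error(rmsd_series(tr, st, "chain Q"), "empty")
})

test_that("interdomain angle follows the anchor-vector contract", {
  # explicit parallel / antiparallel constructions
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0),    # V1 anchors
               c(0, 5, 0), c(1, 5, 0))    # V2 anchors (parallel)
  st <- bare_structure(xyz)
  st$atoms$name <- "CA"
  st$atoms$resid <- c(1L, 2L, 3L, 4L)
  anc <- anchor_pair(chain = "A", v1_from = 1, v1_to = 2,
                     v2_from = 3, v2_to = 4)
  expect_equal(interdomain_angle(st, anc), 0, tolerance = 1e-10)
  anc_rev <- anchor_pair(chain = "A", v1_from = 1, v1_to = 2,
                         v2_from = 4, v2_to = 3)
  expect_equal(interdomain_angle(st, anc_rev), 180, tolerance = 1e-10)

  # hinge fixture built at 120 measures 120 to 1e-6
  toy <- toy_fixture()
  h <- make_hinge_trajectory(toy, 120, 0, n_frames = 2)
  a <- angle_series(h$trajectory, toy$structure, toy$anchors)$angles
  expect_equal(a, c(120, 120), tolerance = 1e-6)

  # invariance under global rotation/translation
  st2 <- toy$structure
  x <- coords(st2)
  st2 <- set_coords(st2, sweep(x %*% t(random_rotation(8)), 2,
                               c(10, -4, 2), `+`))
  expect_equal(interdomain_angle(st2, toy$anchors),
               interdomain_angle(toy$structure, toy$anchors),
               tolerance = 1e-8)

  # unresolvable anchor
  bad <- anchor_pair(chain = "Z")
  expect_error(interdomain_angle(toy$structure, bad), "not resolvable")
})

test_that("angle_series histogram accounts for every frame", {
  toy <- toy_fixture()
  h <- make_hinge_trajectory(toy, 95, 0, n_frames = 7)
  out <- angle_series(h$trajectory, toy$structure, toy$anchors)
  expect_equal(sum(out$histogram$count), 7)
  expect_equal(sum(out$histogram$count > 0), 1L)  # delta-like, one bin
  h2 <- make_hinge_trajectory(toy, 110, 5, n_frames = 300, seed = 4)
  out2 <- angle_series(h2$trajectory, toy$structure, toy$anchors,
                       bin_width = 2)
  expect_equal(sum(out2$histogram$count), 300)
})

test_that("disulfide module detection orders and spans correctly", {
  toy <- toy_fixture()
  mods <- find_disulfide_modules(toy$structure, domain_range = c(1, 10))
  expect_equal(nrow(mods), 2L)
  expect_equal(mods$first_res, c(2L, 6L))
  expect_equal(mods$last_res, c(3L, 7L))
  # COM is the mass-weighted mean over the member residues' atoms
  at <- toy$structure$atoms
  mem <- which(at$chain == "A" & at$resid >= 2 & at$resid <= 3)
  com <- colSums(coords(toy$structure)[mem, ] * at$mass[mem]) /
    sum(at$mass[mem])
  expect_equal(unlist(mods[1, c("com_x", "com_y", "com_z")]), com,
               tolerance = 1e-10, ignore_attr = TRUE)

  # no cysteines -> empty
  none <- find_disulfide_modules(toy$structure, domain_range = c(13, 20))
  expect_equal(nrow(none), 0L)

  # ambiguous partner (three mutually close SG atoms) errors
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1, 0))
  st <- bare_structure(xyz, element = "S")
  st$atoms$name <- "SG"; st$atoms$resname <- "CYS"
  expect_error(find_disulfide_modules(st, c(1, 3)), "two bridge partners")
})

test_that("quadratic curve fit and maximum curvature are exact on parabolas", {
  # collinear -> a = 0 -> curvature 0
  line <- cbind(seq(-5, 5, length.out = 7), 0, 0)
  fit0 <- fit_quadratic_curve(line)
  expect_equal(fit0$a, 0, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(max_curvature(fit0), 0)

  # 7 points on v = 0.125 u^2, rotated arbitrarily: a recovered to 1e-9,
  # vertex inside range -> kappa_max = 2|a| = 0.25
  u <- seq(-10, 10, length.out = 7)
  pts <- cbind(u, 0.125 * u^2, 0)
  pts_rot <- sweep(pts %*% t(random_rotation(13)), 2, c(3, -7, 1), `+`)
  fit <- fit_quadratic_curve(pts_rot)
  expect_equal(abs(fit$a), 0.125, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit$residual, 0, tolerance = 1e-8)
  expect_equal(max_curvature(fit), 0.25, tolerance = 1e-9)

  # off-centre parabola segment: the reported maximum equals a dense-grid
  # search of kappa(u) over the data's u-range (vertex handling included)
  u2 <- seq(5, 12, length.out = 7)
  fit2 <- fit_quadratic_curve(cbind(u2, 0.125 * u2^2, 0))
  a <- fit2$a; b <- fit2$b
  kappa <- function(u) abs(2 * a) / (1 + (2 * a * u + b)^2)^1.5
  grid_max <- max(kappa(seq(fit2$u_range[1], fit2$u_range[2],
                            length.out = 20000)))
  expect_equal(max_curvature(fit2), grid_max, tolerance = 1e-6)
  expect_lt(max_curvature(fit2), 0.25)

  expect_error(fit_quadratic_curve(matrix(1, 5, 3)), "coincident")
  expect_error(fit_quadratic_curve(pts[1:2, ]), "at least 3")
})

test_that("max_curvature is rigid-motion invariant and scales as 1/s", {
  mc <- make_module_chain(0.2, seed = 31)
  k1 <- max_curvature(fit_quadratic_curve(mc$points))
  moved <- sweep(mc$points %*% t(random_rotation(17)), 2, c(5, 5, 5), `+`)
  expect_equal(max_curvature(fit_quadratic_curve(moved)), k1,
               tolerance = 1e-9)
  for (s in c(0.5, 2, 4))
    expect_equal(max_curvature(fit_quadratic_curve(mc$points * s)),
                 k1 / s, tolerance = 1e-9)
})

test_that("gyration descriptors match closed forms and the covariance oracle", {
  # single atom
  one <- bare_structure(rbind(c(1, 2, 3)))
  g1 <- gyration_descriptors(one)
  expect_equal(g1$eigenvalues, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(g1$rg, 0)
  expect_equal(g1$dmax, 0)

  # two unit masses 10 A apart
  two <- bare_structure(rbind(c(0, 0, 0), c(10, 0, 0)), mass = 1)
  g2 <- gyration_descriptors(two)
  expect_equal(g2$eigenvalues, c(25, 0, 0), tolerance = 1e-10)
  expect_equal(g2$rg, 5, tolerance = 1e-10)
  expect_equal(g2$dmax, 10)

  # mass-weighted oracle via explicit covariance on the toy receptor
  toy <- toy_fixture()
  g <- gyration_descriptors(toy$structure, "chain A")
  idx <- select_atoms(toy$structure, "chain A")
  X <- coords(toy$structure)[idx, ]
  w <- toy$structure$atoms$mass[idx]; w <- w / sum(w)
  ctr <- colSums(X * w)
  S <- t(sweep(X, 2, ctr) * w) %*% sweep(X, 2, ctr)
  expect_equal(sort(g$eigenvalues), sort(eigen(S)$values),
               tolerance = 1e-10)
  # rg^2 = sum of eigenvalues, for any selection
  for (sel in list("chain A", "name CA", "element S"))
    with(gyration_descriptors(toy$structure, sel),
         expect_equal(rg^2, sum(eigenvalues), tolerance = 1e-10))
  expect_error(gyration_descriptors(toy$structure, "chain Q"), "empty")
})

test_that("pair distribution is a complete pairwise histogram", {
  two <- bare_structure(rbind(c(0, 0, 0), c(5.2, 0, 0)))
  pd <- pair_distribution(two, bin_width = 1)
  expect_equal(sum(pd$weight), 1)
  expect_equal(pd$bin_center[pd$weight > 0], 5.5)  # bin [5,6)

  # equilateral triangle side 4.3 -> weight 3 in the bin containing 4.3
  s <- 4.3
  tri <- bare_structure(rbind(c(0, 0, 0), c(s, 0, 0),
                              c(s / 2, s * sqrt(3) / 2, 0)))
  pd3 <- pair_distribution(tri, bin_width = 1)
  expect_equal(pd3$weight[pd3$bin_center == 4.5], 3)

  # raw total N(N-1)/2 for every frame of a trajectory
  toy <- toy_fixture()
  n <- length(select_atoms(toy$structure, "chain A"))
  frames <- list(coords(toy$structure), coords(toy$structure) * 1.1)
  pdt <- pair_distribution(toy$structure, "chain A", frames = frames)
  expect_equal(sum(pdt$weight), n * (n - 1) / 2)
  # unit-area normalization
  pdd <- pair_distribution(toy$structure, "chain A", frames = frames,
                           normalize = "density")
  expect_equal(sum(pdd$weight) * 1, 1, tolerance = 1e-12)
  expect_error(pair_distribution(two, bin_width = 0), "positive")
  expect_error(pair_distribution(one <- bare_structure(rbind(c(0, 0, 0)))),
               "2 selected")
})

test_that("PCA recovers planted orthogonal modes and keeps its invariants", {
  set.seed(41)
  base <- matrix(rnorm(18, sd = 3), 6, 3)
  st <- bare_structure(base, mass = 12)
  n3 <- 18
  # rigid-body basis (3 translations + 3 infinitesimal rotations)
  ctr <- colMeans(base)
  rig <- matrix(0, n3, 6)
  for (d in 1:3) rig[seq(d, n3, by = 3), d] <- 1
  ax <- diag(3)
  for (d in 1:3) {
    w <- t(apply(sweep(base, 2, ctr), 1, function(r)
      c(ax[d, 2] * r[3] - ax[d, 3] * r[2],
        ax[d, 3] * r[1] - ax[d, 1] * r[3],
        ax[d, 1] * r[2] - ax[d, 2] * r[1])))
    rig[, 3 + d] <- as.numeric(t(w))
  }
  rig <- qr.Q(qr(rig))
  ortho <- function(v) {
    v <- v - rig %*% (t(rig) %*% v)
    v / sqrt(sum(v^2))
  }
  u1 <- ortho(rnorm(n3))
  v2 <- rnorm(n3)
  u2 <- ortho(v2 - u1 * sum(u1 * v2))

  amp1 <- rnorm(500, sd = 2); amp2 <- rnorm(500, sd = 1)
  frames <- lapply(1:500, function(f)
    base + matrix(u1 * amp1[f] + u2 * amp2[f], ncol = 3, byrow = TRUE))
  pca <- pca_trajectory(new_trajectory(frames), st, "all")

  # orthonormal modes, non-increasing variances, variance sum = trace
  M <- pca$modes
  expect_lt(max(abs(t(M) %*% M - diag(ncol(M)))), 1e-10)
  expect_true(all(diff(pca$variances) <= 1e-10))
  # recovered variance ratio within 10% of 4:1
  expect_equal(pca$variances[1] / pca$variances[2], 4, tolerance = 0.1)
  # first two modes span the planted subspace
  ov <- mode_overlap(M[, 1:2], cbind(u1, u2), k = 2)
  expect_gt(max(ov[1, ]), 0.95)
  expect_gt(max(ov[2, ]), 0.95)
  # overlap with itself is the identity
  expect_equal(mode_overlap(pca, pca, k = 3), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # projections reproduce per-frame displacements along mode 1
  pr <- project_trajectory(new_trajectory(frames), st, pca, k = 2)
  expect_equal(dim(pr), c(500L, 2L))
  expect_gt(abs(cor(pr[, 1], amp1)), 0.99)
  expect_error(pca_trajectory(new_trajectory(frames[1]), st, "all"),
               "at least 2")
})

test_that("contact_fraction counts frames inside the cutoff", {
  st <- bare_structure(rbind(c(0, 0, 0), c(3, 0, 0)))
  near <- new_trajectory(lapply(1:10, function(i)
    rbind(c(0, 0, 0), c(3, 0, 0))))
  expect_equal(contact_fraction(near, st, "resid 1", "resid 2", 4), 1)
  far <- new_trajectory(lapply(1:10, function(i)
    rbind(c(0, 0, 0), c(5, 0, 0))))
  expect_equal(contact_fraction(far, st, "resid 1", "resid 2", 4), 0)
  # 9 of 10 frames inside
  mix <- new_trajectory(c(near$frames[1:9], far$frames[1]))
  expect_equal(contact_fraction(mix, st, "resid 1", "resid 2", 4), 0.9)
  expect_error(contact_fraction(near, st, "all", "resid 2", 4),
               "exactly one")
})
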