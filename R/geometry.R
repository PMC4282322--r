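## Flexibility and shape descriptors: Kabsch superposition, RMSD series,
## interdomain hinge angles, disulfide-module curvature, gyration tensor,
## pair distribution functions, PCA, contact persistence.

#' Default subdomain map of the hEGFR ectodomain
#'
#' Inclusive residue ranges of the four extracellular subdomains in mature
#' numbering. Override for other receptors or deviant depositions.
#' @return named list of length-2 integer vectors.
#' @export
default_domain_map <- function() {
  list(I = c(1L, 165L), II = c(166L, 310L),
       III = c(311L, 480L), IV = c(481L, 614L))
}

#' Rigid-body least-squares superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the (weighted) RMSD
#' of `mobile` onto `reference`.
#'
#' @param mobile n x 3 coordinate matrix.
#' @param reference n x 3 coordinate matrix.
#' @param weights optional non-negative weights (e.g. masses).
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3,
#'   applied after rotation), `rmsd` (Angstrom) and `transform(x)` applying
#'   the fit to any n x 3 matrix.
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L)
    stop("point sets must be equal-size n x 3 matrices")
  if (nrow(mobile) < 3L) stop("superposition needs at least 3 points")
  w <- if (is.null(weights)) rep(1, nrow(mobile)) else as.numeric(weights)
  if (any(w < 0) || sum(w) <= 0) stop("invalid weights")
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- t(A * w) %*% B
  sv <- svd(H)
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2)
    stop("degenerate (collinear) point configuration")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - B)^2)))
  trans <- cr - as.numeric(R %*% cm)
  list(rotation = R, translation = trans, rmsd = rmsd,
       transform = function(x) sweep(as.matrix(x) %*% t(R), 2, trans, `+`))
}

#' Plain RMSD between two coordinate sets (no fitting)
#' @param a,b n x 3 matrices
#' @return RMSD in Angstrom
#' @export
rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' Per-frame RMSD series with separate fit and measure selections
#'
#' Each frame is superposed onto the reference using `fit_selection`; the
#' RMSD is then reported over `measure_selection`.
#'
#' @param trajectory a Trajectory.
#' @param reference a Structure (defines both selections' atoms).
#' @param fit_selection,measure_selection selection expressions or index
#'   vectors resolved against `reference`.
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(trajectory, reference, fit_selection,
                        measure_selection = fit_selection) {
  fit_idx <- select_atoms(reference, fit_selection)
  ms_idx <- select_atoms(reference, measure_selection)
  if (length(fit_idx) == 0L || length(ms_idx) == 0L)
    stop("empty selection in rmsd_series")
  ref <- coords(reference)
  vapply(trajectory$frames, function(fr) {
    sp <- superpose(fr[fit_idx, , drop = FALSE],
                    ref[fit_idx, , drop = FALSE])
    rmsd(sp$transform(fr[ms_idx, , drop = FALSE]),
         ref[ms_idx, , drop = FALSE])
  }, numeric(1))
}

## ---- interdomain angle ----------------------------------------------------

#' Anchor pair for interdomain angle vectors
#'
#' Each vector runs from the first-listed to the second-listed anchor atom.
#' Defaults are the C-alpha anchors of the receptor's Subdomain I
#' (Val36 -> Glu118) and Subdomain III (Ser340 -> Glu431), the ends of a
#' stable parallel beta sheet in each domain.
#'
#' @param chain chain label of all four anchors.
#' @param v1_from,v1_to,v2_from,v2_to residue numbers of the anchors.
#' @param atom anchor atom name (default CA).
#' @return object of class `AnchorPair`.
#' @export
anchor_pair <- function(chain = "A", v1_from = 36L, v1_to = 118L,
                        v2_from = 340L, v2_to = 431L, atom = "CA") {
  structure(list(chain = chain, atom = atom,
                 v1 = c(v1_from, v1_to), v2 = c(v2_from, v2_to)),
            class = "AnchorPair")
}

anchor_coords <- function(structure, anchors, xyz = NULL) {
  at <- structure$atoms
  if (is.null(xyz)) xyz <- coords(structure)
  find <- function(resid) {
    i <- which(at$chain == anchors$chain & at$resid == resid &
                 toupper(at$name) == toupper(anchors$atom))
    if (length(i) != 1L)
      stop("anchor atom not resolvable: ", anchors$chain, ":", resid, ":",
           anchors$atom, " (", length(i), " matches)")
    xyz[i, ]
  }
  list(v1 = find(anchors$v1[2]) - find(anchors$v1[1]),
       v2 = find(anchors$v2[2]) - find(anchors$v2[1]))
}

angle_between <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9) stop("zero-length anchor vector")
  ct <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Interdomain angle from two anchor vectors
#'
#' Angle (degrees, in [0, 180]) between the vectors V1 and V2 defined by an
#' AnchorPair; V1 and V2 run N-terminal to C-terminal anchor.
#'
#' @param structure a Structure.
#' @param anchors an AnchorPair (default: [anchor_pair()]).
#' @return angle in degrees.
#' @export
interdomain_angle <- function(structure, anchors = anchor_pair()) {
  v <- anchor_coords(structure, anchors)
  angle_between(v$v1, v$v2)
}

#' Per-frame interdomain angle series with histogram
#'
#' @param trajectory a Trajectory.
#' @param structure parent Structure (atom identities).
#' @param anchors an AnchorPair.
#' @param bin_width histogram bin width in degrees (default 1).
#' @return list with `angles` (degrees per frame) and `histogram`
#'   (data.frame bin_center, count; counts sum to the frame count).
#' @export
angle_series <- function(trajectory, structure, anchors = anchor_pair(),
                         bin_width = 1) {
  ang <- vapply(trajectory$frames, function(fr) {
    v <- anchor_coords(structure, anchors, xyz = fr)
    angle_between(v$v1, v$v2)
  }, numeric(1))
  edges <- seq(0, 180 + bin_width, by = bin_width)
  cnt <- as.numeric(table(cut(ang, breaks = edges, right = FALSE)))
  list(angles = ang,
       histogram = data.frame(bin_center = edges[-length(edges)] +
                                bin_width / 2, count = cnt))
}

## ---- disulfide modules and curvature --------------------------------------

#' Find disulfide modules within a residue range
#'
#' A module is the inclusive residue span closed by one disulfide bridge:
#' SG atoms of two cysteines within `sg_cutoff`, both inside `domain_range`.
#' Modules are ordered along the sequence by their first cysteine; the
#' centre of mass is mass-weighted over all atoms of the member residues
#' (unit masses where masses are unassigned).
#'
#' @param structure a Structure.
#' @param domain_range length-2 inclusive residue range (default: the
#'   Subdomain II range of [default_domain_map()]).
#' @param sg_cutoff SG-SG bridge cutoff in Angstrom (default 2.5).
#' @param chain optional chain restriction.
#' @return data.frame with columns cys1, cys2, first_res, last_res,
#'   com_x, com_y, com_z; zero rows when no bridges exist.
#' @export
find_disulfide_modules <- function(structure,
                                   domain_range = default_domain_map()$II,
                                   sg_cutoff = 2.5, chain = NULL) {
  at <- structure$atoms
  sel <- toupper(at$name) == "SG" &
    at$resid >= domain_range[1] & at$resid <= domain_range[2]
  if (!is.null(chain)) sel <- sel & at$chain %in% chain
  sg <- which(sel)
  out <- data.frame(cys1 = integer(0), cys2 = integer(0),
                    first_res = integer(0), last_res = integer(0),
                    com_x = numeric(0), com_y = numeric(0),
                    com_z = numeric(0))
  if (length(sg) < 2L) return(out)
  xyz <- coords(structure)[sg, , drop = FALSE]
  dm <- as.matrix(dist(xyz))
  partner <- rep(NA_integer_, length(sg))
  for (a in seq_along(sg)) {
    hits <- which(dm[a, ] < sg_cutoff & seq_along(sg) != a)
    if (length(hits) > 1L)
      stop("cysteine ", at$resid[sg[a]], " matched to two bridge partners")
    if (length(hits) == 1L) partner[a] <- hits
  }
  pairs <- which(!is.na(partner) & seq_along(sg) < partner)
  if (length(pairs) == 0L) return(out)
  rows <- lapply(pairs, function(a) {
    b <- partner[a]
    r1 <- at$resid[sg[a]]; r2 <- at$resid[sg[b]]
    lo <- min(r1, r2); hi <- max(r1, r2)
    mem <- which(at$resid >= lo & at$resid <= hi &
                   (if (!is.null(chain)) at$chain %in% chain
                    else at$chain == at$chain[sg[a]]))
    m <- at$mass[mem]
    if (anyNA(m)) m <- rep(1, length(mem))
    com <- colSums(coords(structure)[mem, , drop = FALSE] * m) / sum(m)
    data.frame(cys1 = lo, cys2 = hi, first_res = lo, last_res = hi,
               com_x = com[1], com_y = com[2], com_z = com[3])
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$cys1), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Quadratic curve fit through 3-D points
#'
#' Reduces the points to 2-D in their least-squares plane (centroid origin;
#' u along the direction of largest in-plane spread, v the second in-plane
#' direction) and least-squares fits v = a u^2 + b u + c.
#'
#' @param points m x 3 matrix, m >= 3.
#' @return object of class `CurveFit`: origin, `u`, `v` (orthonormal
#'   in-plane basis), coefficients `a` (1/A), `b`, `c` (A), `u_range`,
#'   `residual` (RMS fit residual, A).
#' @export
fit_quadratic_curve <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points for a quadratic fit")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  if (max(abs(X)) < 1e-9) stop("coincident points")
  sv <- svd(X)
  u_ax <- sv$v[, 1]; v_ax <- sv$v[, 2]
  u <- as.numeric(X %*% u_ax); v <- as.numeric(X %*% v_ax)
  fit <- stats::lm.fit(cbind(u^2, u, 1), v)
  cf <- unname(fit$coefficients)
  structure(list(origin = ctr, u = u_ax, v = v_ax,
                 a = cf[1], b = cf[2], c = cf[3],
                 u_range = range(u), u_data = u, v_data = v,
                 residual = sqrt(mean(fit$residuals^2))),
            class = "CurveFit")
}

#' Maximum curvature of a quadratic curve fit
#'
#' kappa(u) = |2a| / (1 + (2 a u + b)^2)^{3/2}, maximized over the data's
#' u range; equals 2|a| when the parabola vertex lies inside the range,
#' otherwise the value at the endpoint nearest the vertex.
#'
#' @param curve_fit a CurveFit.
#' @return maximum curvature in 1/Angstrom.
#' @export
max_curvature <- function(curve_fit) {
  a <- curve_fit$a; b <- curve_fit$b
  if (abs(a) < .Machine$double.eps) return(0)
  kappa <- function(u) abs(2 * a) / (1 + (2 * a * u + b)^2)^1.5
  vertex <- -b / (2 * a)
  r <- curve_fit$u_range
  if (vertex >= r[1] && vertex <= r[2]) return(abs(2 * a))
  max(kappa(r[1]), kappa(r[2]))
}

#' Subdomain curvature in one call
#'
#' Convenience wrapper: detect disulfide modules, fit the quadratic through
#' their centres of mass, report the maximum curvature.
#'
#' @inheritParams find_disulfide_modules
#' @return list with `modules`, `fit`, `max_curvature`.
#' @export
subdomain_curvature <- function(structure,
                                domain_range = default_domain_map()$II,
                                sg_cutoff = 2.5, chain = NULL) {
  mods <- find_disulfide_modules(structure, domain_range, sg_cutoff, chain)
  if (nrow(mods) < 3L)
    stop("fewer than 3 disulfide modules found (", nrow(mods), ")")
  fit <- fit_quadratic_curve(as.matrix(mods[, c("com_x", "com_y", "com_z")]))
  list(modules = mods, fit = fit, max_curvature = max_curvature(fit))
}

## ---- gyration tensor, P(r) ------------------------------------------------

#' Gyration tensor descriptors
#'
#' Second-moment (gyration) tensor about the mass-weighted centroid of a
#' selection; eigenvalues are sorted descending and sum to Rg^2.
#'
#' @param structure a Structure.
#' @param selection selection expression or indices (default all atoms).
#' @param xyz optional coordinate matrix overriding the structure's (a
#'   trajectory frame).
#' @param mass_weighted use atomic masses as weights (default TRUE; atoms
#'   with unassigned mass fall back to unit weights).
#' @return list with `eigenvalues` (A^2, descending), `eigenvectors`
#'   (columns), `rg` (A), `dmax` (A, maximum pairwise atom distance).
#' @export
gyration_descriptors <- function(structure, selection = "all", xyz = NULL,
                                 mass_weighted = TRUE) {
  idx <- select_atoms(structure, selection)
  if (length(idx) == 0L) stop("empty selection")
  X <- if (is.null(xyz)) coords(structure) else as.matrix(xyz)
  X <- X[idx, , drop = FALSE]
  w <- if (mass_weighted) structure$atoms$mass[idx] else rep(1, length(idx))
  if (anyNA(w)) w <- rep(1, length(idx))
  w <- w / sum(w)
  ctr <- colSums(X * w)
  Y <- sweep(X, 2, ctr)
  S <- t(Y * w) %*% Y
  ev <- eigen(S, symmetric = TRUE)
  dmax <- if (length(idx) > 1L) max(dist(X)) else 0
  list(eigenvalues = ev$values, eigenvectors = ev$vectors,
       rg = sqrt(sum(ev$values)), dmax = dmax)
}

#' Pair distribution function P(r)
#'
#' Histogram of all intramolecular pairwise distances of a selection. With
#' multiple frames the per-frame histograms are averaged. In raw mode the
#' per-frame total equals N(N-1)/2.
#'
#' @param structure a Structure.
#' @param selection selection expression or indices.
#' @param frames optional list of coordinate matrices (defaults to the
#'   structure's own coordinates as a single frame).
#' @param bin_width bin width in Angstrom (default 1).
#' @param normalize "counts" (raw) or "density" (unit area).
#' @return data.frame with bin_center and weight.
#' @export
pair_distribution <- function(structure, selection = "all", frames = NULL,
                              bin_width = 1, normalize = c("counts",
                                                           "density")) {
  normalize <- match.arg(normalize)
  if (bin_width <= 0) stop("bin width must be positive")
  idx <- select_atoms(structure, selection)
  if (length(idx) < 2L) stop("need at least 2 selected atoms")
  if (is.null(frames)) frames <- list(coords(structure))
  dmax_all <- 0
  dists <- lapply(frames, function(fr) {
    d <- as.numeric(dist(as.matrix(fr)[idx, , drop = FALSE]))
    dmax_all <<- max(dmax_all, max(d))
    d
  })
  edges <- seq(0, (floor(dmax_all / bin_width) + 1) * bin_width,
               by = bin_width)
  counts <- rowMeans(sapply(dists, function(d)
    as.numeric(table(cut(d, breaks = edges, right = FALSE)))))
  out <- data.frame(bin_center = edges[-length(edges)] + bin_width / 2,
                    weight = counts)
  if (normalize == "density")
    out$weight <- out$weight / (sum(out$weight) * bin_width)
  out
}

## ---- PCA ------------------------------------------------------------------

#' Principal component analysis of a trajectory
#'
#' Frames are least-squares superposed onto the trajectory mean (iterated
#' once: fit to frame 1, average, re-fit to the average) over `selection`
#' before the 3N x 3N covariance is diagonalized.
#'
#' @param trajectory a Trajectory.
#' @param structure parent Structure.
#' @param selection selection expression or indices.
#' @return object of class `PCAResult`: `mean` (n x 3), `modes`
#'   (3N x 3N orthonormal columns), `variances` (A^2, non-increasing),
#'   `projections` (frames x modes, A).
#' @export
pca_trajectory <- function(trajectory, structure, selection = "all") {
  idx <- select_atoms(structure, selection)
  if (length(idx) == 0L) stop("empty selection")
  if (n_frames(trajectory) < 2L) stop("PCA needs at least 2 frames")
  frames <- lapply(trajectory$frames, function(fr)
    fr[idx, , drop = FALSE])
  ref <- frames[[1]]
  fit_all <- function(ref) lapply(frames, function(fr)
    superpose(fr, ref)$transform(fr))
  fitted <- fit_all(ref)
  mn <- Reduce(`+`, fitted) / length(fitted)
  fitted <- fit_all(mn)
  mn <- Reduce(`+`, fitted) / length(fitted)
  M <- do.call(rbind, lapply(fitted, function(f) as.numeric(t(f))))
  M <- sweep(M, 2, as.numeric(t(mn)))
  cv <- crossprod(M) / (nrow(M) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  proj <- M %*% ev$vectors
  structure(list(mean = mn, modes = ev$vectors,
                 variances = pmax(ev$values, 0), projections = proj,
                 selection_idx = idx),
            class = "PCAResult")
}

#' Mode overlap matrix
#'
#' Absolute scalar products between the first `k` modes of two PCA results
#' (or raw mode matrices); entries lie in [0, 1].
#'
#' @param modes_a,modes_b PCAResult objects or matrices with modes in
#'   columns.
#' @param k number of leading modes to compare.
#' @return k x k matrix of |dot products|.
#' @export
mode_overlap <- function(modes_a, modes_b, k = 5L) {
  ma <- if (inherits(modes_a, "PCAResult")) modes_a$modes else modes_a
  mb <- if (inherits(modes_b, "PCAResult")) modes_b$modes else modes_b
  k <- min(k, ncol(ma), ncol(mb))
  abs(t(ma[, seq_len(k), drop = FALSE]) %*% mb[, seq_len(k), drop = FALSE])
}

#' Project a trajectory onto PCA modes
#'
#' @param trajectory a Trajectory.
#' @param structure parent Structure.
#' @param pca a PCAResult (its selection and mean are reused).
#' @param k number of modes.
#' @return frames x k matrix of projections (Angstrom).
#' @export
project_trajectory <- function(trajectory, structure, pca, k = 2L) {
  idx <- pca$selection_idx
  mn <- pca$mean
  out <- t(vapply(trajectory$frames, function(fr) {
    f <- fr[idx, , drop = FALSE]
    f <- superpose(f, mn)$transform(f)
    as.numeric(t(f) - t(mn)) %*% pca$modes[, seq_len(k), drop = FALSE]
  }, numeric(k)))
  if (k == 1L) out <- matrix(out, ncol = 1L)
  out
}

#' Fraction of frames with an atom pair inside a distance cutoff
#'
#' Used for salt-bridge persistence (e.g. the fraction of simulation time a
#' CD-NZ distance stays below 4 Angstrom).
#'
#' @param trajectory a Trajectory.
#' @param structure parent Structure.
#' @param atom_a,atom_b selection expressions resolving to one atom each.
#' @param cutoff distance cutoff in Angstrom.
#' @return fraction in [0, 1].
#' @export
contact_fraction <- function(trajectory, structure, atom_a, atom_b,
                             cutoff) {
  ia <- select_atoms(structure, atom_a)
  ib <- select_atoms(structure, atom_b)
  if (length(ia) != 1L || length(ib) != 1L)
    stop("atom selections must resolve to exactly one atom each")
  if (n_frames(trajectory) == 0L) stop("empty trajectory")
  d <- vapply(trajectory$frames, function(fr)
    sqrt(sum((fr[ia, ] - fr[ib, ])^2)), numeric(1))
  mean(d < cutoff)
}
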