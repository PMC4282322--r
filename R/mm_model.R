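## Internal cached energy model: precomputes every geometry-independent
## quantity (exclusion scale matrices, charge products, combined LJ
## parameters, bonded index arrays) once, and evaluates energy and gradient
## with fully vectorized code. Used by the minimizer and the Hessian
## builder, where evaluation count dominates; numerically identical to
## mm_energy()/mm_gradient() (asserted in the test suite).

mm_model <- function(structure, topology, options = mm_options()) {
  at <- structure$atoms
  n <- nrow(at)
  Sele <- pair_scale_matrix(n, topology, options$ele_scale14)
  Svdw <- pair_scale_matrix(n, topology, options$vdw_scale14)
  QQ <- kCOUL * outer(at$charge, at$charge) * Sele
  RM <- outer(at$lj_rmin_half, at$lj_rmin_half, `+`)
  EPS <- sqrt(outer(abs(at$lj_epsilon), abs(at$lj_epsilon))) * Svdw
  ut <- upper.tri(QQ)
  bd <- topology$bonds; an <- topology$angles
  dh <- topology$dihedrals; im <- topology$impropers
  th0 <- an$th0 * pi / 180
  delta <- dh$delta * pi / 180
  psi0 <- im$psi0 * pi / 180

  ## scatter matrices: row r of a term block accumulates into atom idx[r]
  scatter <- function(idx) {
    M <- matrix(0, n, length(idx))
    M[cbind(idx, seq_along(idx))] <- 1
    M
  }
  Sc_bond <- if (nrow(bd)) scatter(c(bd$i, bd$j))
  Sc_ang <- if (nrow(an)) scatter(c(an$i, an$k, an$j))
  Sc_dh <- if (nrow(dh)) scatter(c(dh$i, dh$l, dh$j, dh$k))
  Sc_im <- if (nrow(im)) scatter(c(im$i, im$l, im$j, im$k))

  pair_geom <- function(xyz) {
    G2 <- tcrossprod(xyz)
    sq <- diag(G2)
    D2 <- outer(sq, sq, `+`) - 2 * G2
    D2[D2 < 1e-20] <- 1e-20
    sqrt(D2)
  }

  rows <- function(idx, xyz) xyz[idx, , drop = FALSE]
  rs <- function(m) sqrt(rowSums(m * m))
  crossm <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])

  tors_phi <- function(df, xyz) {
    b1 <- rows(df$j, xyz) - rows(df$i, xyz)
    b2 <- rows(df$k, xyz) - rows(df$j, xyz)
    b3 <- rows(df$l, xyz) - rows(df$k, xyz)
    n1 <- crossm(b1, b2); n2 <- crossm(b2, b3)
    nb2 <- rs(b2)
    list(phi = atan2(rowSums(crossm(n1, n2) * b2) / nb2,
                     rowSums(n1 * n2)),
         b1 = b1, b2 = b2, b3 = b3, n1 = n1, n2 = n2, nb2 = nb2)
  }

  energy <- function(xyz) {
    D <- pair_geom(xyz)
    diag(D) <- 1
    sr6 <- (RM / D)^6
    e_nb <- sum((QQ / D + EPS * (sr6^2 - 2 * sr6))[ut])
    e <- e_nb
    if (nrow(bd)) {
      b <- rs(rows(bd$i, xyz) - rows(bd$j, xyz))
      e <- e + sum(bd$k * (b - bd$b0)^2)
    }
    if (nrow(an)) {
      u <- rows(an$i, xyz) - rows(an$j, xyz)
      v <- rows(an$k, xyz) - rows(an$j, xyz)
      ct <- rowSums(u * v) / (rs(u) * rs(v))
      th <- acos(pmin(1, pmax(-1, ct)))
      e <- e + sum(an$kth * (th - th0)^2)
    }
    if (nrow(dh)) {
      ph <- tors_phi(dh, xyz)$phi
      e <- e + sum(dh$kphi * (1 + cos(dh$n * ph - delta)))
    }
    if (nrow(im)) {
      ps <- tors_phi(im, xyz)$phi
      dpsi <- atan2(sin(ps - psi0), cos(ps - psi0))
      e <- e + sum(im$kpsi * dpsi^2)
    }
    e
  }

  gradient <- function(xyz) {
    n3 <- nrow(xyz)
    D <- pair_geom(xyz)
    diag(D) <- Inf
    sr6 <- (RM / D)^6
    dEdr <- -QQ / D^2 + EPS * 12 * (-sr6^2 + sr6) / D
    G <- matrix(0, n3, 3)
    for (d in 1:3) {
      DIF <- outer(xyz[, d], xyz[, d], `-`)
      G[, d] <- rowSums(dEdr * DIF / D)
    }
    if (nrow(bd)) {
      dv <- rows(bd$i, xyz) - rows(bd$j, xyz)
      b <- rs(dv)
      f <- 2 * bd$k * (b - bd$b0) / b
      G <- G + Sc_bond %*% rbind(f * dv, -f * dv)
    }
    if (nrow(an)) {
      u <- rows(an$i, xyz) - rows(an$j, xyz)
      v <- rows(an$k, xyz) - rows(an$j, xyz)
      nu <- rs(u); nv <- rs(v)
      uh <- u / nu; vh <- v / nv
      ct <- rowSums(uh * vh)
      st <- sqrt(pmax(1 - ct^2, 1e-12))
      th <- acos(pmin(1, pmax(-1, ct)))
      dV <- 2 * an$kth * (th - th0)
      di <- (ct * uh - vh) / (nu * st) * dV
      dk <- (ct * vh - uh) / (nv * st) * dV
      G <- G + Sc_ang %*% rbind(di, dk, -(di + dk))
    }
    tors_grad <- function(df, Sc, dVdphi) {
      tg <- tors_phi(df, xyz)
      dV <- dVdphi(tg$phi)
      p <- -(tg$nb2 / rowSums(tg$n1 * tg$n1)) * tg$n1 * dV
      q <- (tg$nb2 / rowSums(tg$n2 * tg$n2)) * tg$n2 * dV
      s1 <- rowSums(tg$b1 * tg$b2) / tg$nb2^2
      s2 <- rowSums(tg$b3 * tg$b2) / tg$nb2^2
      G + Sc %*% rbind(p, q, -p - s1 * p + s2 * q, -q + s1 * p - s2 * q)
    }
    if (nrow(dh)) G <- tors_grad(dh, Sc_dh, function(phi)
      -dh$kphi * dh$n * sin(dh$n * phi - delta))
    if (nrow(im)) G <- tors_grad(im, Sc_im, function(phi) {
      dpsi <- atan2(sin(phi - psi0), cos(phi - psi0))
      2 * im$kpsi * dpsi
    })
    G
  }

  list(energy = energy, gradient = gradient)
}
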