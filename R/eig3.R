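# Vectorized analytic eigendecomposition of symmetric 3x3 tensors.
#
# Input is an n x 6 matrix of the unique components (xx, xy, xz, yy, yz, zz),
# the storage order used throughout the package. Eigenvalues come from the
# trigonometric solution of the characteristic polynomial; the principal
# eigenvector from a column of (D - l2 I)(D - l3 I), which annihilates the
# two minor eigenspaces. Both are exact for symmetric input up to roundoff
# and are cross-checked against base eigen() in the tests.

eig3_sym <- function(D6) {
  D6 <- rbind(D6)
  n <- nrow(D6)
  xx <- D6[, 1]; xy <- D6[, 2]; xz <- D6[, 3]
  yy <- D6[, 4]; yz <- D6[, 5]; zz <- D6[, 6]

  q <- (xx + yy + zz) / 3
  p1 <- xy^2 + xz^2 + yz^2
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)

  scale <- pmax(abs(xx), abs(yy), abs(zz), abs(xy), abs(xz), abs(yz))
  iso <- p <= scale * 1e-9 + 1e-300  # numerically isotropic (or all-zero)

  l1 <- l2 <- l3 <- q
  act <- which(!iso)
  if (length(act)) {
    pa <- p[act]; qa <- q[act]
    bxx <- (xx[act] - qa) / pa; byy <- (yy[act] - qa) / pa; bzz <- (zz[act] - qa) / pa
    bxy <- xy[act] / pa; bxz <- xz[act] / pa; byz <- yz[act] / pa
    detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(1, pmax(-1, detB / 2))
    phi <- acos(r) / 3
    l1[act] <- qa + 2 * pa * cos(phi)
    l3[act] <- qa + 2 * pa * cos(phi + 2 * pi / 3)
    l2[act] <- 3 * qa - l1[act] - l3[act]
  }

  # principal eigenvector: M = D^2 - (l2+l3) D + l2 l3 I, any nonzero column
  s <- l2 + l3; t2 <- l2 * l3
  d2xx <- xx^2 + xy^2 + xz^2
  d2xy <- xx * xy + xy * yy + xz * yz
  d2xz <- xx * xz + xy * yz + xz * zz
  d2yy <- xy^2 + yy^2 + yz^2
  d2yz <- xy * xz + yy * yz + yz * zz
  d2zz <- xz^2 + yz^2 + zz^2
  mxx <- d2xx - s * xx + t2; mxy <- d2xy - s * xy; mxz <- d2xz - s * xz
  myy <- d2yy - s * yy + t2; myz <- d2yz - s * yz
  mzz <- d2zz - s * zz + t2

  n1 <- mxx^2 + mxy^2 + mxz^2
  n2 <- mxy^2 + myy^2 + myz^2
  n3 <- mxz^2 + myz^2 + mzz^2
  pick <- max.col(cbind(n1, n2, n3), ties.method = "first")
  vx <- ifelse(pick == 1L, mxx, ifelse(pick == 2L, mxy, mxz))
  vy <- ifelse(pick == 1L, mxy, ifelse(pick == 2L, myy, myz))
  vz <- ifelse(pick == 1L, mxz, ifelse(pick == 2L, myz, mzz))
  nv <- sqrt(vx^2 + vy^2 + vz^2)
  good <- !iso & nv > (scale^2 + 1e-300) * 1e-8
  vx <- ifelse(good, vx / nv, 0)
  vy <- ifelse(good, vy / nv, 0)
  vz <- ifelse(good, vz / nv, 0)

  list(values = cbind(l1, l2, l3), pev = cbind(vx, vy, vz), degenerate = !good)
}

# pack a 3x3 symmetric matrix into the 6-component row order
sym_to_6 <- function(M) c(M[1, 1], M[1, 2], M[1, 3], M[2, 2], M[2, 3], M[3, 3])

six_to_sym <- function(v) {
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3, 3)
}
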