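# Small 3D geometry toolbox used throughout the package.
# All angles at the API are in degrees, all lengths in Angstrom.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Rotation matrices (right-handed, angle in degrees)
rot_z <- function(theta) {
  t <- deg2rad(theta); c_ <- cos(t); s <- sin(t)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3L, 3L)
}

rot_y <- function(theta) {
  t <- deg2rad(theta); c_ <- cos(t); s <- sin(t)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3L, 3L)
}

rot_x <- function(theta) {
  t <- deg2rad(theta); c_ <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3L, 3L)
}

# Rotation of `theta` degrees about an arbitrary axis (Rodrigues)
rot_axis <- function(axis, theta) {
  u <- vunit(axis)
  t <- deg2rad(theta); c_ <- cos(t); s <- sin(t)
  ux <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) * c_ + s * ux + (1 - c_) * (u %o% u)
}

# Axis and angle (degrees) of a rotation matrix
rot_decompose <- function(R) {
  skew <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L],
            R[2L, 1L] - R[1L, 2L])
  s <- vnorm(skew) / 2
  co <- (sum(diag(R)) - 1) / 2
  ang <- atan2(s, co)
  if (s < 1e-9) {
    if (co > 0) return(list(axis = c(0, 0, 1), angle = 0))
    # 180 degree rotation: axis from the symmetric part
    M <- (R + diag(3L)) / 2
    ax <- sqrt(pmax(diag(M), 0))
    k <- which.max(ax)
    sgn <- sign(M[k, ] + (seq_len(3L) == k))
    sgn[sgn == 0] <- 1
    return(list(axis = vunit(ax * sgn), angle = 180))
  }
  list(axis = skew / (2 * s), angle = rad2deg(ang))
}

# Geometric midpoint of two rotations (half-way along the geodesic)
rot_mid <- function(R1, R2) {
  d <- rot_decompose(t(R1) %*% R2)
  R1 %*% rot_axis(d$axis, d$angle / 2)
}

# Angle a-b-c in degrees
angle3 <- function(a, b, c) {
  u <- vunit(a - b); v <- vunit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# Signed torsion a-b-c-d in degrees (IUPAC convention)
torsion4 <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

# Place atom D given positions of A, B, C, the C-D bond length, the
# B-C-D angle and the A-B-C-D torsion (natural extension reference frame).
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle); tor <- -deg2rad(torsion)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(M %*% d2 + c)
}

# Least-squares plane normal of a set of points (rows of X).
# The sign is canonicalized against the ring circulation (cross product of
# the first two edges around the centroid) so that the normal is equivariant
# under rigid rotation of the points.
fit_plane_normal <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 atoms to fit a plane")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  ev <- eigen(crossprod(Xc), symmetric = TRUE)
  n <- ev$vectors[, 3L]
  ref <- vcross(Xc[1L, ], Xc[2L, ])
  if (vnorm(ref) > 1e-9 && sum(ref * n) < 0) n <- -n
  n
}

# Kabsch superposition: rotation R and translation t such that
# Q ~ P %*% t(R) + t (P, Q are n x 3 matrices of paired points).
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L, ncol(Q) == 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  fitted <- sweep(Pc %*% t(R), 2L, cq, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(R = R, t = t, rmsd = rmsd, fitted = fitted)
}

apply_rt <- function(X, R, t) {
  sweep(as.matrix(X) %*% t(R), 2L, t, "+")
}
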