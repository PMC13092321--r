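# Internal rigid-body geometry: dihedrals, NeRF atom placement, Kabsch.

#' @noRd
.vnorm <- function(v) sqrt(sum(v * v))

#' @noRd
.unit <- function(v) v / .vnorm(v)

#' Dihedral angle of four points, in degrees, in (-180, 180].
#' @noRd
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(
    b1[2] * b2[3] - b1[3] * b2[2],
    b1[3] * b2[1] - b1[1] * b2[3],
    b1[1] * b2[2] - b1[2] * b2[1]
  )
  n2 <- c(
    b2[2] * b3[3] - b2[3] * b3[2],
    b2[3] * b3[1] - b2[1] * b3[3],
    b2[1] * b3[2] - b2[2] * b3[1]
  )
  m1 <- c(
    n1[2] * b2[3] - n1[3] * b2[2],
    n1[3] * b2[1] - n1[1] * b2[3],
    n1[1] * b2[2] - n1[2] * b2[1]
  )
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / .vnorm(b2)
  -atan2(y, x) * 180 / pi  # IUPAC sign convention
}

#' Place atom D given A-B-C, |CD|, angle(B,C,D) and dihedral(A,B,C,D).
#' Angles in degrees (natural extension reference frame).
#' @noRd
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- .unit(c - b)
  ab <- b - a
  n <- c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  )
  n <- .unit(n)
  m <- c(
    n[2] * bc[3] - n[3] * bc[2],
    n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  d2 <- c(
    -bond * cos(ang),
    bond * sin(ang) * cos(dih),
    bond * sin(ang) * sin(dih)
  )
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Optimal rotation/translation of Q onto P (both n x 3), Kabsch via SVD.
#' Returns list(R, t, rmsd); apply as Q %*% R + t (rows).
#' @noRd
.kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- crossprod(Qc, Pc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  t <- cp - as.vector(cq %*% R)
  Qr <- sweep(Qc %*% R, 2, cp, "+")
  rmsd <- sqrt(mean(rowSums((Qr - P)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

#' Apply a fitted superposition to an m x 3 coordinate matrix.
#' @noRd
.apply_superposition <- function(X, fit) {
  sweep(X %*% fit$R, 2, fit$t, "+")
}

# Ideal backbone geometry constants (single source of truth for generators
# and tests): bond lengths in angstrom, angles in degrees.
.BB_GEOM <- list(
  len_n_ca = 1.458,
  len_ca_c = 1.525,
  len_c_n  = 1.329,
  ang_n_ca_c = 111.2,
  ang_ca_c_n = 116.2,
  ang_c_n_ca = 121.7,
  omega = 180
)
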