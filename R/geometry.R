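# Geometric primitives: torsions, rigid superposition, frame construction.

#' Torsion angle of four points
#'
#' Signed dihedral angle, in degrees, of the four points `p1-p2-p3-p4`
#' (the angle between the plane through p1,p2,p3 and the plane through
#' p2,p3,p4). Vectorised: each argument may be an n x 3 matrix.
#'
#' @param p1,p2,p3,p4 Numeric length-3 vectors or n x 3 matrices.
#' @return Numeric vector of angles in `(-180, 180]`.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, nrow = 1)
  p1 <- as_m(p1); p2 <- as_m(p2); p3 <- as_m(p3); p4 <- as_m(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cross(n1, n2) * b2n)
  ang <- atan2(y, x) * 180 / pi
  # fold -180 onto +180 so the range is (-180, 180]
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

#' Minimal RMSD under rigid superposition (Kabsch)
#'
#' Best-fit root-mean-square deviation between two equally sized point sets
#' after optimal rotation and translation (proper rotation only; no
#' reflection), computed with the Kabsch SVD algorithm.
#'
#' @param a,b n x 3 coordinate matrices, n >= 3.
#' @return RMSD in the units of the coordinates (Angstrom for structures).
#' @export
kabsch_rmsd <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || ncol(a) != 3L || ncol(b) != 3L) {
    stop("coordinates must be n x 3 matrices")
  }
  if (nrow(a) != nrow(b)) stop("point counts differ: ", nrow(a), " vs ", nrow(b))
  if (nrow(a) < 3L) stop("need at least 3 points")
  n <- nrow(a)
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  ga <- sum(a0^2); gb <- sum(b0^2)
  h <- crossprod(a0, b0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  # trace of optimal rotation applied to covariance; reflection excluded
  tr <- sv$d[1] + sv$d[2] + d * sv$d[3]
  msd <- (ga + gb - 2 * tr) / n
  sqrt(max(msd, 0))
}

#' Optimal rigid superposition of one point set onto another
#'
#' Returns the rotation and translation that minimise the RMSD of `mobile`
#' onto `fixed`, plus the transformed coordinates.
#'
#' @param fixed,mobile n x 3 coordinate matrices.
#' @return List with `rotation` (3 x 3), `translation` (length 3), `coords`
#'   (transformed mobile) and `rmsd`.
#' @export
kabsch_superpose <- function(fixed, mobile) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  f0 <- sweep(fixed, 2, cf); m0 <- sweep(mobile, 2, cm)
  sv <- svd(crossprod(m0, f0))
  d <- sign(det(sv$v %*% t(sv$u)))
  corr <- diag(c(1, 1, d))
  rot <- sv$v %*% corr %*% t(sv$u)
  moved <- m0 %*% t(rot)
  out <- sweep(moved, 2, cf, "+")
  list(rotation = rot,
       translation = cf - as.numeric(rot %*% cm),
       coords = out,
       rmsd = sqrt(mean(rowSums((out - fixed)^2))))
}

# Place a new atom D given three reference atoms A-B-C, a bond length |C-D|,
# a bond angle B-C-D (degrees) and a torsion A-B-C-D (degrees). The standard
# internal-coordinate (NeRF) construction used to grow side-chain templates
# and synthetic backbones.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
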