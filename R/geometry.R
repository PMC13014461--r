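## Vector geometry for molecular mechanics. All angles at the API boundary
## are degrees; internal trigonometry is radians.

DEG <- pi / 180

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap angles into (-180, 180]
#'
#' @param x angle(s) in degrees.
#' @return wrapped angle(s) in degrees.
#' @export
wrapAngle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  ifelse(w == -180, 180, w)
}

#' Wrapped absolute angular difference
#'
#' d(a, b) = |((a - b + 180) mod 360) - 180|, the shorter arc between two
#' dihedral readings.
#'
#' @param a,b angles in degrees.
#' @return nonnegative difference in degrees, at most 180.
#' @export
angleDiff <- function(a, b) abs(wrapAngle(a - b))

#' Signed dihedral angle of four atoms
#'
#' IUPAC sign convention: looking down the j-k bond, the angle is positive
#' when i-j-k-l traces a clockwise rotation; a cis (eclipsed) arrangement is
#' 0 degrees and trans is 180. Reversing the quadruple (l,k,j,i) returns the
#' same value.
#'
#' @param conformation N x 3 coordinate matrix (Angstrom).
#' @param quad integer vector of four distinct 1-based atom indices.
#' @return angle in degrees, in (-180, 180].
#' @export
dihedralAngle <- function(conformation, quad) {
  stopifnot(length(quad) == 4L, !anyDuplicated(quad))
  p <- conformation[quad, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-14 || sum(n2^2) < 1e-14)
    stop("degenerate geometry: three consecutive atoms are collinear")
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  wrapAngle(atan2(y, x) / DEG)
}

## Gradient of the dihedral (radians) w.r.t. the four atom positions.
## Returns a 4 x 3 matrix. Standard rigid-rotation formulas.
dihedralGradient <- function(conformation, quad) {
  p <- conformation[quad, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  n1sq <- sum(n1^2); n2sq <- sum(n2^2)
  if (n1sq < 1e-14 || n2sq < 1e-14)
    stop("degenerate geometry: three consecutive atoms are collinear")
  b2n <- sqrt(sum(b2^2))
  gi <- -(b2n / n1sq) * n1
  gl <- (b2n / n2sq) * n2
  f12 <- sum(b1 * b2) / sum(b2^2)
  f32 <- sum(b3 * b2) / sum(b2^2)
  gj <- -(1 + f12) * gi + f32 * gl
  gk <- f12 * gi - (1 + f32) * gl
  rbind(gi, gj, gk, gl)
}

## Bond angle i-j-k in radians plus its gradient (3 x 3) when grad = TRUE.
bondAngle <- function(conformation, ijk, grad = FALSE) {
  u <- conformation[ijk[1], ] - conformation[ijk[2], ]
  v <- conformation[ijk[3], ] - conformation[ijk[2], ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  ct <- max(-1, min(1, sum(u * v) / (nu * nv)))
  th <- acos(ct)
  if (!grad) return(th)
  st <- sqrt(max(1e-12, 1 - ct^2))
  uh <- u / nu; vh <- v / nv
  gi <- (ct * uh - vh) / (nu * st)
  gk <- (ct * vh - uh) / (nv * st)
  list(theta = th, grad = rbind(gi, -(gi + gk), gk))
}

## Rodrigues rotation of points about a unit axis through the origin.
rotateAbout <- function(pts, axis, angleRad) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angleRad) * K + (1 - cos(angleRad)) * (K %*% K)
  pts %*% R
}

#' Set a dihedral by rigid rotation about its central bond
#'
#' Rotates the side of the molecule containing atoms k and l about the j-k
#' axis so that the dihedral i-j-k-l equals `target`. The bond j-k must not
#' lie in a ring (the two sides must separate when it is removed).
#'
#' @param topology a [MoleculeTopology-class].
#' @param conformation N x 3 coordinates.
#' @param quad four atom indices i, j, k, l.
#' @param target target dihedral in degrees.
#' @return the rotated conformation.
#' @export
setDihedral <- function(topology, conformation, quad, target) {
  side <- bondSideAtoms(topology, quad[2], quad[3])
  cur <- dihedralAngle(conformation, quad)
  delta <- -wrapAngle(target - cur) * DEG
  axis <- conformation[quad[3], ] - conformation[quad[2], ]
  origin <- conformation[quad[2], ]
  shifted <- sweep(conformation[side, , drop = FALSE], 2, origin)
  conformation[side, ] <- sweep(rotateAbout(shifted, axis, delta), 2, origin,
                                `+`)
  conformation
}

## Atoms on the k-side of bond j-k (excluding j), by BFS on the bond graph
## with the j-k edge removed. Errors if j-k lies in a ring.
bondSideAtoms <- function(topology, j, k) {
  g <- topologyGraph(topology)
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(j, k)))
  comp <- igraph::components(g2)$membership
  if (comp[j] == comp[k])
    stop("central bond lies in a ring; cannot rotate")
  which(comp == comp[k])
}

## Kabsch optimal superposition: rotate+translate `mob` onto `ref`.
kabschAlign <- function(mob, ref) {
  cm <- colMeans(mob); cr <- colMeans(ref)
  A <- sweep(mob, 2, cm); B <- sweep(ref, 2, cr)
  sv <- svd(crossprod(A, B))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(A %*% t(R), 2, cr, `+`)
}

#' Heavy-atom RMSD after optimal superposition
#'
#' Kabsch rigid-body superposition on the heavy atoms, then root mean square
#' deviation over those atoms.
#'
#' @param topology a [MoleculeTopology-class].
#' @param a,b N x 3 conformations.
#' @return RMSD in Angstrom.
#' @export
heavyAtomRMSD <- function(topology, a, b) {
  hv <- which(topology@atoms$element != "H")
  am <- a[hv, , drop = FALSE]; bm <- b[hv, , drop = FALSE]
  if (length(hv) >= 3L) am <- kabschAlign(am, bm)
  else am <- sweep(sweep(am, 2, colMeans(am)), 2, colMeans(bm), `+`)
  sqrt(mean(rowSums((am - bm)^2)))
}
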