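## Gas-phase AMBER potential: harmonic bonds and angles, Fourier dihedrals,
## Lennard-Jones 12-6 and Coulomb over all non-excluded pairs, with 1-4
## pairs divided by scnb (LJ) and scee (Coulomb). No cutoffs, no periodic
## boundary conditions. All term evaluations are vectorized over rows.

## Coulomb prefactor in kcal*A/(mol*e^2), AMBER convention.
COULOMB_CONST <- 332.0522173

rowCross <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

rowDot <- function(A, B) rowSums(A * B)

## Batch dihedral evaluation for a quad matrix (rows = i,j,k,l indices).
## Returns angles in radians and, when grad = TRUE, the four 3-column
## gradient blocks (d omega / d x, radians per Angstrom).
batchDihedrals <- function(conformation, quads, grad = FALSE) {
  b1 <- conformation[quads[, 2], , drop = FALSE] -
    conformation[quads[, 1], , drop = FALSE]
  b2 <- conformation[quads[, 3], , drop = FALSE] -
    conformation[quads[, 2], , drop = FALSE]
  b3 <- conformation[quads[, 4], , drop = FALSE] -
    conformation[quads[, 3], , drop = FALSE]
  n1 <- rowCross(b1, b2)
  n2 <- rowCross(b2, b3)
  n1sq <- rowDot(n1, n1); n2sq <- rowDot(n2, n2)
  if (any(n1sq < 1e-14) || any(n2sq < 1e-14))
    stop("degenerate geometry: three consecutive atoms are collinear")
  b2n <- sqrt(rowDot(b2, b2))
  y <- rowDot(rowCross(n1, n2), b2) / b2n
  x <- rowDot(n1, n2)
  om <- atan2(y, x)
  if (!grad) return(list(omega = om))
  gi <- -n1 * (b2n / n1sq)
  gl <- n2 * (b2n / n2sq)
  f12 <- rowDot(b1, b2) / b2n^2
  f32 <- rowDot(b3, b2) / b2n^2
  gj <- -gi * (1 + f12) + gl * f32
  gk <- gi * f12 - gl * (1 + f32)
  list(omega = om, gi = gi, gj = gj, gk = gk, gl = gl)
}

## Batch bond angles (radians) with optional gradients.
batchAngles <- function(conformation, ijk, grad = FALSE) {
  u <- conformation[ijk[, 1], , drop = FALSE] -
    conformation[ijk[, 2], , drop = FALSE]
  v <- conformation[ijk[, 3], , drop = FALSE] -
    conformation[ijk[, 2], , drop = FALSE]
  nu <- sqrt(rowDot(u, u)); nv <- sqrt(rowDot(v, v))
  ct <- pmax(-1, pmin(1, rowDot(u, v) / (nu * nv)))
  th <- acos(ct)
  if (!grad) return(list(theta = th))
  st <- sqrt(pmax(1e-12, 1 - ct^2))
  uh <- u / nu; vh <- v / nv
  gi <- (uh * ct - vh) / (nu * st)
  gk <- (vh * ct - uh) / (nv * st)
  list(theta = th, gi = gi, gj = -(gi + gk), gk = gk)
}

#' Dihedral restraint specification
#'
#' Flat-bottom harmonic restraint on a dihedral: zero penalty while the
#' wrapped deviation from `target` is within `tolerance`, quadratic
#' k * (|delta| - tol)^2 beyond it (delta in radians).
#'
#' @param quad four atom indices.
#' @param target target dihedral, degrees.
#' @param k force constant, kcal/mol/rad^2 (default 500).
#' @param tolerance flat-bottom half width, degrees (default 0.5).
#' @return a list of class `DihedralRestraint`.
#' @export
dihedralRestraint <- function(quad, target, k = 500, tolerance = 0.5) {
  stopifnot(k >= 0, tolerance >= 0, length(quad) == 4L)
  structure(list(quad = as.integer(quad), target = target, k = k,
                 tolerance = tolerance), class = "DihedralRestraint")
}

## Flatten a topology into plain vectors/matrices once, so the hot
## minimization loop avoids repeated data.frame access.
compileTopology <- function(topology) {
  at <- topology@atoms
  bd <- topology@bonds
  an <- topology@angles
  to <- topology@torsions
  nb <- topology@nbPairs
  list(
    natom = nrow(at),
    bi = bd$i, bj = bd$j, kb = bd$kb, l0 = bd$l0,
    aijk = as.matrix(an[, c("i", "j", "k"), drop = FALSE]),
    ka = an$ka, th0 = an$theta0 * DEG,
    quads = as.matrix(to[, c("i", "j", "k", "l"), drop = FALSE]),
    vn = to$vn, tn = to$n, tg = to$gamma * DEG,
    nbi = nb$i, nbj = nb$j,
    eps = sqrt(at$epsilon[nb$i] * at$epsilon[nb$j]) / nb$scnb,
    rmin = at$rminHalf[nb$i] + at$rminHalf[nb$j],
    qq = COULOMB_CONST * at$charge[nb$i] * at$charge[nb$j] / nb$scee)
}

compiledEnergy <- function(ct, conformation, restraints = list()) {
  e <- c(bond = 0, angle = 0, torsion = 0, lj = 0, coulomb = 0,
         restraint = 0)
  if (length(ct$bi)) {
    d <- conformation[ct$bj, , drop = FALSE] -
      conformation[ct$bi, , drop = FALSE]
    r <- sqrt(rowDot(d, d))
    e["bond"] <- sum(ct$kb * (r - ct$l0)^2)
  }
  if (nrow(ct$aijk)) {
    th <- batchAngles(conformation, ct$aijk)$theta
    e["angle"] <- sum(ct$ka * (th - ct$th0)^2)
  }
  if (nrow(ct$quads)) {
    om <- batchDihedrals(conformation, ct$quads)$omega
    e["torsion"] <- sum(ct$vn / 2 * (1 + cos(ct$tn * om - ct$tg)))
  }
  if (length(ct$nbi)) {
    d <- conformation[ct$nbj, , drop = FALSE] -
      conformation[ct$nbi, , drop = FALSE]
    r2 <- rowDot(d, d)
    if (any(r2 < 1e-12))
      stop("singularity: zero interatomic distance in a nonbonded pair")
    r <- sqrt(r2)
    s6 <- (ct$rmin / r)^6
    e["lj"] <- sum(ct$eps * (s6^2 - 2 * s6))
    e["coulomb"] <- sum(ct$qq / r)
  }
  for (rs in restraints) {
    if (rs$k == 0) next
    om <- dihedralAngle(conformation, rs$quad)
    dev <- abs(wrapAngle(om - rs$target)) * DEG
    excess <- max(0, dev - rs$tolerance * DEG)
    e["restraint"] <- e["restraint"] + rs$k * excess^2
  }
  c(e, total = sum(e))
}

compiledGradient <- function(ct, conformation, restraints = list()) {
  n <- nrow(conformation)
  G <- matrix(0, n, 3)
  add <- function(idx, v) {
    for (col in 1:3) {
      s <- rowsum(v[, col], idx)
      ii <- as.integer(rownames(s))
      G[ii, col] <<- G[ii, col] + s[, 1]
    }
  }
  if (length(ct$bi)) {
    d <- conformation[ct$bj, , drop = FALSE] -
      conformation[ct$bi, , drop = FALSE]
    r <- sqrt(rowDot(d, d))
    Fv <- d * (2 * ct$kb * (r - ct$l0) / r)
    add(ct$bi, -Fv); add(ct$bj, Fv)
  }
  if (nrow(ct$aijk)) {
    ba <- batchAngles(conformation, ct$aijk, grad = TRUE)
    coef <- 2 * ct$ka * (ba$theta - ct$th0)
    add(ct$aijk[, 1], ba$gi * coef)
    add(ct$aijk[, 2], ba$gj * coef)
    add(ct$aijk[, 3], ba$gk * coef)
  }
  if (nrow(ct$quads)) {
    bt <- batchDihedrals(conformation, ct$quads, grad = TRUE)
    dEdom <- -ct$vn / 2 * ct$tn * sin(ct$tn * bt$omega - ct$tg)
    add(ct$quads[, 1], bt$gi * dEdom)
    add(ct$quads[, 2], bt$gj * dEdom)
    add(ct$quads[, 3], bt$gk * dEdom)
    add(ct$quads[, 4], bt$gl * dEdom)
  }
  if (length(ct$nbi)) {
    d <- conformation[ct$nbj, , drop = FALSE] -
      conformation[ct$nbi, , drop = FALSE]
    r2 <- rowDot(d, d)
    if (any(r2 < 1e-12))
      stop("singularity: zero interatomic distance in a nonbonded pair")
    r <- sqrt(r2)
    s6 <- (ct$rmin / r)^6
    dlj <- (12 * ct$eps / r) * (s6 - s6^2)
    dcl <- -ct$qq / r2
    Fv <- d * ((dlj + dcl) / r)
    add(ct$nbi, -Fv); add(ct$nbj, Fv)
  }
  for (rs in restraints) {
    if (rs$k == 0) next
    om <- dihedralAngle(conformation, rs$quad)
    dev <- wrapAngle(om - rs$target) * DEG
    excess <- abs(dev) - rs$tolerance * DEG
    if (excess > 0) {
      dEdom <- 2 * rs$k * excess * sign(dev)
      dg <- dihedralGradient(conformation, rs$quad)
      G[rs$quad, ] <- G[rs$quad, ] + dEdom * dg
    }
  }
  G
}

#' Total AMBER energy of a conformation
#'
#' Evaluates the AMBER functional form term by term and returns a named
#' breakdown. Restraint energies are reported separately and included in
#' `total`.
#'
#' @param topology a [MoleculeTopology-class].
#' @param conformation N x 3 coordinates (Angstrom).
#' @param restraints optional list of [dihedralRestraint()] objects.
#' @return named numeric vector with components `bond`, `angle`, `torsion`,
#'   `lj`, `coulomb`, `restraint`, `total` (kcal/mol).
#' @export
totalEnergy <- function(topology, conformation, restraints = list()) {
  compiledEnergy(compileTopology(topology), conformation, restraints)
}

#' Analytic gradient of the AMBER energy
#'
#' Exact first derivatives of [totalEnergy()] with respect to Cartesian
#' coordinates, including restraint forces.
#'
#' @inheritParams totalEnergy
#' @return N x 3 matrix, kcal/mol/Angstrom.
#' @export
energyGradient <- function(topology, conformation, restraints = list()) {
  compiledGradient(compileTopology(topology), conformation, restraints)
}

#' Restrained Cartesian energy minimization
#'
#' Limited-memory quasi-Newton (L-BFGS-B) minimization of the AMBER energy
#' plus optional flat-bottom dihedral restraints. Converges on the maximum
#' gradient component.
#'
#' @inheritParams totalEnergy
#' @param convergence maximum allowed gradient component at the solution,
#'   kcal/mol/Angstrom (default 1e-4).
#' @param maxit maximum optimizer iterations.
#' @return list with `conformation`, `energy` (breakdown at the solution),
#'   `converged`, `maxGradient`.
#' @export
restrainedMinimize <- function(topology, conformation, restraints = list(),
                               convergence = 1e-4, maxit = 2000) {
  n <- nrow(conformation)
  ct <- compileTopology(topology)
  fn <- function(p) {
    unname(compiledEnergy(ct, matrix(p, n, 3), restraints)["total"])
  }
  gr <- function(p) as.numeric(compiledGradient(ct, matrix(p, n, 3),
                                                restraints))
  opt <- stats::optim(as.numeric(conformation), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 100,
                                     pgtol = convergence))
  conf <- matrix(opt$par, n, 3)
  g <- compiledGradient(ct, conf, restraints)
  mg <- max(abs(g))
  conv <- mg <= convergence
  if (!conv)
    warning(sprintf(
      "minimization did not reach max-gradient %.1e (reached %.2e); returning best geometry",
      convergence, mg))
  list(conformation = conf,
       energy = totalEnergy(topology, conf, restraints),
       converged = conv, maxGradient = mg)
}
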