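## Seeded synthetic fixtures: small united-atom molecules with explicit
## hand-specified force-field parameters (physically plausible round
## numbers, not real GAFF2 values), deterministic 3D geometries, synthetic
## Fourier reference profiles, and a mock reference backend with exactly
## known ground truth.

## Place a new atom from three predecessors with given internal
## coordinates (bond r to c, angle theta at c w.r.t. b, dihedral phi
## w.r.t. a-b-c).
placeAtom <- function(a, b, c, r, theta, phi) {
  th <- theta * DEG; ph <- phi * DEG
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + d[1] * bc + d[2] * m + d[3] * n
}

## Default parameter table for auto-generated bonded terms.
fixtureBondParams <- function(elA, elB, ring) {
  if (ring) c(kb = 450, l0 = 1.40)
  else if ("O" %in% c(elA, elB)) c(kb = 570, l0 = 1.23)
  else if ("N" %in% c(elA, elB)) c(kb = 330, l0 = 1.38)
  else c(kb = 300, l0 = 1.526)
}

## Derive angle and torsion tables from the bond graph with plausible
## defaults: ring centers are trigonal (120 deg), chains tetrahedral-like
## (112 deg); ring torsions are stiff twofold planar terms, rotatable
## chain torsions soft threefold terms.
deriveBondedTerms <- function(atoms, bonds) {
  tmp <- moleculeTopology(atoms, bonds,
                          data.frame(i = integer(), j = integer(),
                                     k = integer(), ka = numeric(),
                                     theta0 = numeric()), NULL)
  ra <- ringAtoms(tmp)
  rb <- ringBonds(tmp)
  rkey <- paste(rb$i, rb$j)
  angles <- NULL
  for (j in seq_len(nrow(atoms))) {
    nbs <- neighborsOf(tmp, j)
    if (length(nbs) < 2) next
    for (a in seq_along(nbs)[-length(nbs)]) for (b in (a + 1):length(nbs)) {
      inRing <- j %in% ra
      angles <- rbind(angles, data.frame(
        i = nbs[a], j = j, k = nbs[b],
        ka = if (inRing) 70 else 60,
        theta0 = if (inRing) 120 else 112))
    }
  }
  tors <- NULL
  for (r in seq_len(nrow(bonds))) {
    j <- bonds$i[r]; k <- bonds$j[r]
    ring <- paste(min(j, k), max(j, k)) %in% rkey
    for (i in setdiff(neighborsOf(tmp, j), k)) {
      for (l in setdiff(neighborsOf(tmp, k), j)) {
        if (i == l) next
        tors <- rbind(tors, if (ring) {
          data.frame(i = i, j = j, k = k, l = l, vn = 3.5, n = 2,
                     gamma = 180)
        } else {
          data.frame(i = i, j = j, k = k, l = l, vn = 0.30, n = 3,
                     gamma = 0)
        })
      }
    }
  }
  if (is.null(angles)) angles <- data.frame(i = integer(), j = integer(),
                                            k = integer(), ka = numeric(),
                                            theta0 = numeric())
  list(angles = angles, torsions = tors)
}

fixtureAtomRow <- function(name, element, type, charge) {
  lj <- switch(element,
               H = c(1.487, 0.0157), O = c(1.6612, 0.21),
               N = c(1.824, 0.17), c(1.908, 0.1094))
  data.frame(name = name, element = element, type = type, charge = charge,
             mass = switch(element, H = 1.008, O = 16.00, N = 14.01, 12.01),
             rminHalf = lj[1], epsilon = lj[2])
}

#' Built-in test molecules
#'
#' Deterministic united-atom fixtures with explicit force-field parameters:
#' * `butane_like` — a six-carbon alkane chain whose central torsion is a
#'   butane-like rotor with non-terminal ends.
#' * `biphenyl_like` — two six-rings joined by a single bond (exercises the
#'   ring-exclusion rule).
#' * `amide_chain` — an alkyl chain interrupted by an amide (exercises
#'   functional-group cleavage protection).
#' * `two_region` — two flexible chains on opposite sides of a rigid ring
#'   (exercises the fragmentation decision).
#' * `rigid_ring` — a lone aromatic-like ring (no significant torsions).
#' * `torsion_probe` — a four-atom rotor with zero nonbonded background,
#'   for clean parameter-recovery experiments.
#'
#' @param name one of the fixture names above.
#' @return list with `name`, `topology` ([MoleculeTopology-class]) and
#'   `conformation` (N x 3 matrix).
#' @export
makeFixture <- function(name = c("butane_like", "biphenyl_like",
                                 "amide_chain", "two_region", "rigid_ring",
                                 "torsion_probe")) {
  name <- match.arg(name)
  fx <- switch(name,
    butane_like = fixtureChain(6, prefix = "C", type = "c3"),
    torsion_probe = fixtureProbe(),
    rigid_ring = fixtureRing(),
    biphenyl_like = fixtureBiphenyl(),
    amide_chain = fixtureAmide(),
    two_region = fixtureTwoRegion())
  fx$name <- name
  fx
}

chainCoords <- function(n, l = 1.526, theta = 112, phi = 180) {
  co <- matrix(0, n, 3)
  co[1, ] <- c(0, 0, 0)
  if (n >= 2) co[2, ] <- c(l, 0, 0)
  if (n >= 3) co[3, ] <- co[2, ] + l * c(-cos(theta * DEG),
                                         sin(theta * DEG), 0)
  if (n >= 4) for (q in 4:n)
    co[q, ] <- placeAtom(co[q - 3, ], co[q - 2, ], co[q - 1, ], l, theta,
                         phi)
  co
}

fixtureChain <- function(n, prefix = "C", type = "c3") {
  atoms <- do.call(rbind, lapply(seq_len(n), function(q)
    fixtureAtomRow(paste0(prefix, q), "C", type,
                   0.05 * (-1)^q)))
  bonds <- data.frame(i = seq_len(n - 1), j = 2:n, kb = 300, l0 = 1.526,
                      order = 1)
  bt <- deriveBondedTerms(atoms, bonds)
  list(topology = moleculeTopology(atoms, bonds, bt$angles, bt$torsions),
       conformation = chainCoords(n))
}

fixtureProbe <- function() {
  atoms <- rbind(fixtureAtomRow("X1", "C", "x1", 0),
                 fixtureAtomRow("X2", "C", "x2", 0),
                 fixtureAtomRow("X3", "C", "x2", 0),
                 fixtureAtomRow("X4", "C", "x1", 0))
  atoms$epsilon <- 0
  bonds <- data.frame(i = 1:3, j = 2:4, kb = 300, l0 = 1.526, order = 1)
  angles <- data.frame(i = 1:2, j = 2:3, k = 3:4, ka = 60, theta0 = 112)
  torsions <- data.frame(i = 1, j = 2, k = 3, l = 4, vn = 1.0, n = 3,
                         gamma = 0)
  list(topology = moleculeTopology(atoms, bonds, angles, torsions),
       conformation = chainCoords(4))
}

ringCoords <- function(center = c(0, 0, 0), radius = 1.40, twist = 0,
                       phase = 0) {
  ang <- (phase + seq(0, 300, by = 60)) * DEG
  base <- cbind(radius * cos(ang), radius * sin(ang) * cos(twist * DEG),
                radius * sin(ang) * sin(twist * DEG))
  sweep(base, 2, center, `+`)
}

fixtureRing <- function() {
  atoms <- do.call(rbind, lapply(1:6, function(q)
    fixtureAtomRow(paste0("R", q), "C", "ca", 0.02 * (-1)^q)))
  bonds <- data.frame(i = 1:6, j = c(2:6, 1), kb = 450, l0 = 1.40,
                      order = rep(c(2, 1), 3))
  bt <- deriveBondedTerms(atoms, bonds)
  list(topology = moleculeTopology(atoms, bonds, bt$angles, bt$torsions),
       conformation = ringCoords())
}

fixtureBiphenyl <- function() {
  co1 <- ringCoords(center = c(0, 0, 0))
  co2 <- ringCoords(center = c(4.28, 0, 0), twist = 40, phase = 180)
  atoms <- do.call(rbind, lapply(1:12, function(q)
    fixtureAtomRow(paste0("R", q), "C", if (q %in% c(1, 7)) "cp" else "ca",
                   0.02 * (-1)^q)))
  bonds <- rbind(
    data.frame(i = 1:6, j = c(2:6, 1), kb = 450, l0 = 1.40,
               order = rep(c(2, 1), 3)),
    data.frame(i = 7:12, j = c(8:12, 7), kb = 450, l0 = 1.40,
               order = rep(c(2, 1), 3)),
    data.frame(i = 1, j = 7, kb = 350, l0 = 1.48, order = 1))
  bt <- deriveBondedTerms(atoms, bonds)
  ## soften the inter-ring torsions so the rotor actually turns
  sel <- (bt$torsions$j == 1 & bt$torsions$k == 7) |
    (bt$torsions$j == 7 & bt$torsions$k == 1)
  bt$torsions$vn[sel] <- 0.5
  bt$torsions$n[sel] <- 2
  bt$torsions$gamma[sel] <- 180
  list(topology = moleculeTopology(atoms, bonds, bt$angles, bt$torsions),
       conformation = rbind(co1, co2))
}

fixtureAmide <- function() {
  ## C1-C2-C3-C4(=O9)-N5-C6-C7-C8, united atom
  el <- c("C", "C", "C", "C", "N", "C", "C", "C", "O")
  ty <- c("c3", "c3", "c3", "c", "n", "c3", "c3", "c3", "o")
  ch <- c(0.05, -0.05, 0.02, 0.55, -0.55, 0.05, -0.05, 0.03, -0.05)
  atoms <- do.call(rbind, lapply(1:9, function(q)
    fixtureAtomRow(paste0(el[q], q), el[q], ty[q], ch[q])))
  bonds <- data.frame(
    i = c(1, 2, 3, 4, 5, 6, 7, 4),
    j = c(2, 3, 4, 5, 6, 7, 8, 9),
    kb = c(300, 300, 300, 330, 330, 300, 300, 570),
    l0 = c(1.526, 1.526, 1.526, 1.38, 1.45, 1.526, 1.526, 1.23),
    order = c(1, 1, 1, 1, 1, 1, 1, 2))
  bt <- deriveBondedTerms(atoms, bonds)
  ## stiffen the amide C-N torsions (planar) and keep chain rotors soft
  sel <- (bt$torsions$j == 4 & bt$torsions$k == 5) |
    (bt$torsions$j == 5 & bt$torsions$k == 4)
  bt$torsions$vn[sel] <- 10
  bt$torsions$n[sel] <- 2
  bt$torsions$gamma[sel] <- 180
  co <- chainCoords(8, theta = 112)
  co <- rbind(co, placeAtom(co[2, ], co[3, ], co[4, ], 1.23, 120, 60))
  list(topology = moleculeTopology(atoms, bonds, bt$angles, bt$torsions),
       conformation = co)
}

fixtureTwoRegion <- function() {
  ## chain A (4 C) - six-ring - chain B (4 C)
  ring <- ringCoords(center = c(0, 0, 0))
  atoms <- do.call(rbind, c(
    lapply(1:6, function(q) fixtureAtomRow(paste0("R", q), "C", "ca",
                                           0.02 * (-1)^q)),
    lapply(1:4, function(q) fixtureAtomRow(paste0("A", q), "C", "c3",
                                           0.05 * (-1)^q)),
    lapply(1:4, function(q) fixtureAtomRow(paste0("B", q), "C", "c3",
                                           0.05 * (-1)^q))))
  ## atoms 1..6 ring, 7..10 chain A off ring atom 1, 11..14 chain B off
  ## ring atom 4 (para)
  bonds <- rbind(
    data.frame(i = 1:6, j = c(2:6, 1), kb = 450, l0 = 1.40,
               order = rep(c(2, 1), 3)),
    data.frame(i = c(1, 7, 8, 9), j = c(7, 8, 9, 10), kb = 300,
               l0 = 1.526, order = 1),
    data.frame(i = c(4, 11, 12, 13), j = c(11, 12, 13, 14), kb = 300,
               l0 = 1.526, order = 1))
  bt <- deriveBondedTerms(atoms, bonds)
  co <- ring
  co <- rbind(co, placeAtom(co[3, ], co[2, ], co[1, ], 1.526, 120, 180))
  co <- rbind(co, placeAtom(co[2, ], co[1, ], co[7, ], 1.526, 112, 180))
  co <- rbind(co, placeAtom(co[1, ], co[7, ], co[8, ], 1.526, 112, 60))
  co <- rbind(co, placeAtom(co[7, ], co[8, ], co[9, ], 1.526, 112, 180))
  co <- rbind(co, placeAtom(co[6, ], co[5, ], co[4, ], 1.526, 120, 180))
  co <- rbind(co, placeAtom(co[5, ], co[4, ], co[11, ], 1.526, 112, 180))
  co <- rbind(co, placeAtom(co[4, ], co[11, ], co[12, ], 1.526, 112, -60))
  co <- rbind(co, placeAtom(co[11, ], co[12, ], co[13, ], 1.526, 112, 180))
  list(topology = moleculeTopology(atoms, bonds, bt$angles, bt$torsions),
       conformation = co)
}

#' Synthetic Fourier reference profile
#'
#' E(theta) = sum_n Vn/2 (1 + cos(n theta - gamma_n)) plus optional seeded
#' Gaussian noise, shifted so the minimum is zero.
#'
#' @param components data.frame with columns `vn`, `n`, `gamma`.
#' @param grid a [ScanGrid-class].
#' @param sigma noise standard deviation, kcal/mol (default 0).
#' @param seed RNG seed for the noise.
#' @return a [ScanProfile-class] with empty geometries.
#' @export
syntheticReference <- function(components, grid = makeGrid(), sigma = 0,
                               seed = 1) {
  stopifnot(sigma >= 0)
  th <- grid@angles * DEG
  e <- vapply(th, function(t0)
    sum(components$vn / 2 * (1 + cos(components$n * t0 -
                                       components$gamma * DEG))), 0)
  if (sigma > 0)
    e <- e + withSeed(seed, function() stats::rnorm(length(e), 0, sigma))
  new("ScanProfile", key = list(quad = NA_integer_, typeQuad = "synthetic"),
      grid = grid, energies = e - min(e), geometries = list(),
      backend = "synthetic-oracle", centroid = NA_integer_,
      degraded = FALSE)
}

#' Mock reference backend with exactly known ground truth
#'
#' Draws a seeded perturbation of every proper torsion type's leading
#' amplitude and returns a scan backend that computes restrained-minimized
#' energies under the perturbed topology. Fitting the original topology
#' against this backend therefore has a known answer: the perturbed
#' parameters.
#'
#' @param topology a [MoleculeTopology-class].
#' @param perturbationSeed integer seed.
#' @param deltaV half-width of the uniform amplitude perturbation,
#'   kcal/mol (default 2; 0 gives an identity backend).
#' @param k,tolerance restraint settings of the backend's minimizations.
#' @return list with `backend` (a ScanBackend), `topology` (the perturbed
#'   topology) and `truth` (named list of perturbed component tables by
#'   type quadruple).
#' @export
mockQmBackend <- function(topology, perturbationSeed = 1, deltaV = 2,
                          k = 500, tolerance = 0.5) {
  to <- topology@torsions
  ty <- topology@atoms$type
  proper <- which(!to$improper)
  quadType <- vapply(proper, function(r) {
    fwd <- paste(ty[c(to$i[r], to$j[r], to$k[r], to$l[r])], collapse = "-")
    rev <- paste(ty[c(to$l[r], to$k[r], to$j[r], to$i[r])], collapse = "-")
    min(fwd, rev)
  }, "")
  types <- unique(quadType)
  shifts <- withSeed(perturbationSeed, function()
    stats::runif(length(types), -deltaV, deltaV))
  names(shifts) <- types
  pert <- topology
  newV <- to$vn
  for (r in seq_along(proper)) {
    rr <- proper[r]
    newV[rr] <- max(0.05, to$vn[rr] + shifts[quadType[r]])
  }
  if (deltaV == 0) newV <- to$vn
  pert@torsions$vn <- newV
  truth <- lapply(types, function(tq) {
    rows <- proper[quadType == tq]
    first <- rows[to$i[rows] == to$i[rows[1]] & to$j[rows] == to$j[rows[1]] &
                    to$k[rows] == to$k[rows[1]] &
                    to$l[rows] == to$l[rows[1]]]
    data.frame(vn = newV[first], n = to$n[first], gamma = to$gamma[first],
               scee = to$scee[first], scnb = to$scnb[first])
  })
  names(truth) <- types
  backend <- structure(list(
    tag = "mock-qm",
    point = function(topo, conformation, quad, target) {
      conf <- setDihedral(pert, conformation, quad, target)
      res <- suppressWarnings(restrainedMinimize(
        pert, conf,
        list(dihedralRestraint(quad, target, k = k,
                               tolerance = tolerance)),
        convergence = 1e-3))
      list(conformation = res$conformation,
           energy = unname(totalEnergy(pert, res$conformation)["total"]),
           ok = res$converged ||
             angleDiff(dihedralAngle(res$conformation, quad), target) <=
               tolerance + 2)
    }), class = "ScanBackend")
  list(backend = backend, topology = pert, truth = truth)
}

#' Seeded per-centroid charge sets
#'
#' Jitters the topology charges independently per centroid while exactly
#' conserving the total molecular charge, emulating conformer-dependent
#' charge models.
#'
#' @param topology a [MoleculeTopology-class].
#' @param nSets number of charge sets.
#' @param sigma jitter scale, e (default 0.01).
#' @param seed RNG seed.
#' @return list of per-atom charge vectors.
#' @export
makeChargeSets <- function(topology, nSets, sigma = 0.01, seed = 1) {
  q0 <- topology@atoms$charge
  withSeed(seed, function() {
    lapply(seq_len(nSets), function(k) {
      dq <- stats::rnorm(length(q0), 0, sigma)
      q0 + dq - mean(dq)
    })
  })
}
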