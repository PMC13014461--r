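## Independent oracles used across the suite. Deliberately naive: double
## loops, Floyd-Warshall distances, plain trigonometry — no shared code
## paths with the implementation beyond the public topology accessors.

DEG_T <- pi / 180

## All-pairs graph distances by Floyd-Warshall on the bond list.
oracleDistances <- function(natom, bonds) {
  D <- matrix(Inf, natom, natom)
  diag(D) <- 0
  for (r in seq_len(nrow(bonds))) {
    D[bonds$i[r], bonds$j[r]] <- 1
    D[bonds$j[r], bonds$i[r]] <- 1
  }
  for (k in seq_len(natom)) for (i in seq_len(natom)) for (j in seq_len(natom))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

## Naive term-by-term AMBER energy: explicit double loop over atom pairs,
## scalar trigonometry per bonded term.
oracleEnergy <- function(top, conf) {
  at <- atoms(top)
  bd <- bonds(top)
  n <- nrow(at)
  eb <- ea <- et <- el <- ec <- 0
  for (r in seq_len(nrow(bd))) {
    d <- sqrt(sum((conf[bd$i[r], ] - conf[bd$j[r], ])^2))
    eb <- eb + bd$kb[r] * (d - bd$l0[r])^2
  }
  an <- top@angles
  for (r in seq_len(nrow(an))) {
    u <- conf[an$i[r], ] - conf[an$j[r], ]
    v <- conf[an$k[r], ] - conf[an$j[r], ]
    th <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    ea <- ea + an$ka[r] * (th - an$theta0[r] * DEG_T)^2
  }
  to <- torsions(top)
  for (r in seq_len(nrow(to))) {
    om <- oracleDihedral(conf, c(to$i[r], to$j[r], to$k[r], to$l[r])) * DEG_T
    et <- et + to$vn[r] / 2 * (1 + cos(to$n[r] * om - to$gamma[r] * DEG_T))
  }
  D <- oracleDistances(n, bd)
  p14 <- top@pairs14
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] <= 2) next
    r <- sqrt(sum((conf[i, ] - conf[j, ])^2))
    rmin <- at$rminHalf[i] + at$rminHalf[j]
    eps <- sqrt(at$epsilon[i] * at$epsilon[j])
    se <- 1; sn <- 1
    if (D[i, j] == 3) {
      m <- which(p14$i == i & p14$j == j)
      se <- p14$scee[m]; sn <- p14$scnb[m]
    }
    el <- el + eps * ((rmin / r)^12 - 2 * (rmin / r)^6) / sn
    ec <- ec + 332.0522173 * at$charge[i] * at$charge[j] / (r * se)
  }
  c(bond = eb, angle = ea, torsion = et, lj = el, coulomb = ec,
    total = eb + ea + et + el + ec)
}

## Signed dihedral by explicit plane-normal construction.
oracleDihedral <- function(conf, quad) {
  p <- conf[quad, ]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(max(-1, min(1, cosphi))) / DEG_T
  if (sum(cr(n1, n2) * b2) < 0) phi <- -phi
  phi
}

## Central finite-difference gradient of the total energy.
fdGradient <- function(top, conf, h = 1e-5) {
  G <- matrix(0, nrow(conf), 3)
  for (i in seq_len(nrow(conf))) for (c0 in 1:3) {
    cp <- conf; cm <- conf
    cp[i, c0] <- cp[i, c0] + h
    cm[i, c0] <- cm[i, c0] - h
    G[i, c0] <- (totalEnergy(top, cp)["total"] -
                   totalEnergy(top, cm)["total"]) / (2 * h)
  }
  G
}

## Random tree-shaped topology with jittered chain geometry. Small enough
## for the oracles, general enough to hit every energy term.
randomFixture <- function(seed, natom = 6) {
  set.seed(seed)
  parent <- c(0, seq_len(natom - 1))
  for (q in 3:natom) parent[q] <- sample(seq_len(q - 1), 1)
  bonds <- data.frame(i = parent[-1], j = 2:natom,
                      kb = runif(natom - 1, 200, 400),
                      l0 = runif(natom - 1, 1.3, 1.6))
  atoms <- data.frame(name = paste0("C", seq_len(natom)), element = "C",
                      type = paste0("t", sample(1:3, natom, TRUE)),
                      charge = round(runif(natom, -0.2, 0.2), 3),
                      mass = 12.01, rminHalf = runif(natom, 1.7, 2.0),
                      epsilon = runif(natom, 0.05, 0.15))
  atoms$charge <- atoms$charge - mean(atoms$charge)
  ## bonded paths for angle/torsion terms
  adj <- lapply(seq_len(natom), function(v)
    c(bonds$j[bonds$i == v], bonds$i[bonds$j == v]))
  angles <- NULL
  for (j in seq_len(natom)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    for (a in seq_along(nb)[-length(nb)]) for (b in (a + 1):length(nb))
      angles <- rbind(angles, data.frame(i = nb[a], j = j, k = nb[b],
                                         ka = runif(1, 40, 80),
                                         theta0 = runif(1, 100, 120)))
  }
  tors <- NULL
  for (r in seq_len(nrow(bonds))) {
    j <- bonds$i[r]; k <- bonds$j[r]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
      if (i == l) next
      tors <- rbind(tors, data.frame(i = i, j = j, k = k, l = l,
                                     vn = runif(1, 0.2, 2), n = sample(1:3, 1),
                                     gamma = sample(c(0, 180), 1)))
    }
  }
  if (is.null(angles))
    angles <- data.frame(i = integer(), j = integer(), k = integer(),
                         ka = numeric(), theta0 = numeric())
  top <- moleculeTopology(atoms, bonds, angles, tors)
  conf <- matrix(rnorm(natom * 3, sd = 0.25), natom, 3)
  for (q in 2:natom) conf[q, ] <- conf[parent[q], ] +
    runif(3, 0.7, 1.2) * sample(c(-1, 1), 3, TRUE)
  list(topology = top, conformation = conf)
}
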