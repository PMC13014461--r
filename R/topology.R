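## Topology construction. The nonbonded pair classification follows AMBER
## convention: 1-2 and 1-3 pairs excluded, 1-4 pairs scaled by the owning
## dihedral's scee/scnb divisors, all more distant pairs full strength.

#' Build a MoleculeTopology from explicit parameter tables
#'
#' Derives the exclusion and 1-4 pair lists from graph distances on the bond
#' network: pairs at distance 1 or 2 are excluded, pairs at distance exactly
#' 3 are 1-4 pairs scaled by the scee/scnb of the first proper torsion
#' spanning them (AMBER defaults 1.2/2.0 if no torsion spans the pair), and
#' every other pair interacts at full strength.
#'
#' @param atoms data.frame with columns name, element, type, charge, mass,
#'   rminHalf, epsilon.
#' @param bonds data.frame with columns i, j, kb, l0 and optionally order.
#' @param angles data.frame with columns i, j, k, ka, theta0.
#' @param torsions data.frame with columns i, j, k, l, vn, n, gamma and
#'   optionally scee, scnb, improper.
#' @return a [MoleculeTopology-class].
#' @export
moleculeTopology <- function(atoms, bonds, angles, torsions) {
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  angles <- as.data.frame(angles)
  torsions <- as.data.frame(torsions)
  if (is.null(bonds$order)) bonds$order <- rep(1, nrow(bonds))
  if (nrow(torsions)) {
    if (is.null(torsions$scee)) torsions$scee <- 1.2
    if (is.null(torsions$scnb)) torsions$scnb <- 2.0
    if (is.null(torsions$improper)) torsions$improper <- FALSE
  } else {
    torsions <- data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), vn = numeric(), n = integer(),
                           gamma = numeric(), scee = numeric(),
                           scnb = numeric(), improper = logical())
  }
  ## canonical row order makes topologies comparable however they were
  ## assembled (merging fit results in any order yields identical objects)
  if (nrow(torsions)) {
    ord <- order(torsions$i, torsions$j, torsions$k, torsions$l,
                 torsions$improper, torsions$n)
    torsions <- torsions[ord, , drop = FALSE]
    rownames(torsions) <- NULL
  }
  nb <- classifyPairs(nrow(atoms), bonds, torsions)
  torsions$calc14 <- nb$calc14
  new("MoleculeTopology", atoms = atoms, bonds = bonds, angles = angles,
      torsions = torsions, pairs14 = nb$pairs14, excluded = nb$excluded,
      nbPairs = nb$nbPairs)
}

classifyPairs <- function(natom, bonds, torsions) {
  emptyPair <- data.frame(i = integer(), j = integer())
  if (natom < 2L || nrow(bonds) == 0L) {
    nbP <- if (natom < 2L) {
      data.frame(i = integer(), j = integer(), scee = numeric(),
                 scnb = numeric())
    } else {
      cmb <- t(combn(natom, 2))
      data.frame(i = cmb[, 1], j = cmb[, 2], scee = 1, scnb = 1)
    }
    return(list(pairs14 = cbind(emptyPair, scee = numeric(0),
                                scnb = numeric(0)),
                excluded = emptyPair, nbPairs = nbP,
                calc14 = rep(FALSE, nrow(torsions))))
  }
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, natom - igraph::vcount(g)))
  D <- igraph::distances(g)
  cmb <- t(combn(natom, 2))
  dd <- D[cmb]
  excluded <- data.frame(i = cmb[dd <= 2, 1], j = cmb[dd <= 2, 2])
  is14 <- dd == 3
  p14 <- data.frame(i = cmb[is14, 1], j = cmb[is14, 2],
                    scee = rep(1.2, sum(is14)), scnb = rep(2.0, sum(is14)))
  ## assign each 1-4 pair to the first proper torsion spanning it
  calc14 <- rep(FALSE, nrow(torsions))
  if (nrow(p14) && nrow(torsions)) {
    pkey <- paste(p14$i, p14$j)
    proper <- which(!torsions$improper)
    owned <- character()
    for (t in proper) {
      a <- min(torsions$i[t], torsions$l[t])
      b <- max(torsions$i[t], torsions$l[t])
      k <- paste(a, b)
      if (k %in% pkey && !(k %in% owned)) {
        owned <- c(owned, k)
        calc14[t] <- TRUE
        m <- match(k, pkey)
        p14$scee[m] <- torsions$scee[t]
        p14$scnb[m] <- torsions$scnb[t]
      }
    }
  }
  full <- dd > 3
  nbP <- rbind(
    data.frame(i = cmb[full, 1], j = cmb[full, 2],
               scee = rep(1, sum(full)), scnb = rep(1, sum(full))),
    p14)
  list(pairs14 = p14, excluded = excluded, nbPairs = nbP, calc14 = calc14)
}

## igraph bond graph of a topology (vertices = atoms, edges = bonds).
topologyGraph <- function(topology) {
  g <- igraph::make_empty_graph(n = nrow(topology@atoms), directed = FALSE)
  if (nrow(topology@bonds))
    g <- igraph::add_edges(g, t(as.matrix(topology@bonds[, c("i", "j")])))
  g
}

## Heavy-atom induced subgraph; vertex attribute `parent` maps back.
heavyGraph <- function(topology) {
  hv <- which(topology@atoms$element != "H")
  g <- topologyGraph(topology)
  sub <- igraph::induced_subgraph(g, hv)
  igraph::V(sub)$parent <- hv
  sub
}

## Ring membership. An edge is in a ring iff it is not a bridge; an atom iff
## it is an endpoint of a ring edge. Equivalent to SSSR membership for the
## exclusion tests the workflow performs, independent of ring size.
ringAtoms <- function(topology) {
  g <- topologyGraph(topology)
  if (igraph::ecount(g) == 0L) return(integer())
  br <- igraph::bridges(g)
  ringE <- setdiff(seq_len(igraph::ecount(g)), as.integer(br))
  if (!length(ringE)) return(integer())
  sort(unique(as.integer(igraph::ends(g, ringE))))
}

ringBonds <- function(topology) {
  g <- topologyGraph(topology)
  if (igraph::ecount(g) == 0L)
    return(data.frame(i = integer(), j = integer()))
  br <- as.integer(igraph::bridges(g))
  ringE <- setdiff(seq_len(igraph::ecount(g)), br)
  e <- igraph::ends(g, ringE)
  data.frame(i = pmin(e[, 1], e[, 2]), j = pmax(e[, 1], e[, 2]))
}

## Neighbor list helper.
neighborsOf <- function(topology, v) {
  b <- topology@bonds
  sort(c(b$j[b$i == v], b$i[b$j == v]))
}

## Terminal heavy atoms: heavy atoms with exactly one heavy neighbor.
terminalHeavyAtoms <- function(topology) {
  el <- topology@atoms$element
  hv <- which(el != "H")
  out <- integer()
  for (v in hv) {
    nb <- neighborsOf(topology, v)
    if (sum(el[nb] != "H") <= 1L) out <- c(out, v)
  }
  out
}

#' Replace one torsion type's Fourier components
#'
#' Replaces, for every proper torsion instance matching the atom-type
#' quadruple of `key`, the Fourier component rows with `components`
#' (columns vn, n, gamma, scee, scnb). The nonbonded 1-4 scaling of the
#' affected pairs is updated consistently.
#'
#' @param topology a [MoleculeTopology-class].
#' @param key a torsion key (see [enumerateCandidates()]).
#' @param components data.frame of replacement components.
#' @return the updated topology.
#' @export
setTorsionComponents <- function(topology, key, components) {
  to <- topology@torsions
  inst <- matchTorsionInstances(topology, key)
  if (!length(inst$rows)) stop("no torsion instances match key type ",
                               key$typeQuad)
  keep <- setdiff(seq_len(nrow(to)), inst$rows)
  newRows <- do.call(rbind, lapply(seq_len(nrow(inst$quads)), function(q) {
    qd <- unname(inst$quads[q, ])
    data.frame(i = qd[1], j = qd[2], k = qd[3], l = qd[4],
               vn = components$vn, n = components$n,
               gamma = components$gamma, scee = components$scee,
               scnb = components$scnb, improper = FALSE, calc14 = FALSE)
  }))
  to2 <- rbind(to[keep, , drop = FALSE], newRows)
  moleculeTopology(topology@atoms, topology@bonds, topology@angles,
                   to2[, c("i", "j", "k", "l", "vn", "n", "gamma",
                           "scee", "scnb", "improper")])
}

## Rows of topology@torsions (and distinct quadruples) whose proper type
## quadruple matches key$typeQuad in either reading direction.
matchTorsionInstances <- function(topology, key) {
  to <- topology@torsions
  if (!nrow(to)) return(list(rows = integer(), quads = matrix(0L, 0, 4)))
  ty <- topology@atoms$type
  fwd <- paste(ty[to$i], ty[to$j], ty[to$k], ty[to$l], sep = "-")
  rev <- paste(ty[to$l], ty[to$k], ty[to$j], ty[to$i], sep = "-")
  hit <- which(!to$improper & (fwd == key$typeQuad | rev == key$typeQuad))
  qk <- paste(to$i[hit], to$j[hit], to$k[hit], to$l[hit])
  list(rows = hit,
       quads = unique(as.matrix(to[hit, c("i", "j", "k", "l")])))
}
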