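## Torsion-focused fragmentation: partition significant torsions into
## connected regions, decide whether fragmenting pays off, cleave distal
## acyclic single bonds outside protected functional groups, and cap the
## cut ends with methyl groups.

## Generic parameters used for cap atoms (plausible sp3-carbon/hydrogen
## round numbers; caps never carry fitted torsions).
CAP_PARAMS <- list(
  c = list(type = "c3", element = "C", mass = 12.01, rminHalf = 1.908,
           epsilon = 0.1094, charge = -0.09),
  h = list(type = "hc", element = "H", mass = 1.008, rminHalf = 1.487,
           epsilon = 0.0157, charge = 0.03),
  bondCC = c(kb = 300, l0 = 1.526), bondCH = c(kb = 340, l0 = 1.09),
  angle = c(ka = 50, theta0 = 109.5),
  torsion = c(vn = 0.16, n = 3, gamma = 0))

DEFAULT_PROTECTED_GROUPS <- c("amide", "ester", "sulfonamide", "nitro",
                              "carboxylate", "guanidinium")

## Bonds protected from cleavage because they belong to a recognizable
## functional group. Patterns are structural rules on the element /
## bond-order graph.
protectedBonds <- function(topology, groups = DEFAULT_PROTECTED_GROUPS) {
  el <- topology@atoms$element
  bd <- topology@bonds
  bkey <- function(a, b) paste(min(a, b), max(a, b))
  prot <- character()
  nbOrders <- function(v) {
    sel <- bd$i == v | bd$j == v
    data.frame(nb = ifelse(bd$i[sel] == v, bd$j[sel], bd$i[sel]),
               order = bd$order[sel])
  }
  for (c0 in which(el == "C")) {
    nb <- nbOrders(c0)
    oDouble <- nb$nb[el[nb$nb] == "O" & nb$order == 2]
    oAll <- nb$nb[el[nb$nb] == "O"]
    nAll <- nb$nb[el[nb$nb] == "N"]
    if ("amide" %in% groups && length(oDouble) && length(nAll))
      prot <- c(prot, bkey(c0, oDouble[1]),
                vapply(nAll, bkey, "", a = c0))
    if ("ester" %in% groups && length(oDouble) &&
        length(setdiff(oAll, oDouble)))
      prot <- c(prot, vapply(oAll, bkey, "", a = c0))
    if ("carboxylate" %in% groups && length(oAll) >= 2)
      prot <- c(prot, vapply(oAll, bkey, "", a = c0))
    if ("guanidinium" %in% groups && length(nAll) >= 3)
      prot <- c(prot, vapply(nAll, bkey, "", a = c0))
  }
  for (s0 in which(el == "S")) {
    nb <- nbOrders(s0)
    if ("sulfonamide" %in% groups &&
        any(el[nb$nb] == "O" & nb$order == 2) && any(el[nb$nb] == "N"))
      prot <- c(prot, vapply(nb$nb, bkey, "", a = s0))
  }
  for (n0 in which(el == "N")) {
    nb <- nbOrders(n0)
    if ("nitro" %in% groups && sum(el[nb$nb] == "O") >= 2)
      prot <- c(prot, vapply(nb$nb[el[nb$nb] == "O"], bkey, "", a = n0))
  }
  unique(prot)
}

#' Partition significant torsions into connected regions
#'
#' Two torsions belong to one region iff their central bonds are connected
#' under shared-atom adjacency (consecutive torsions on the molecular
#' graph).
#'
#' @param topology a [MoleculeTopology-class].
#' @param significant list of torsion keys.
#' @return list of regions, each a list with `torsions` (keys), `atoms`
#'   (union of member quadruples), `bonds` (central bonds, 2-col matrix).
#' @export
partitionRegions <- function(topology, significant) {
  if (!length(significant)) return(list())
  nb <- length(significant)
  bondsM <- t(vapply(significant, function(k) k$bond, integer(2)))
  comp <- seq_len(nb)
  repeat {
    changed <- FALSE
    for (a in seq_len(nb - 1L)) for (b in (a + 1L):nb) {
      if (comp[a] != comp[b] &&
          length(intersect(bondsM[a, ], bondsM[b, ]))) {
        comp[comp == comp[b]] <- comp[a]; changed <- TRUE
      }
    }
    if (!changed || nb == 1L) break
  }
  lapply(unique(comp), function(cc) {
    mem <- which(comp == cc)
    list(torsions = significant[mem],
         atoms = sort(unique(unlist(lapply(significant[mem],
                                           function(k) k$quad)))),
         bonds = bondsM[mem, , drop = FALSE])
  })
}

#' Decide whether to fragment the molecule
#'
#' Fragmentation is worthwhile when at least two distinct torsion regions
#' exist, or when the molecule is large (more than `sizeThreshold` heavy
#' atoms) and at least one region is localized to fewer than half the heavy
#' atoms.
#'
#' @param topology a [MoleculeTopology-class].
#' @param significant list of torsion keys.
#' @param sizeThreshold heavy-atom count above which a large molecule with
#'   a localized region is fragmented (default 35).
#' @return list with `fragment` (logical) and `rationale` (character).
#' @export
decideFragmentation <- function(topology, significant, sizeThreshold = 35) {
  if (!length(significant))
    return(list(fragment = FALSE,
                rationale = "no significant torsions; nothing to fragment"))
  regions <- partitionRegions(topology, significant)
  nHeavy <- sum(topology@atoms$element != "H")
  if (length(regions) >= 2L)
    return(list(fragment = TRUE,
                rationale = sprintf("%d distinct torsion regions",
                                    length(regions))))
  localized <- any(vapply(regions, function(r)
    length(r$atoms) < nHeavy / 2, TRUE))
  if (nHeavy > sizeThreshold && localized)
    return(list(fragment = TRUE,
                rationale = sprintf(
                  "large molecule (%d heavy atoms) with a localized region",
                  nHeavy)))
  list(fragment = FALSE,
       rationale = "single region covering the molecule; no gain")
}

#' Select cleavage bonds for one torsion region
#'
#' A bond is a legal cleavage site when it is an acyclic single bond with
#' neither endpoint in the region's atom set, at least two bonds away from
#' every member torsion's central bond, not part of a protected functional
#' group, and not incident to a ring atom bearing an exocyclic double bond.
#' The selected set is the boundary of the atoms reachable from the region
#' without crossing a legal bond, i.e. the cuts closest to the region. An
#' empty set means the fragment is the whole molecule.
#'
#' @param topology a [MoleculeTopology-class].
#' @param region one region from [partitionRegions()].
#' @param protectedGroups names of functional-group rules to protect.
#' @return data.frame of bonds (`i` inside, `j` outside the fragment).
#' @export
selectCleavageBonds <- function(topology, region,
                                protectedGroups = DEFAULT_PROTECTED_GROUPS) {
  bd <- topology@bonds
  rb <- ringBonds(topology)
  rkey <- paste(rb$i, rb$j)
  prot <- protectedBonds(topology, protectedGroups)
  ra <- ringAtoms(topology)
  g <- topologyGraph(topology)
  D <- igraph::distances(g)
  centralAtoms <- unique(as.integer(region$bonds))
  exoDouble <- unique(unlist(lapply(which(bd$order >= 2), function(r) {
    a <- bd$i[r]; b <- bd$j[r]
    if (paste(min(a, b), max(a, b)) %in% rkey) return(integer())
    c(a, b)[c(a, b) %in% ra]
  })))
  legal <- vapply(seq_len(nrow(bd)), function(r) {
    a <- bd$i[r]; b <- bd$j[r]
    if (paste(min(a, b), max(a, b)) %in% rkey) return(FALSE)
    if (bd$order[r] != 1) return(FALSE)
    if (a %in% region$atoms || b %in% region$atoms) return(FALSE)
    if (min(D[c(a, b), centralAtoms]) < 2) return(FALSE)
    if (paste(min(a, b), max(a, b)) %in% prot) return(FALSE)
    if (a %in% exoDouble || b %in% exoDouble) return(FALSE)
    TRUE
  }, TRUE)
  if (!any(legal))
    return(data.frame(i = integer(), j = integer()))
  ## BFS from the region, not crossing legal bonds
  inside <- region$atoms
  repeat {
    grow <- integer()
    for (r in which(!legal)) {
      a <- bd$i[r]; b <- bd$j[r]
      if (a %in% inside && !(b %in% inside)) grow <- c(grow, b)
      if (b %in% inside && !(a %in% inside)) grow <- c(grow, a)
    }
    if (!length(grow)) break
    inside <- sort(unique(c(inside, grow)))
  }
  cuts <- which(legal & xor(bd$i %in% inside, bd$j %in% inside))
  data.frame(
    i = ifelse(bd$i[cuts] %in% inside, bd$i[cuts], bd$j[cuts]),
    j = ifelse(bd$i[cuts] %in% inside, bd$j[cuts], bd$i[cuts]))
}

#' Build a methyl-capped fragment around a torsion region
#'
#' Severs the cleavage bonds, keeps the connected component containing the
#' region, and replaces each severed neighbor with a methyl cap (one sp3
#' carbon completed with three hydrogens at tetrahedral positions). Mapped
#' atoms inherit all parent parameters; terms touching cap atoms get
#' generic sp3 parameters.
#'
#' @param topology parent [MoleculeTopology-class].
#' @param conformation parent N x 3 coordinates.
#' @param region one region from [partitionRegions()].
#' @param cleavage data.frame from [selectCleavageBonds()].
#' @param fragmentId identifier stored in the atom map.
#' @return a [FragmentSpec-class].
#' @export
buildFragment <- function(topology, conformation, region, cleavage,
                          fragmentId = "frag1") {
  bd <- topology@bonds
  cutKey <- paste(pmin(cleavage$i, cleavage$j), pmax(cleavage$i, cleavage$j))
  keepBond <- !(paste(pmin(bd$i, bd$j), pmax(bd$i, bd$j)) %in% cutKey)
  g <- igraph::make_empty_graph(n = nrow(topology@atoms), directed = FALSE)
  if (any(keepBond))
    g <- igraph::add_edges(g, t(as.matrix(bd[keepBond, c("i", "j")])))
  comp <- igraph::components(g)$membership
  keepAtoms <- sort(which(comp == comp[region$atoms[1]]))
  if (!all(region$atoms %in% keepAtoms))
    stop("fragment construction error: region atoms split across components")

  at <- topology@atoms[keepAtoms, , drop = FALSE]
  coords <- conformation[keepAtoms, , drop = FALSE]
  old2new <- setNames(seq_along(keepAtoms), keepAtoms)
  nm <- function(v) unname(old2new[as.character(v)])

  newAtoms <- at
  newBonds <- {
    b2 <- bd[keepBond & bd$i %in% keepAtoms & bd$j %in% keepAtoms, ,
             drop = FALSE]
    data.frame(i = nm(b2$i), j = nm(b2$j), kb = b2$kb, l0 = b2$l0,
               order = b2$order)
  }
  caps <- integer()
  ## methyl cap per severed bond
  tet <- 109.47 * DEG
  for (r in seq_len(nrow(cleavage))) {
    aP <- cleavage$i[r]; bP <- cleavage$j[r]
    a <- nm(aP)
    u <- conformation[bP, ] - conformation[aP, ]
    u <- u / sqrt(sum(u^2))
    capC <- conformation[aP, ] + CAP_PARAMS$bondCC["l0"] * u
    ## basis perpendicular to u
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- cross3(u, ref); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- cross3(u, e1)
    cIdx <- nrow(newAtoms) + 1L
    newAtoms <- rbind(newAtoms, data.frame(
      name = sprintf("CP%d", r), element = CAP_PARAMS$c$element,
      type = CAP_PARAMS$c$type, charge = CAP_PARAMS$c$charge,
      mass = CAP_PARAMS$c$mass, rminHalf = CAP_PARAMS$c$rminHalf,
      epsilon = CAP_PARAMS$c$epsilon))
    coords <- rbind(coords, capC)
    newBonds <- rbind(newBonds, data.frame(
      i = a, j = cIdx, kb = CAP_PARAMS$bondCC["kb"],
      l0 = CAP_PARAMS$bondCC["l0"], order = 1))
    caps <- c(caps, cIdx)
    for (hh in 1:3) {
      phi <- 2 * pi * (hh - 1) / 3
      dir <- cos(tet) * u +
        sin(tet) * (cos(phi) * e1 + sin(phi) * e2)
      hIdx <- nrow(newAtoms) + 1L
      newAtoms <- rbind(newAtoms, data.frame(
        name = sprintf("HP%d%d", r, hh), element = CAP_PARAMS$h$element,
        type = CAP_PARAMS$h$type, charge = CAP_PARAMS$h$charge,
        mass = CAP_PARAMS$h$mass, rminHalf = CAP_PARAMS$h$rminHalf,
        epsilon = CAP_PARAMS$h$epsilon))
      coords <- rbind(coords, capC + CAP_PARAMS$bondCH["l0"] * dir)
      newBonds <- rbind(newBonds, data.frame(
        i = cIdx, j = hIdx, kb = CAP_PARAMS$bondCH["kb"],
        l0 = CAP_PARAMS$bondCH["l0"], order = 1))
      caps <- c(caps, hIdx)
    }
  }
  rownames(newAtoms) <- NULL
  rownames(coords) <- NULL

  ## angles: copy parent angles fully inside the mapped set, generic for
  ## paths touching caps
  an <- topology@angles
  selA <- an$i %in% keepAtoms & an$j %in% keepAtoms & an$k %in% keepAtoms
  newAngles <- data.frame(i = nm(an$i[selA]), j = nm(an$j[selA]),
                          k = nm(an$k[selA]), ka = an$ka[selA],
                          theta0 = an$theta0[selA])
  to <- topology@torsions
  selT <- to$i %in% keepAtoms & to$j %in% keepAtoms &
    to$k %in% keepAtoms & to$l %in% keepAtoms
  newTors <- data.frame(i = nm(to$i[selT]), j = nm(to$j[selT]),
                        k = nm(to$k[selT]), l = nm(to$l[selT]),
                        vn = to$vn[selT], n = to$n[selT],
                        gamma = to$gamma[selT], scee = to$scee[selT],
                        scnb = to$scnb[selT], improper = to$improper[selT])
  ## enumerate fragment angle/torsion paths touching cap atoms
  tmpTop <- moleculeTopology(newAtoms, newBonds,
                             data.frame(i = integer(), j = integer(),
                                        k = integer(), ka = numeric(),
                                        theta0 = numeric()),
                             NULL)
  nbF <- function(v) neighborsOf(tmpTop, v)
  angKey <- paste(newAngles$i, newAngles$j, newAngles$k)
  for (j in seq_len(nrow(newAtoms))) {
    nbs <- nbF(j)
    if (length(nbs) < 2) next
    for (a in seq_along(nbs)[-length(nbs)]) for (b in (a + 1):length(nbs)) {
      i <- nbs[a]; k <- nbs[b]
      if (!any(c(i, j, k) %in% caps)) next
      if (paste(i, j, k) %in% angKey || paste(k, j, i) %in% angKey) next
      newAngles <- rbind(newAngles, data.frame(
        i = i, j = j, k = k, ka = CAP_PARAMS$angle["ka"],
        theta0 = CAP_PARAMS$angle["theta0"]))
    }
  }
  torKey <- paste(newTors$i, newTors$j, newTors$k, newTors$l)
  for (r in seq_len(nrow(newBonds))) {
    j <- newBonds$i[r]; k <- newBonds$j[r]
    for (i in setdiff(nbF(j), k)) for (l in setdiff(nbF(k), j)) {
      if (i == l) next
      if (!any(c(i, j, k, l) %in% caps)) next
      if (paste(i, j, k, l) %in% torKey ||
          paste(l, k, j, i) %in% torKey) next
      torKey <- c(torKey, paste(i, j, k, l))
      newTors <- rbind(newTors, data.frame(
        i = i, j = j, k = k, l = l, vn = CAP_PARAMS$torsion["vn"],
        n = CAP_PARAMS$torsion["n"], gamma = CAP_PARAMS$torsion["gamma"],
        scee = 1.2, scnb = 2.0, improper = FALSE))
    }
  }
  fragTop <- moleculeTopology(newAtoms, newBonds, newAngles, newTors)
  mapPairs <- cbind(fragment = unname(old2new), parent = keepAtoms)
  new("FragmentSpec", topology = fragTop, conformation = coords,
      map = list(fragmentId = fragmentId, pairs = mapPairs, caps = caps),
      cleaved = cleavage, region = region$torsions)
}

#' Translate a parent torsion key into fragment indexing
#'
#' @param key torsion key with parent atom indices.
#' @param map fragment atom map.
#' @param fragmentTopology the fragment's topology.
#' @return the torsion key re-expressed with fragment atom indices.
#' @export
mapKeyToFragment <- function(key, map, fragmentTopology) {
  lut <- setNames(map$pairs[, 1], map$pairs[, 2])
  quad <- unname(lut[as.character(key$quad)])
  if (anyNA(quad))
    stop("mapping error: torsion atoms absent from fragment ",
         map$fragmentId)
  makeTorsionKey(fragmentTopology, as.integer(quad))
}
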