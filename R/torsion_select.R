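## Candidate torsion enumeration, wrapped dihedral dispersion across the
## centroid set, and pruning down to the significant-torsion list.

#' Canonical torsion key for an atom quadruple
#'
#' The canonical orientation is the type-quadruple reading (forward vs
#' reversed) that is lexicographically smaller; ties broken by the smaller
#' index sequence.
#'
#' @param topology a [MoleculeTopology-class].
#' @param quad four atom indices along a bonded path.
#' @return list with `quad`, `bond` (central bond, sorted), `typeQuad`
#'   (type string `a-b-c-d`), `depth` (backbone-likeness score).
#' @export
makeTorsionKey <- function(topology, quad) {
  ty <- topology@atoms$type
  fwd <- paste(ty[quad], collapse = "-")
  rev <- paste(ty[rev(quad)], collapse = "-")
  if (rev < fwd || (rev == fwd &&
                    paste(rev(quad), collapse = ",") <
                      paste(quad, collapse = ","))) {
    quad <- rev(quad)
    fwd <- rev
  }
  list(quad = as.integer(quad),
       bond = as.integer(c(min(quad[2:3]), max(quad[2:3]))),
       typeQuad = fwd,
       depth = backboneDepth(topology, quad))
}

## Backbone-likeness: min over the two end atoms of the graph distance to
## the nearest terminal heavy atom (larger = deeper in the heavy-atom
## framework).
backboneDepth <- function(topology, quad) {
  term <- terminalHeavyAtoms(topology)
  if (!length(term)) return(Inf)
  g <- topologyGraph(topology)
  D <- igraph::distances(g, v = c(quad[1], quad[4]), to = term)
  min(apply(D, 1, min))
}

#' Enumerate candidate proper torsions
#'
#' One candidate per bonded path i-j-k-l (canonical orientation), excluding
#' improper terms and three-membered wrap-arounds (i = l).
#'
#' @param topology a [MoleculeTopology-class].
#' @return list of torsion keys, each a list with `quad`, `bond`,
#'   `typeQuad`, `depth`.
#' @export
enumerateCandidates <- function(topology) {
  out <- list()
  seen <- character()
  bd <- topology@bonds
  for (r in seq_len(nrow(bd))) {
    j <- bd$i[r]; k <- bd$j[r]
    for (i in setdiff(neighborsOf(topology, j), k)) {
      for (l in setdiff(neighborsOf(topology, k), j)) {
        if (i == l) next
        key <- makeTorsionKey(topology, c(i, j, k, l))
        id <- paste(key$quad, collapse = ",")
        if (id %in% seen) next
        seen <- c(seen, id)
        out[[length(out) + 1L]] <- key
      }
    }
  }
  out
}

#' Wrapped dihedral dispersion of a torsion across centroids
#'
#' Maximum over centroid pairs of the wrapped angular difference
#' d(a, b) = |((a - b + 180) mod 360) - 180|. A single centroid has
#' dispersion 0.
#'
#' @param centroids a [CentroidSet-class] (or a numeric vector of dihedral
#'   angles in degrees, for direct use).
#' @param key a torsion key (ignored when `centroids` is numeric).
#' @return dispersion in degrees.
#' @export
wrappedDispersion <- function(centroids, key = NULL) {
  ang <- if (is.numeric(centroids)) centroids
  else vapply(centroids@conformations, dihedralAngle, 0, quad = key$quad)
  if (length(ang) < 2L) return(0)
  mx <- 0
  for (a in seq_along(ang)[-length(ang)])
    for (b in (a + 1):length(ang))
      mx <- max(mx, angleDiff(ang[a], ang[b]))
  mx
}

#' Longest simple path on the heavy-atom subgraph
#'
#' Exhaustive depth-first search for a longest simple path; ties are broken
#' by the lexicographically smallest atom-index sequence (a path and its
#' reverse count once, keeping the smaller reading).
#'
#' @param topology a [MoleculeTopology-class].
#' @return integer vector of atom indices along the chain.
#' @export
longestHeavyChain <- function(topology) {
  hv <- which(topology@atoms$element != "H")
  if (length(hv) == 1L) return(hv)
  g <- topologyGraph(topology)
  adj <- lapply(seq_len(nrow(topology@atoms)), function(v)
    intersect(neighborsOf(topology, v), hv))
  best <- NULL
  consider <- function(path) {
    rev2 <- rev(path)
    cand <- if (paste(rev2, collapse = ",") < paste(path, collapse = ","))
      rev2 else path
    if (is.null(best) || length(cand) > length(best) ||
        (length(cand) == length(best) &&
         paste(cand, collapse = ",") < paste(best, collapse = ","))) {
      best <<- cand
    }
  }
  dfs <- function(path) {
    consider(path)
    for (nb in adj[[path[length(path)]]]) {
      if (!(nb %in% path)) dfs(c(path, nb))
    }
  }
  for (v in hv) dfs(v)
  as.integer(best)
}

#' Prune candidate torsions to the significant list
#'
#' Keeps candidates whose dispersion strictly exceeds `cutoff`, then
#' (optionally) drops torsions whose end atoms are terminal (hydrogens or
#' heavy atoms with a single heavy neighbor), drops torsions contained in
#' rings (all four atoms ring members, or the central bond itself a ring
#' bond — a ring bond is never rotatable), and finally keeps one torsion
#' per central bond: the
#' highest backbone depth, ties to the lower canonical key.
#'
#' @param topology a [MoleculeTopology-class].
#' @param candidates list of torsion keys from [enumerateCandidates()].
#' @param dispersions numeric vector of dispersions (degrees), parallel to
#'   `candidates`.
#' @param cutoff dispersion cutoff in degrees (default 30; strict
#'   inequality).
#' @param excludeTerminal drop terminal-atom torsions (default TRUE).
#' @param excludeRing drop all-ring torsions (default TRUE).
#' @return list of surviving torsion keys (possibly empty).
#' @export
pruneTorsions <- function(topology, candidates, dispersions, cutoff = 30,
                          excludeTerminal = TRUE, excludeRing = TRUE) {
  stopifnot(length(candidates) == length(dispersions))
  keep <- dispersions > cutoff
  cand <- candidates[keep]
  if (excludeTerminal && length(cand)) {
    el <- topology@atoms$element
    term <- terminalHeavyAtoms(topology)
    isTerm <- function(a) el[a] == "H" || a %in% term
    cand <- Filter(function(k) !isTerm(k$quad[1]) && !isTerm(k$quad[4]),
                   cand)
  }
  if (excludeRing && length(cand)) {
    ra <- ringAtoms(topology)
    rb <- ringBonds(topology)
    rbKey <- paste(rb$i, rb$j)
    cand <- Filter(function(k)
      !all(k$quad %in% ra) &&
        !(paste(k$bond[1], k$bond[2]) %in% rbKey), cand)
  }
  if (!length(cand)) return(list())
  ## per central bond keep the deepest (ties -> lower canonical key)
  bondId <- vapply(cand, function(k) paste(k$bond, collapse = "-"), "")
  out <- list()
  for (b in sort(unique(bondId))) {
    grp <- cand[bondId == b]
    depth <- vapply(grp, function(k) k$depth, 0)
    keyStr <- vapply(grp, function(k)
      paste(k$typeQuad, paste(k$quad, collapse = ",")), "")
    ord <- order(-depth, keyStr)
    out[[length(out) + 1L]] <- grp[[ord[1]]]
  }
  out
}

#' Restrict significant torsions to those on the backbone chain
#'
#' @param significant list of torsion keys.
#' @param chain atom path from [longestHeavyChain()].
#' @return the subset whose central bond is an edge of the chain.
#' @export
backboneConnected <- function(significant, chain) {
  if (length(chain) < 2L) return(list())
  edges <- paste(pmin(chain[-length(chain)], chain[-1]),
                 pmax(chain[-length(chain)], chain[-1]))
  Filter(function(k) paste(k$bond[1], k$bond[2]) %in% edges, significant)
}
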