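## Conformer ensemble generation, minimization, two-feature Ward clustering
## and centroid filtering.

BOLTZMANN_KCAL <- 0.0019872041  # kcal/mol/K

## Evaluate fn() under a local RNG state seeded with `seed`.
withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

## Rotatable bonds: non-ring bonds whose two atoms each have at least one
## further heavy neighbor (rotating a terminal group changes nothing the
## sampler cares about when the group is a single atom).
rotatableBonds <- function(topology) {
  rb <- ringBonds(topology)
  rkey <- paste(rb$i, rb$j)
  bd <- topology@bonds
  out <- list()
  for (r in seq_len(nrow(bd))) {
    i <- bd$i[r]; j <- bd$j[r]
    if (paste(min(i, j), max(i, j)) %in% rkey) next
    if (length(setdiff(neighborsOf(topology, i), j)) == 0) next
    if (length(setdiff(neighborsOf(topology, j), i)) == 0) next
    out[[length(out) + 1L]] <- c(min(i, j), max(i, j))
  }
  out
}

## A representative dihedral quadruple for rotating about bond (j, k).
bondQuad <- function(topology, j, k) {
  i <- setdiff(neighborsOf(topology, j), k)[1]
  l <- setdiff(neighborsOf(topology, k), j)[1]
  c(i, j, k, l)
}

#' Generate a conformer ensemble
#'
#' Backends:
#' * `"torsion"` (default): seeded torsion-space sampling — every rotatable
#'   bond of the molecule is set to a uniformly random dihedral starting
#'   from the supplied 3D geometry. Appropriate for molecules that already
#'   carry a chemically sensible conformation (the workflow's inputs always
#'   do).
#' * `"fixture"`: pass through pre-built geometries supplied via `fixtures`.
#' * a function `(topology, conformation, n) -> list of conformations` for
#'   custom embedding.
#'
#' @param topology a [MoleculeTopology-class].
#' @param conformation N x 3 seed coordinates.
#' @param nConformers number of conformers to generate (default 300).
#' @param seed integer RNG seed.
#' @param backend `"torsion"`, `"fixture"`, or a function (see above).
#' @param fixtures list of conformations for the fixture backend.
#' @return a [ConformerEnsemble-class] (energies NA until minimized).
#' @export
generateConformers <- function(topology, conformation, nConformers = 300,
                               seed = 1, backend = "torsion",
                               fixtures = NULL) {
  confs <- if (is.function(backend)) {
    withSeed(seed, function() backend(topology, conformation, nConformers))
  } else if (identical(backend, "fixture")) {
    if (is.null(fixtures) || !length(fixtures))
      stop("conformer generation error: fixture backend needs geometries")
    fixtures
  } else if (identical(backend, "torsion")) {
    rot <- rotatableBonds(topology)
    withSeed(seed, function() {
      lapply(seq_len(nConformers), function(q) {
        conf <- conformation
        for (b in rot) {
          quad <- bondQuad(topology, b[1], b[2])
          conf <- setDihedral(topology, conf, quad,
                              stats::runif(1, -180, 180))
        }
        conf
      })
    })
  } else stop("unknown conformer backend")
  if (!length(confs)) stop("conformer generation error: no conformations")
  tag <- if (is.function(backend)) "custom" else backend
  new("ConformerEnsemble", conformations = confs,
      energies = rep(NA_real_, length(confs)), backend = tag,
      seed = as.integer(seed))
}

#' Minimize every conformer of an ensemble
#'
#' Backends: `"mm"` (the internal AMBER engine, default), `"fixture"`
#' (energies supplied in `energies`, geometries untouched), or a function
#' `(topology, conformation) -> list(conformation, energy)`. Conformers on
#' which the backend fails are dropped with a warning; the surviving
#' ordering is preserved.
#'
#' @param topology a [MoleculeTopology-class].
#' @param ensemble a [ConformerEnsemble-class].
#' @param backend see above.
#' @param energies energies for the fixture backend (kcal/mol).
#' @param convergence max-gradient convergence for the MM backend.
#' @return a minimized [ConformerEnsemble-class].
#' @export
minimizeEnsemble <- function(topology, ensemble, backend = "mm",
                             energies = NULL, convergence = 1e-4) {
  confs <- ensemble@conformations
  doOne <- if (is.function(backend)) backend
  else if (identical(backend, "mm")) {
    function(top, conf) {
      r <- restrainedMinimize(top, conf, convergence = convergence)
      list(conformation = r$conformation,
           energy = unname(r$energy["total"]))
    }
  } else if (identical(backend, "fixture")) {
    if (is.null(energies) || length(energies) != length(confs))
      stop("fixture minimizer needs one energy per conformer")
    local({
      tab <- energies
      k <- 0L
      function(top, conf) {
        k <<- k + 1L
        list(conformation = conf, energy = tab[k])
      }
    })
  } else stop("unknown minimizer backend")
  outC <- list(); outE <- numeric(); kept <- integer()
  for (q in seq_along(confs)) {
    res <- tryCatch(doOne(topology, confs[[q]]), error = function(e) NULL)
    if (is.null(res)) {
      warning(sprintf("minimizer failed on conformer %d; dropped", q))
      next
    }
    outC[[length(outC) + 1L]] <- res$conformation
    outE <- c(outE, res$energy)
    kept <- c(kept, q)
  }
  if (!length(outC)) stop("all conformers failed to minimize")
  ens <- new("ConformerEnsemble", conformations = outC, energies = outE,
             backend = if (is.function(backend)) "custom" else backend,
             seed = ensemble@seed)
  attr(ens@conformations, "kept") <- kept
  ens
}

#' Cluster a minimized ensemble and pick centroids
#'
#' Each conformer is represented by the two-feature vector (heavy-atom RMSD
#' to the lowest-energy conformer after optimal superposition, relative
#' energy). Both feature columns are L2-normalized and the normalized
#' vectors clustered by Ward hierarchical clustering on Euclidean
#' distances. The dendrogram is cut at `cutFraction` of the maximum merge
#' height (at most `maxClusters` clusters); each cluster's lowest-energy
#' member becomes its centroid. An all-zero feature column is left as zeros
#' so clustering degrades gracefully to the other feature.
#'
#' @param topology a [MoleculeTopology-class].
#' @param ensemble a minimized [ConformerEnsemble-class].
#' @param cutFraction cophenetic-distance fraction of the maximum merge
#'   height at which the dendrogram is cut (default 0.25).
#' @param maxClusters upper bound on the number of clusters (default 10).
#' @param temperature temperature for the Boltzmann weights, K.
#' @return a [CentroidSet-class] (pre energy-window filtering).
#' @export
clusterCentroids <- function(topology, ensemble, cutFraction = 0.25,
                             maxClusters = 10, temperature = 298) {
  confs <- ensemble@conformations
  en <- ensemble@energies
  K <- length(confs)
  ref <- confs[[which.min(en)]]
  rmsd <- vapply(confs, function(c3) heavyAtomRMSD(topology, c3, ref), 0)
  dE <- en - min(en)
  l2 <- function(v) { n <- sqrt(sum(v^2)); if (n > 0) v / n else v }
  feat <- cbind(l2(rmsd), l2(dE))
  cl <- if (K == 1L) 1L else {
    hc <- stats::hclust(stats::dist(feat), method = "ward.D2")
    h <- cutFraction * max(hc$height)
    memb <- stats::cutree(hc, h = h)
    if (max(memb) > min(K, maxClusters))
      memb <- stats::cutree(hc, k = min(K, maxClusters))
    memb
  }
  cid <- sort(unique(cl))
  pick <- vapply(cid, function(cc) {
    mem <- which(cl == cc)
    mem[which.min(en[mem])]
  }, 0L)
  ord <- pick[order(en[pick])]
  dEk <- en[ord] - min(en[ord])
  out <- new("CentroidSet", conformations = confs[ord], deltaE = dEk,
             weights = boltzmannWeights(dEk, temperature),
             ids = as.integer(ord))
  attr(out, "membership") <- cl
  out
}

#' Filter centroids by relative-energy window
#'
#' Retains centroids with `deltaE <= window` (boundary inclusive); the
#' lowest-energy centroid is always retained. Weights are recomputed over
#' the survivors. Idempotent.
#'
#' @param centroids a [CentroidSet-class].
#' @param window energy window, kcal/mol (default 3.5).
#' @param temperature temperature for reweighting, K.
#' @return the filtered [CentroidSet-class].
#' @export
filterByEnergyWindow <- function(centroids, window = 3.5,
                                 temperature = 298) {
  stopifnot(window > 0)
  keep <- centroids@deltaE <= window
  keep[which.min(centroids@deltaE)] <- TRUE
  dEk <- centroids@deltaE[keep]
  new("CentroidSet", conformations = centroids@conformations[keep],
      deltaE = dEk - min(dEk),
      weights = boltzmannWeights(dEk - min(dEk), temperature),
      ids = centroids@ids[keep])
}

#' Boltzmann weights from relative energies
#'
#' w_k proportional to exp(-deltaE_k / (kB T)) with
#' kB = 0.0019872041 kcal/mol/K, normalized to sum 1.
#'
#' @param deltaE relative energies, kcal/mol.
#' @param temperature temperature, K (default 298).
#' @return numeric weights summing to 1.
#' @export
boltzmannWeights <- function(deltaE, temperature = 298) {
  stopifnot(temperature > 0)
  w <- exp(-(deltaE - min(deltaE)) / (BOLTZMANN_KCAL * temperature))
  w / sum(w)
}
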