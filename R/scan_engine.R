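## Restrained 360-degree torsional scans on a uniform grid, profile
## smoothness scoring, and best-profile selection across centroids.

#' Uniform dihedral scan grid
#'
#' @param spacing grid spacing in degrees; must divide 360 (default 20,
#'   giving 18 points over a full rotation).
#' @return a [ScanGrid-class] with angles in (-180, 180].
#' @export
makeGrid <- function(spacing = 20) {
  if (spacing <= 0 || 360 %% spacing != 0)
    stop("config error: grid spacing must divide 360")
  n <- 360 / spacing
  new("ScanGrid", spacing = spacing,
      angles = wrapAngle(seq(-180 + spacing, 180, by = spacing)))
}

## Scan backends map (topology, conformation, quad, target) to a
## restrained-minimized point. `energy` must be the plain MM energy at the
## restrained geometry (no restraint term).
scanBackendMM <- function(k = 500, tolerance = 0.5, convergence = 1e-3) {
  structure(list(
    tag = "internal-mm",
    point = function(topology, conformation, quad, target) {
      conf <- setDihedral(topology, conformation, quad, target)
      res <- suppressWarnings(restrainedMinimize(
        topology, conf,
        list(dihedralRestraint(quad, target, k = k, tolerance = tolerance)),
        convergence = convergence))
      list(conformation = res$conformation,
           energy = unname(totalEnergy(topology, res$conformation)["total"]),
           ok = res$converged ||
             angleDiff(dihedralAngle(res$conformation, quad), target) <=
               tolerance + 2)
    }), class = "ScanBackend")
}

## Closed-form Fourier oracle backend: E(theta) = sum Vn/2 (1+cos(n t - g)).
scanBackendSynthetic <- function(components) {
  structure(list(
    tag = "synthetic-oracle",
    point = function(topology, conformation, quad, target) {
      conf <- setDihedral(topology, conformation, quad, target)
      th <- target * DEG
      e <- sum(components$vn / 2 *
                 (1 + cos(components$n * th - components$gamma * DEG)))
      list(conformation = conf, energy = e, ok = TRUE)
    }), class = "ScanBackend")
}

#' Run a restrained torsional scan
#'
#' Visits the grid sequentially around the circle starting from the point
#' nearest the starting dihedral, seeding each point with the previous
#' point's geometry (standard torsion-drive practice; reduces the
#' discontinuities the smoothness score exists to catch). Energies are
#' shifted so the profile minimum is zero. A point whose backend fails is
#' linearly interpolated from its circular neighbors and the profile is
#' marked degraded.
#'
#' @param backend a scan backend (see [scanBackends()]).
#' @param topology a [MoleculeTopology-class].
#' @param conformation starting N x 3 coordinates.
#' @param key torsion key to scan.
#' @param grid a [ScanGrid-class].
#' @param centroid originating centroid id (bookkeeping).
#' @return a [ScanProfile-class].
#' @export
runScan <- function(backend, topology, conformation, key,
                    grid = makeGrid(), centroid = NA_integer_) {
  ang <- grid@angles
  start <- which.min(angleDiff(ang, dihedralAngle(conformation, key$quad)))
  order <- c(start:length(ang), seq_len(start - 1L))
  energies <- rep(NA_real_, length(ang))
  geoms <- vector("list", length(ang))
  failed <- logical(length(ang))
  conf <- conformation
  for (p in order) {
    res <- tryCatch(backend$point(topology, conf, key$quad, ang[p]),
                    error = function(e) NULL)
    if (is.null(res) || !isTRUE(res$ok)) {
      failed[p] <- TRUE
      if (!is.null(res)) conf <- res$conformation
      next
    }
    conf <- res$conformation
    energies[p] <- res$energy
    geoms[[p]] <- res$conformation
  }
  if (all(failed)) stop("scan failed at every grid point")
  if (any(failed)) {
    n <- length(ang)
    for (p in which(failed)) {
      lo <- p; hi <- p
      while (failed[(lo - 2L) %% n + 1L]) lo <- lo - 1L
      while (failed[hi %% n + 1L]) hi <- hi + 1L
      a <- (lo - 2L) %% n + 1L; b <- hi %% n + 1L
      w <- (p - lo + 1) / (hi - lo + 2)
      energies[p] <- (1 - w) * energies[a] + w * energies[b]
      geoms[[p]] <- geoms[[a]]
    }
  }
  new("ScanProfile", key = key, grid = grid,
      energies = energies - min(energies), geometries = geoms,
      backend = backend$tag, centroid = as.integer(centroid),
      degraded = any(failed))
}

#' Scan backends
#'
#' Constructors for the pluggable scan backends:
#' `scanBackendMM()` performs restrained minimization with the internal
#' AMBER engine (restraint force constant `k` kcal/mol/rad^2, flat-bottom
#' `tolerance` degrees); `scanBackendSynthetic(components)` returns
#' closed-form Fourier energies (a reference oracle for tests);
#' `mockQmBackend()` (see [syntheticFixtures()]) scans a perturbed-torsion
#' copy of the topology.
#'
#' @param k restraint force constant, kcal/mol/rad^2.
#' @param tolerance flat-bottom half width, degrees.
#' @param convergence minimizer convergence, kcal/mol/A.
#' @param components data.frame with vn, n, gamma for the synthetic oracle.
#' @return a ScanBackend object.
#' @name scanBackends
#' @aliases scanBackendMM scanBackendSynthetic
#' @export scanBackendMM scanBackendSynthetic
NULL

#' Smoothness score of a scan profile
#'
#' Composite of (i) the RMS residual of a linear least-squares fit of the
#' profile to a low-order Fourier basis (order `fourierOrder`), (ii) the
#' largest absolute jump of that residual between circularly consecutive
#' points, and (iii) the RMS circular second difference of the residual.
#' A profile fully captured by the basis scores zero; spikes and
#' high-frequency jaggedness are penalized. Lower is smoother. All
#' components scale linearly with the energies.
#'
#' @param profile a [ScanProfile-class].
#' @param fourierOrder basis order (default 4).
#' @param weightJump,weightCurvature composite weights (defaults 0.5, 0.5;
#'   the Fourier residual has weight 1).
#' @return list with `fourierResidual`, `maxJump`, `jaggedness`,
#'   `composite` (kcal/mol).
#' @export
smoothness <- function(profile, fourierOrder = 4, weightJump = 0.5,
                       weightCurvature = 0.5) {
  e <- profile@energies
  th <- profile@grid@angles * DEG
  X <- cbind(1, do.call(cbind, lapply(seq_len(fourierOrder), function(n)
    cbind(cos(n * th), sin(n * th)))))
  fit <- qr.fitted(qr(X), e)
  res <- e - fit
  fr <- sqrt(mean(res^2))
  ## jump and curvature penalties act on the out-of-basis residual, so an
  ## in-basis (genuinely smooth) signal scores zero in every component
  resC <- c(res, res[1])
  mj <- max(abs(diff(resC)))
  second <- res[c(2:length(res), 1)] - 2 * res +
    res[c(length(res), 1:(length(res) - 1))]
  jg <- sqrt(mean(second^2))
  list(fourierResidual = fr, maxJump = mj, jaggedness = jg,
       composite = fr + weightJump * mj + weightCurvature * jg)
}

#' Select the smoothest profile for a torsion
#'
#' Returns the candidate with the lowest composite smoothness score.
#' Degraded profiles lose all ties; remaining ties go to the lowest
#' originating centroid id.
#'
#' @param profiles list of [ScanProfile-class] candidates for one torsion.
#' @param ... passed to [smoothness()].
#' @return the selected [ScanProfile-class].
#' @export
selectBestProfile <- function(profiles, ...) {
  stopifnot(length(profiles) >= 1L)
  score <- vapply(profiles, function(p) smoothness(p, ...)$composite, 0)
  degraded <- vapply(profiles, function(p) isTRUE(p@degraded), TRUE)
  cid <- vapply(profiles, function(p)
    ifelse(is.na(p@centroid), .Machine$integer.max, p@centroid), 0L)
  ord <- order(score, degraded, cid)
  profiles[[ord[1]]]
}
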