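## Least-squares refitting of torsion Fourier components (and optionally
## the 1-4 scaling divisors) against a reference profile. Inner problem:
## bounded quasi-Newton (L-BFGS-B) on frozen scan geometries, warm-started
## from the exact linear least-squares solution in the cos/sin
## parameterization. Outer problem: refresh the scan geometries under the
## updated parameters until the MM profile stops moving.

#' Fitting specification
#'
#' @param mode `"full"` (barrier heights, phases and the torsion type's
#'   scee/scnb) or `"torsion_only"` (barrier heights only; phases and 1-4
#'   scaling bitwise untouched).
#' @param basis periodicities carried by the fit (default 1:4; amplitudes
#'   driven to zero retire a periodicity).
#' @param convergence outer-loop profile-RMSD change threshold, kcal/mol
#'   (default 0.001).
#' @param maxOuter maximum outer geometry-refresh cycles (default 10).
#' @param pruneFloor amplitude floor below which a fitted component is
#'   dropped from the result (default 0.005 kcal/mol).
#' @param stepScale initial step-scale handed to the optimizer's line
#'   search (default 0.05).
#' @param seed seed for the jittered restart taken after an inner-optimizer
#'   failure.
#' @param boundsV,boundsScee,boundsScnb parameter boxes.
#' @return a list of class `FitSpec`.
#' @export
fitSpec <- function(mode = c("full", "torsion_only"), basis = 1:4,
                    convergence = 0.001, maxOuter = 10, pruneFloor = 0.005,
                    stepScale = 0.05, seed = 1L,
                    boundsV = c(0, 20), boundsScee = c(0.5, 3),
                    boundsScnb = c(0.5, 4)) {
  mode <- match.arg(mode)
  structure(list(mode = mode, basis = sort(unique(as.integer(basis))),
                 convergence = convergence, maxOuter = maxOuter,
                 pruneFloor = pruneFloor, stepScale = stepScale,
                 seed = as.integer(seed), boundsV = boundsV,
                 boundsScee = boundsScee, boundsScnb = boundsScnb),
            class = "FitSpec")
}

## Frozen-geometry decomposition of the MM profile for one torsion type:
## E_g = base_g + sum_inst sum_b Vb/2 (1 + cos(b*omega - gamma_b))
##       + C_g/scee + L_g/scnb
profileDecomposition <- function(topology, key, geometries) {
  inst <- matchTorsionInstances(topology, key)
  if (!length(inst$rows)) stop("no torsion instances match ", key$typeQuad)
  at <- topology@atoms
  pairKey <- paste(topology@pairs14$i, topology@pairs14$j)
  owned <- unique(vapply(seq_len(nrow(inst$quads)), function(q)
    paste(min(inst$quads[q, c(1, 4)]), max(inst$quads[q, c(1, 4)])), ""))
  owned <- owned[owned %in% pairKey]
  ownedIJ <- do.call(rbind, lapply(strsplit(owned, " "), as.integer))

  base <- topology
  base@torsions <- topology@torsions[-inst$rows, , drop = FALSE]
  if (length(owned)) {
    nbp <- base@nbPairs
    base@nbPairs <- nbp[!(paste(nbp$i, nbp$j) %in% owned), , drop = FALSE]
  }
  G <- length(geometries)
  baseE <- vapply(geometries, function(g)
    unname(totalEnergy(base, g)["total"]), 0)
  omega <- matrix(0, G, nrow(inst$quads))
  for (g in seq_len(G)) for (q in seq_len(nrow(inst$quads)))
    omega[g, q] <- dihedralAngle(geometries[[g]], inst$quads[q, ]) * DEG
  C14 <- L14 <- numeric(G)
  if (length(owned)) {
    for (g in seq_len(G)) {
      d <- geometries[[g]][ownedIJ[, 2], , drop = FALSE] -
        geometries[[g]][ownedIJ[, 1], , drop = FALSE]
      r <- sqrt(rowSums(d^2))
      rmin <- at$rminHalf[ownedIJ[, 1]] + at$rminHalf[ownedIJ[, 2]]
      eps <- sqrt(at$epsilon[ownedIJ[, 1]] * at$epsilon[ownedIJ[, 2]])
      s6 <- (rmin / r)^6
      L14[g] <- sum(eps * (s6^2 - 2 * s6))
      C14[g] <- sum(COULOMB_CONST * at$charge[ownedIJ[, 1]] *
                      at$charge[ownedIJ[, 2]] / r)
    }
  }
  list(base = baseE, omega = omega, C14 = C14, L14 = L14,
       instances = inst)
}

## MM profile energies from a decomposition and a parameter state.
decompositionEnergies <- function(dec, V, gamma, basis, scee, scnb) {
  G <- length(dec$base)
  tor <- numeric(G)
  gRad <- gamma * DEG
  for (b in seq_along(basis)) {
    tor <- tor + rowSums(V[b] / 2 *
                           (1 + cos(basis[b] * dec$omega - gRad[b])))
  }
  dec$base + tor + dec$C14 / scee + dec$L14 / scnb
}

#' Sum-of-squares fitting objective and its exact gradient
#'
#' Both the MM profile implied by `params` and the reference energies are
#' mean-centered before differencing, which removes the arbitrary energy
#' offset analytically. The gradient is exact (analytic).
#'
#' @param params parameter vector: amplitudes `V` over the basis, then (in
#'   full mode) phases in degrees, scee, scnb.
#' @param dec decomposition from geometries frozen for this inner problem.
#' @param reference reference energies on the grid, kcal/mol.
#' @param basis integer periodicities.
#' @param mode `"full"` or `"torsion_only"`.
#' @param fixed list with `gamma`, `scee`, `scnb` used in torsion_only mode.
#' @return list with `value` and `gradient`.
#' @export
fitObjective <- function(params, dec, reference, basis,
                         mode = "full", fixed = NULL) {
  B <- length(basis)
  if (mode == "full") {
    V <- params[seq_len(B)]
    gamma <- params[B + seq_len(B)]
    scee <- params[2 * B + 1]; scnb <- params[2 * B + 2]
  } else {
    V <- params
    gamma <- fixed$gamma; scee <- fixed$scee; scnb <- fixed$scnb
  }
  Emm <- decompositionEnergies(dec, V, gamma, basis, scee, scnb)
  rC <- (Emm - mean(Emm)) - (reference - mean(reference))
  val <- sum(rC^2)
  gRad <- gamma * DEG
  gV <- vapply(seq_len(B), function(b)
    2 * sum(rC * rowSums(0.5 * (1 + cos(basis[b] * dec$omega - gRad[b])))),
    0)
  if (mode != "full") return(list(value = val, gradient = gV))
  gG <- vapply(seq_len(B), function(b)
    2 * sum(rC * rowSums(V[b] / 2 * sin(basis[b] * dec$omega - gRad[b]))) *
      DEG, 0)
  gS <- 2 * sum(rC * (-dec$C14 / scee^2))
  gN <- 2 * sum(rC * (-dec$L14 / scnb^2))
  list(value = val, gradient = c(gV, gG, gS, gN))
}

#' Closed-form amplitude solution with phases fixed
#'
#' With the geometries and phases frozen, the profile is linear in the
#' amplitudes; this solves the mean-centered normal equations directly
#' (the independent oracle for the optimizer path).
#'
#' @inheritParams fitObjective
#' @param gamma fixed phases, degrees.
#' @param scee,scnb fixed divisors.
#' @return amplitude vector over the basis.
#' @export
linearAmplitudeSolution <- function(dec, reference, basis, gamma,
                                    scee, scnb) {
  G <- length(dec$base)
  X <- vapply(seq_along(basis), function(b)
    rowSums(0.5 * (1 + cos(basis[b] * dec$omega - gamma[b] * DEG))),
    numeric(G))
  X <- as.matrix(X)
  y <- reference - (dec$base + dec$C14 / scee + dec$L14 / scnb)
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  qr.coef(qr(Xc), yc)
}

## cos/sin linear warm start: solve for a_b = V/2 cos g, s_b = V/2 sin g.
cosSinWarmStart <- function(dec, reference, basis, scee, scnb) {
  G <- length(dec$base)
  cols <- list()
  for (b in seq_along(basis)) {
    cols[[2 * b - 1]] <- rowSums(cos(basis[b] * dec$omega)) / 2
    cols[[2 * b]] <- rowSums(sin(basis[b] * dec$omega)) / 2
  }
  X <- do.call(cbind, cols)
  y <- reference - (dec$base + dec$C14 / scee + dec$L14 / scnb)
  co <- qr.coef(qr(sweep(X, 2, colMeans(X))), y - mean(y))
  co[is.na(co)] <- 0
  V <- gamma <- numeric(length(basis))
  for (b in seq_along(basis)) {
    a <- co[2 * b - 1]; s <- co[2 * b]
    V[b] <- 2 * sqrt(a^2 + s^2)
    gamma[b] <- if (V[b] > 0) (atan2(s, a) / DEG) %% 360 else 0
  }
  list(V = V, gamma = gamma)
}

#' Fit one torsion's Fourier components to a reference profile
#'
#' Alternating scheme: the inner problem minimizes the mean-centered
#' sum-of-squares objective on frozen scan geometries with bounded
#' L-BFGS-B (warm-started from the exact cos/sin linear solution in full
#' mode); the outer loop re-relaxes the scan geometries under the updated
#' parameters and repeats until the MM profile moves by less than
#' `spec$convergence` RMSD or `spec$maxOuter` cycles, closing with one
#' frozen-geometry fit on the converged geometries. When the reference
#' profile carries scan geometries they seed the first cycle; otherwise an
#' internal MM scan provides them. With `maxOuter = 1` the fit is a pure
#' frozen-geometry least squares on those starting geometries. If the fit
#' would end worse than it started, the initial parameters are returned
#' with a warning.
#'
#' @param topology a [MoleculeTopology-class].
#' @param key torsion key to fit.
#' @param reference a [ScanProfile-class] on the same grid.
#' @param spec a [fitSpec()].
#' @param conformation starting geometry for the MM scans.
#' @param scanK,scanTol restraint settings for the internal scans.
#' @return list with `result` (a [FitResult-class]) and `topology` (the
#'   updated topology).
#' @export
fitTorsion <- function(topology, key, reference, spec = fitSpec(),
                       conformation, scanK = 500, scanTol = 0.5) {
  grid <- reference@grid
  refE <- reference@energies
  inst0 <- matchTorsionInstances(topology, key)
  init <- topology@torsions[inst0$rows, , drop = FALSE]
  init <- init[init$i == inst0$quads[1, 1] & init$j == inst0$quads[1, 2] &
                 init$k == inst0$quads[1, 3] & init$l == inst0$quads[1, 4], ,
               drop = FALSE]
  basis <- sort(unique(c(spec$basis, init$n)))
  B <- length(basis)
  V0 <- gamma0 <- numeric(B)
  m <- match(init$n, basis)
  V0[m] <- init$vn; gamma0[m] <- init$gamma
  scee0 <- if (nrow(init)) init$scee[1] else 1.2
  scnb0 <- if (nrow(init)) init$scnb[1] else 2.0

  curTop <- topology
  curV <- V0; curGamma <- gamma0; curScee <- scee0; curScnb <- scnb0
  mkComponents <- function(V, gamma, scee, scnb)
    data.frame(vn = V, n = basis, gamma = gamma, scee = scee, scnb = scnb)

  ## frozen starting geometries: reuse the reference profile's own scan
  ## geometries when it carries them, otherwise run an initial MM scan
  geoms <- if (length(reference@geometries) &&
                 !any(vapply(reference@geometries, is.null, TRUE))) {
    reference@geometries
  } else {
    runScan(scanBackendMM(k = scanK, tolerance = scanTol), curTop,
            conformation, key, grid)@geometries
  }
  mmE <- profileRaw(curTop, geoms)
  centered <- function(x) x - mean(x)
  rmse <- function(a, b) sqrt(mean((centered(a) - centered(b))^2))
  rmse0 <- rmse(mmE, refE)

  trace <- numeric()
  converged <- FALSE
  cyc <- 0L
  finalFrozen <- FALSE
  while (cyc < spec$maxOuter || finalFrozen) {
    if (!finalFrozen) cyc <- cyc + 1L
    dec <- profileDecomposition(curTop, key, geoms)
    if (spec$mode == "full") {
      ws <- cosSinWarmStart(dec, refE, basis, curScee, curScnb)
      p0 <- c(pmin(pmax(ws$V, spec$boundsV[1]), spec$boundsV[2]),
              ws$gamma %% 360, curScee, curScnb)
      lower <- c(rep(spec$boundsV[1], B), rep(0, B),
                 spec$boundsScee[1], spec$boundsScnb[1])
      upper <- c(rep(spec$boundsV[2], B), rep(360 - 1e-9, B),
                 spec$boundsScee[2], spec$boundsScnb[2])
      fixed <- NULL
    } else {
      p0 <- curV
      lower <- rep(spec$boundsV[1], B)
      upper <- rep(spec$boundsV[2], B)
      fixed <- list(gamma = curGamma, scee = curScee, scnb = curScnb)
    }
    fn <- function(p) fitObjective(p, dec, refE, basis, spec$mode,
                                   fixed)$value
    gr <- function(p) fitObjective(p, dec, refE, basis, spec$mode,
                                   fixed)$gradient
    runOpt <- function(start) stats::optim(
      start, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = 500, factr = 1e2))
    opt <- tryCatch(runOpt(p0), error = function(e) NULL)
    if (is.null(opt)) {
      jit <- withSeed(spec$seed, function()
        p0 + stats::runif(length(p0), -spec$stepScale, spec$stepScale))
      opt <- tryCatch(runOpt(pmin(pmax(jit, lower), upper)),
                      error = function(e) NULL)
    }
    if (is.null(opt)) {
      warning("inner optimizer failed twice; returning initial parameters")
      comp0 <- mkComponents(V0, gamma0, scee0, scnb0)
      return(list(result = new("FitResult", key = key,
                               components = comp0[comp0$vn >=
                                                    spec$pruneFloor, ,
                                                  drop = FALSE],
                               rmseInitial = rmse0, rmseFinal = rmse0,
                               cycles = cyc, converged = FALSE,
                               trace = trace),
                  topology = topology))
    }
    if (spec$mode == "full") {
      curV <- opt$par[seq_len(B)]
      curGamma <- opt$par[B + seq_len(B)] %% 360
      curScee <- opt$par[2 * B + 1]; curScnb <- opt$par[2 * B + 2]
    } else curV <- opt$par
    curTop <- setTorsionComponents(topology, key,
                                   mkComponents(curV, curGamma, curScee,
                                                curScnb))
    if (finalFrozen || spec$maxOuter == 1L) {
      ## closing frozen-geometry fit: the geometries are (near-)optimal for
      ## these parameters, so evaluate the profile on them directly
      mmE <- decompositionEnergies(dec, curV, curGamma, basis, curScee,
                                   curScnb)
      converged <- converged || spec$maxOuter == 1L
      break
    }
    ## outer refresh: re-relax each scan point under the new parameters
    newGeoms <- geoms
    for (p in seq_along(grid@angles)) {
      r <- suppressWarnings(restrainedMinimize(
        curTop, geoms[[p]],
        list(dihedralRestraint(key$quad, grid@angles[p], k = scanK,
                               tolerance = scanTol)),
        convergence = 1e-3))
      newGeoms[[p]] <- r$conformation
    }
    newE <- profileRaw(curTop, newGeoms)
    change <- sqrt(mean((centered(newE) - centered(mmE))^2))
    trace <- c(trace, change)
    geoms <- newGeoms
    mmE <- newE
    if (change < spec$convergence) { converged <- TRUE; finalFrozen <- TRUE }
  }
  rmseF <- rmse(mmE, refE)
  if (rmseF > rmse0 + 1e-12) {
    warning(sprintf(
      "fit degraded the objective for %s (%.4f -> %.4f); keeping initial parameters",
      key$typeQuad, rmse0, rmseF))
    comp0 <- mkComponents(V0, gamma0, scee0, scnb0)
    return(list(result = new("FitResult", key = key,
                             components = comp0[comp0$vn >= spec$pruneFloor,
                                                , drop = FALSE],
                             rmseInitial = rmse0, rmseFinal = rmse0,
                             cycles = cyc, converged = FALSE, trace = trace),
                topology = topology))
  }
  comp <- mkComponents(curV, curGamma, curScee, curScnb)
  comp <- comp[comp$vn >= spec$pruneFloor, , drop = FALSE]
  list(result = new("FitResult", key = key, components = comp,
                    rmseInitial = rmse0, rmseFinal = rmseF,
                    cycles = cyc, converged = converged, trace = trace),
       topology = curTop)
}

## Plain MM energies of a list of geometries.
profileRaw <- function(topology, geometries) {
  vapply(geometries, function(g)
    unname(totalEnergy(topology, g)["total"]), 0)
}

#' Fit every significant torsion independently
#'
#' Per-torsion fits are executed independently from the same initial
#' topology (results do not depend on execution order); the fitted types
#' are then merged into one updated topology.
#'
#' @param topology initial [MoleculeTopology-class].
#' @param significant list of torsion keys.
#' @param references named list of reference [ScanProfile-class] objects,
#'   one per torsion (names: `typeQuad`).
#' @param spec a [fitSpec()].
#' @param conformation starting geometry for the MM scans.
#' @param ... passed to [fitTorsion()].
#' @return list with `results` (list of [FitResult-class]) and `topology`
#'   (all fits merged).
#' @export
fitAll <- function(topology, significant, references, spec = fitSpec(),
                   conformation, ...) {
  results <- list()
  merged <- topology
  for (key in significant) {
    ref <- references[[key$typeQuad]]
    if (is.null(ref)) stop("no reference profile for ", key$typeQuad)
    fit <- fitTorsion(topology, key, ref, spec, conformation, ...)
    results[[key$typeQuad]] <- fit$result
    merged <- setTorsionComponents(merged, key, fit$result@components)
  }
  list(results = results, topology = merged)
}

#' Boltzmann-averaged atomic charges
#'
#' Per-atom weighted mean over per-centroid charge sets with the centroid
#' Boltzmann weights. All charge sets must carry the same total molecular
#' charge (to 1e-6 e), which the average then preserves.
#'
#' @param chargeSets list of per-atom charge vectors, one per centroid.
#' @param centroids a [CentroidSet-class] (its weights are used), or a
#'   numeric weight vector.
#' @return averaged per-atom charges.
#' @export
boltzmannAverageCharges <- function(chargeSets, centroids) {
  w <- if (is.numeric(centroids)) centroids else centroids@weights
  stopifnot(length(chargeSets) == length(w))
  totals <- vapply(chargeSets, sum, 0)
  if (max(totals) - min(totals) > 1e-6)
    stop("total molecular charge differs across conformer charge sets")
  Reduce(`+`, Map(function(q, wk) q * wk, chargeSets, w))
}
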