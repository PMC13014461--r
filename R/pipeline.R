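## End-to-end orchestration: conformers -> minimization -> clustering ->
## energy window -> torsion selection -> fragmentation decision -> scans
## from all centroids -> smoothest-profile selection -> fitting -> output
## files. Every step persists its artifacts in a numbered subdirectory so
## a run can be inspected and resumed at any step.

#' Pipeline run configuration
#'
#' @param nConformers conformers generated per unit (default 300).
#' @param seed master RNG seed.
#' @param energyWindow centroid energy window, kcal/mol (default 3.5).
#' @param temperature Boltzmann temperature, K (default 298).
#' @param dispersionCutoff significant-torsion dispersion cutoff, degrees
#'   (default 30).
#' @param gridSpacing scan grid spacing, degrees (default 20).
#' @param restraintK scan restraint force constant, kcal/mol/rad^2
#'   (default 500).
#' @param restraintTol restraint flat-bottom half width, degrees
#'   (default 0.5).
#' @param fitMode `"full"` or `"torsion_only"`.
#' @param convergence outer fit convergence, kcal/mol (default 0.001).
#' @param maxOuter maximum outer fit cycles (default 10).
#' @param sizeThreshold fragmentation size threshold, heavy atoms
#'   (default 35).
#' @param cutFraction dendrogram cut fraction (default 0.25).
#' @param maxClusters maximum cluster count (default 10).
#' @param excludeTerminal,excludeRing pruning flags (defaults TRUE).
#' @param referenceBackend `"mm"` (reference = initial force field),
#'   `"mock-qm"` (seeded perturbed-torsion backend), or a ScanBackend.
#' @param mockDeltaV amplitude perturbation half-width of the mock
#'   backend, kcal/mol.
#' @return a named list of class `RunConfig`.
#' @export
runConfig <- function(nConformers = 300, seed = 1, energyWindow = 3.5,
                      temperature = 298, dispersionCutoff = 30,
                      gridSpacing = 20, restraintK = 500,
                      restraintTol = 0.5, fitMode = "full",
                      convergence = 0.001, maxOuter = 10,
                      sizeThreshold = 35, cutFraction = 0.25,
                      maxClusters = 10, excludeTerminal = TRUE,
                      excludeRing = TRUE, referenceBackend = "mm",
                      mockDeltaV = 2) {
  stopifnot(nConformers >= 1, energyWindow > 0, temperature > 0,
            dispersionCutoff >= 0, 360 %% gridSpacing == 0,
            restraintK >= 0, restraintTol >= 0, convergence > 0,
            maxOuter >= 1)
  structure(list(nConformers = nConformers, seed = as.integer(seed),
                 energyWindow = energyWindow, temperature = temperature,
                 dispersionCutoff = dispersionCutoff,
                 gridSpacing = gridSpacing, restraintK = restraintK,
                 restraintTol = restraintTol, fitMode = fitMode,
                 convergence = convergence, maxOuter = maxOuter,
                 sizeThreshold = sizeThreshold, cutFraction = cutFraction,
                 maxClusters = maxClusters,
                 excludeTerminal = excludeTerminal,
                 excludeRing = excludeRing,
                 referenceBackend = referenceBackend,
                 mockDeltaV = mockDeltaV), class = "RunConfig")
}

## ---- artifact helpers ---------------------------------------------------

stepDir <- function(runDir, n, name) {
  d <- file.path(runDir, sprintf("step%02d_%s", n, name))
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

writeConf <- function(conf, path) {
  write.table(format(conf, digits = 17), path, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
}

readConf <- function(path) {
  as.matrix(read.table(path))
}

writeConfList <- function(confs, dir, prefix = "conf") {
  for (q in seq_along(confs))
    writeConf(confs[[q]], file.path(dir, sprintf("%s_%03d.txt", prefix, q)))
}

readConfList <- function(dir, prefix = "conf") {
  files <- sort(list.files(dir, pattern = paste0("^", prefix, "_\\d+\\.txt$"),
                           full.names = TRUE))
  lapply(files, readConf)
}

keyToList <- function(key) {
  list(quad = key$quad, bond = key$bond, typeQuad = key$typeQuad,
       depth = key$depth)
}

listToKey <- function(x) {
  list(quad = as.integer(unlist(x$quad)),
       bond = as.integer(unlist(x$bond)),
       typeQuad = x$typeQuad, depth = as.numeric(x$depth))
}

## ---- pipeline -----------------------------------------------------------

PIPE_STEPS <- c("conformers", "minimize", "centroids", "window", "select",
                "fragment", "scans", "profiles", "fit", "outputs")

#' Run the full reparameterization pipeline
#'
#' Executes all ten workflow steps on one molecule and persists every
#' step's artifacts under `outDir` (numbered subdirectories plus a
#' manifest), enabling step-by-step inspection and [resumePipeline()].
#'
#' @param topology a [MoleculeTopology-class].
#' @param conformation N x 3 starting coordinates.
#' @param config a [runConfig()].
#' @param outDir run directory (created).
#' @return the run report (named list), invisibly written as
#'   `report.json`.
#' @export
runPipeline <- function(topology, conformation, config = runConfig(),
                        outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  inp <- file.path(outDir, "inputs")
  dir.create(inp, showWarnings = FALSE)
  writePrmtop(topology, file.path(inp, "topology.prmtop"))
  writeConf(conformation, file.path(inp, "conformation.txt"))
  yaml::write_yaml(unclass(config), file.path(inp, "config.yaml"))
  pipelineFromStep(outDir, 1L)
}

#' Resume a persisted pipeline run
#'
#' Recomputes from `fromStep` (1-10) using the artifacts persisted by the
#' earlier steps; a fresh resume from step 1 is identical to a fresh run.
#'
#' @param runDir directory of a previous [runPipeline()] run.
#' @param fromStep first step to recompute.
#' @return the updated run report.
#' @export
resumePipeline <- function(runDir, fromStep = 1L) {
  pipelineFromStep(runDir, as.integer(fromStep))
}

pipelineFromStep <- function(runDir, fromStep) {
  inp <- file.path(runDir, "inputs")
  if (!file.exists(file.path(inp, "config.yaml")))
    stop("run directory has no inputs/config.yaml")
  config <- do.call(runConfig, yaml::read_yaml(file.path(inp, "config.yaml")))
  topology <- readTopology(file.path(inp, "topology.prmtop"))
  conformation <- readConf(file.path(inp, "conformation.txt"))
  grid <- makeGrid(config$gridSpacing)
  report <- list(steps = list(), config = unclass(config))
  t0 <- Sys.time()
  mark <- function(step, status, detail = NULL) {
    report$steps[[step]] <<- list(
      status = status, detail = detail,
      elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  need <- function(path, step) {
    if (!file.exists(path))
      stop(sprintf("resume error: artifact %s missing (run step %s first)",
                   path, step))
    path
  }

  ## steps 1-2: conformers + minimization
  d1 <- stepDir(runDir, 1, "conformers")
  d2 <- stepDir(runDir, 2, "minimize")
  if (fromStep <= 1L) {
    ens <- generateConformers(topology, conformation, config$nConformers,
                              config$seed)
    writeConfList(ens@conformations, d1)
    mark("conformers", "ok", length(ens@conformations))
  }
  if (fromStep <= 2L) {
    confs <- readConfList(need(d1, "conformers"))
    ens <- new("ConformerEnsemble", conformations = confs,
               energies = rep(NA_real_, length(confs)), backend = "disk",
               seed = config$seed)
    mins <- suppressWarnings(minimizeEnsemble(topology, ens,
                                              convergence = 1e-3))
    writeConfList(mins@conformations, d2)
    jsonlite::write_json(mins@energies, file.path(d2, "energies.json"),
                         digits = NA)
    mark("minimize", "ok", length(mins@conformations))
  }

  ## step 3: clustering, step 4: energy window
  d3 <- stepDir(runDir, 3, "centroids")
  d4 <- stepDir(runDir, 4, "window")
  if (fromStep <= 3L) {
    confs <- readConfList(need(d2, "minimize"))
    en <- as.numeric(jsonlite::read_json(
      need(file.path(d2, "energies.json"), "minimize"),
      simplifyVector = TRUE))
    mins <- new("ConformerEnsemble", conformations = confs, energies = en,
                backend = "disk", seed = config$seed)
    cen <- clusterCentroids(topology, mins, config$cutFraction,
                            config$maxClusters, config$temperature)
    writeConfList(cen@conformations, d3, "cent")
    jsonlite::write_json(list(deltaE = cen@deltaE, weights = cen@weights,
                              ids = cen@ids),
                         file.path(d3, "centroids.json"), digits = NA)
    mark("centroids", "ok", length(cen@conformations))
  }
  if (fromStep <= 4L) {
    cen <- loadCentroids(need(d3, "centroids"))
    cen <- filterByEnergyWindow(cen, config$energyWindow,
                                config$temperature)
    writeConfList(cen@conformations, d4, "cent")
    jsonlite::write_json(list(deltaE = cen@deltaE, weights = cen@weights,
                              ids = cen@ids),
                         file.path(d4, "centroids.json"), digits = NA)
    mark("window", "ok", length(cen@conformations))
  }

  ## step 5: torsion selection
  d5 <- stepDir(runDir, 5, "select")
  if (fromStep <= 5L) {
    cen <- loadCentroids(need(d4, "window"))
    cand <- enumerateCandidates(topology)
    disp <- vapply(cand, function(k) wrappedDispersion(cen, k), 0)
    sig <- pruneTorsions(topology, cand, disp, config$dispersionCutoff,
                         config$excludeTerminal, config$excludeRing)
    chain <- longestHeavyChain(topology)
    bb <- backboneConnected(sig, chain)
    jsonlite::write_json(list(
      candidates = lapply(cand, keyToList), dispersions = disp,
      significant = lapply(sig, keyToList),
      backbone = lapply(bb, keyToList), chain = chain),
      file.path(d5, "torsions.json"), digits = NA, auto_unbox = TRUE)
    mark("select", "ok", length(sig))
  }

  ## step 6: fragmentation
  d6 <- stepDir(runDir, 6, "fragment")
  if (fromStep <= 6L) {
    sel <- jsonlite::read_json(need(file.path(d5, "torsions.json"),
                                    "select"), simplifyVector = FALSE)
    sig <- lapply(sel$significant, listToKey)
    dec <- decideFragmentation(topology, sig, config$sizeThreshold)
    plan <- list(fragment = dec$fragment, rationale = dec$rationale,
                 fragments = list())
    if (dec$fragment && length(sig)) {
      regions <- partitionRegions(topology, sig)
      for (q in seq_along(regions)) {
        fid <- sprintf("frag%d", q)
        cl <- selectCleavageBonds(topology, regions[[q]])
        fs <- buildFragment(topology, conformation, regions[[q]], cl, fid)
        writePrmtop(fs@topology, file.path(d6, paste0(fid, ".prmtop")))
        writeConf(fs@conformation, file.path(d6, paste0(fid, "_conf.txt")))
        writeMol2(fs@topology, fs@conformation,
                  file.path(d6, paste0(fid, ".mol2")))
        writeAtomMap(fs@map, file.path(d6, paste0(fid, "_map.json")))
        plan$fragments[[q]] <- list(
          id = fid,
          torsions = lapply(fs@region, keyToList),
          cleaved = fs@cleaved)
      }
    }
    jsonlite::write_json(plan, file.path(d6, "plan.json"), digits = NA,
                         auto_unbox = TRUE)
    mark("fragment", "ok", dec$rationale)
  }

  ## scan units: either fragments or the whole molecule
  loadUnits <- function() {
    plan <- jsonlite::read_json(need(file.path(d6, "plan.json"),
                                     "fragment"), simplifyVector = FALSE)
    sel <- jsonlite::read_json(need(file.path(d5, "torsions.json"),
                                    "select"), simplifyVector = FALSE)
    sig <- lapply(sel$significant, listToKey)
    if (isTRUE(plan$fragment) && length(plan$fragments)) {
      lapply(plan$fragments, function(fr) {
        top <- readTopology(file.path(d6, paste0(fr$id, ".prmtop")))
        map <- readAtomMap(file.path(d6, paste0(fr$id, "_map.json")))
        parentKeys <- lapply(fr$torsions, listToKey)
        list(id = fr$id, topology = top,
             conformation = readConf(file.path(d6,
                                               paste0(fr$id, "_conf.txt"))),
             keys = lapply(parentKeys, mapKeyToFragment, map = map,
                           fragmentTopology = top),
             parentKeys = parentKeys, map = map)
      })
    } else if (length(sig)) {
      list(list(id = "ligand", topology = topology,
                conformation = conformation, keys = sig,
                parentKeys = sig, map = NULL))
    } else list()
  }

  ## step 7: scans from every centroid, step 8: best profile per torsion
  d7 <- stepDir(runDir, 7, "scans")
  d8 <- stepDir(runDir, 8, "profiles")
  if (fromStep <= 7L) {
    units <- loadUnits()
    for (u in units) {
      refBackend <- makeReferenceBackend(config, u$topology)
      cen <- if (identical(u$id, "ligand")) loadCentroids(d4) else {
        ens <- generateConformers(u$topology, u$conformation,
                                  max(10, config$nConformers %/% 10),
                                  config$seed + 1L)
        mins <- suppressWarnings(minimizeEnsemble(u$topology, ens,
                                                  convergence = 1e-3))
        filterByEnergyWindow(
          clusterCentroids(u$topology, mins, config$cutFraction,
                           config$maxClusters, config$temperature),
          config$energyWindow, config$temperature)
      }
      for (t in seq_along(u$keys)) {
        key <- u$keys[[t]]
        for (c0 in seq_along(cen@conformations)) {
          prof <- runScan(refBackend, u$topology, cen@conformations[[c0]],
                          key, makeGrid(config$gridSpacing),
                          centroid = cen@ids[c0])
          base <- sprintf("%s_t%02d_c%02d", u$id, t, c0)
          writeProfileTable(prof, file.path(d7, paste0(base, ".dat")))
          gdir <- file.path(d7, paste0(base, "_geom"))
          dir.create(gdir, showWarnings = FALSE)
          writeConfList(prof@geometries, gdir, "p")
        }
      }
    }
    mark("scans", "ok")
  }
  if (fromStep <= 8L) {
    units <- loadUnits()
    for (u in units) {
      for (t in seq_along(u$keys)) {
        files <- list.files(d7, sprintf("^%s_t%02d_c\\d+\\.dat$", u$id, t),
                            full.names = TRUE)
        if (!length(files))
          stop("resume error: no scans for unit ", u$id, " torsion ", t)
        profs <- lapply(files, readProfileTable,
                        grid = makeGrid(config$gridSpacing))
        for (q in seq_along(profs)) profs[[q]]@centroid <- q
        best <- selectBestProfile(profs)
        writeProfileTable(best, file.path(
          d8, sprintf("%s_t%02d_best.dat", u$id, t)))
        ## carry the winning scan's geometries along: they seed the MM
        ## relaxations of the fitting stage
        srcGeom <- sub("\\.dat$", "_geom", files[best@centroid])
        dstGeom <- file.path(d8, sprintf("%s_t%02d_best_geom", u$id, t))
        dir.create(dstGeom, showWarnings = FALSE)
        file.copy(list.files(srcGeom, full.names = TRUE), dstGeom,
                  overwrite = TRUE)
      }
    }
    mark("profiles", "ok")
  }

  ## step 9: fitting
  d9 <- stepDir(runDir, 9, "fit")
  if (fromStep <= 9L) {
    units <- loadUnits()
    fitInfo <- list()
    for (u in units) {
      spec <- fitSpec(mode = config$fitMode,
                      convergence = config$convergence,
                      maxOuter = config$maxOuter, seed = config$seed)
      for (t in seq_along(u$keys)) {
        key <- u$keys[[t]]
        ref <- readProfileTable(
          need(file.path(d8, sprintf("%s_t%02d_best.dat", u$id, t)),
               "profiles"),
          grid = makeGrid(config$gridSpacing))
        gdir <- file.path(d8, sprintf("%s_t%02d_best_geom", u$id, t))
        if (dir.exists(gdir)) ref@geometries <- readConfList(gdir, "p")
        fit <- suppressWarnings(
          fitTorsion(u$topology, key, ref, spec, u$conformation,
                     scanK = config$restraintK,
                     scanTol = config$restraintTol))
        res <- fit$result
        parentKey <- u$parentKeys[[t]]
        item <- list(unit = u$id, typeQuad = res@key$typeQuad,
                     parentTypeQuad = parentKey$typeQuad,
                     parentQuad = parentKey$quad,
                     components = res@components,
                     rmseInitial = res@rmseInitial,
                     rmseFinal = res@rmseFinal, cycles = res@cycles,
                     converged = res@converged)
        fitInfo[[length(fitInfo) + 1L]] <- item
      }
    }
    jsonlite::write_json(fitInfo, file.path(d9, "fits.json"), digits = NA,
                         auto_unbox = TRUE)
    mark("fit", "ok", length(fitInfo))
  }

  ## step 10: outputs
  d10 <- stepDir(runDir, 10, "outputs")
  if (fromStep <= 10L) {
    fitInfo <- jsonlite::read_json(need(file.path(d9, "fits.json"), "fit"),
                                   simplifyVector = FALSE)
    fits <- lapply(fitInfo, function(fi) {
      comp <- as.data.frame(do.call(rbind, lapply(fi$components, function(r)
        data.frame(vn = r$vn, n = as.integer(r$n), gamma = r$gamma,
                   scee = r$scee, scnb = r$scnb))))
      new("FitResult",
          key = list(typeQuad = fi$parentTypeQuad,
                     quad = as.integer(unlist(fi$parentQuad))),
          components = comp, rmseInitial = fi$rmseInitial,
          rmseFinal = fi$rmseFinal, cycles = as.integer(fi$cycles),
          converged = isTRUE(fi$converged), trace = numeric())
    })
    manifest <- character()
    if (length(fits)) {
      writeFrcmod(fits, file.path(d10, "fitted.frcmod"))
      writeParmedScript(fits, file.path(d10, "update.parmed"))
      manifest <- c(manifest, "fitted.frcmod", "update.parmed")
      merged <- topology
      for (fr in fits)
        merged <- setTorsionComponents(merged, fr@key, fr@components)
      writePrmtop(merged, file.path(d10, "fitted.prmtop"))
      manifest <- c(manifest, "fitted.prmtop")
    }
    writeMol2(topology, conformation, file.path(d10, "ligand.mol2"))
    manifest <- c(manifest, "ligand.mol2")
    report$manifest <- manifest
    report$fits <- fitInfo
    mark("outputs", "ok", length(manifest))
  }

  jsonlite::write_json(report, file.path(runDir, "report.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(report)
}

loadCentroids <- function(dir) {
  confs <- readConfList(dir, "cent")
  meta <- jsonlite::read_json(file.path(dir, "centroids.json"),
                              simplifyVector = TRUE)
  new("CentroidSet", conformations = confs,
      deltaE = as.numeric(meta$deltaE), weights = as.numeric(meta$weights),
      ids = as.integer(meta$ids))
}

makeReferenceBackend <- function(config, topology) {
  rb <- config$referenceBackend
  if (inherits(rb, "ScanBackend")) return(rb)
  if (identical(rb, "mm"))
    return(scanBackendMM(k = config$restraintK,
                         tolerance = config$restraintTol))
  if (identical(rb, "mock-qm"))
    return(mockQmBackend(topology, perturbationSeed = config$seed,
                         deltaV = config$mockDeltaV,
                         k = config$restraintK,
                         tolerance = config$restraintTol)$backend)
  stop("unknown reference backend")
}
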