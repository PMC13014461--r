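## Shared scaffolding: a probe rotor with flat nonbonded background, its MM
## scan under prescribed "true" parameters as the reference, and fits run
## from deliberately wrong starting values.

probeWithTruth <- function(vn, n, gamma) {
  fx <- makeFixture("torsion_probe")
  key <- makeTorsionKey(fx$topology, 1:4)
  truthTop <- setTorsionComponents(fx$topology, key,
                                   data.frame(vn = vn, n = n,
                                              gamma = gamma, scee = 1.2,
                                              scnb = 2))
  ref <- runScan(scanBackendMM(), truthTop, fx$conformation, key,
                 makeGrid(20))
  list(fx = fx, key = key, ref = ref, truthTop = truthTop)
}

test_that("objective vanishes with zero gradient at the generating parameters", {
  pw <- probeWithTruth(3, 2, 180)
  dec <- torsionsmith:::profileDecomposition(pw$truthTop, pw$key,
                                             pw$ref@geometries)
  basis <- 1:4
  p <- c(0, 3, 0, 0, 0, 180, 0, 0, 1.2, 2)
  ob <- fitObjective(p, dec, pw$ref@energies, basis, mode = "full")
  expect_lt(ob$value, 1e-12)
  expect_lt(max(abs(ob$gradient)), 1e-5)
  ## adding a constant to the reference leaves the objective unchanged
  ob2 <- fitObjective(p, dec, pw$ref@energies + 7.3, basis, mode = "full")
  expect_equal(ob2$value, ob$value, tolerance = 1e-10)
})

test_that("objective gradient matches central finite differences", {
  pw <- probeWithTruth(2.2, 3, 45)
  dec <- torsionsmith:::profileDecomposition(pw$fx$topology, pw$key,
                                             pw$ref@geometries)
  basis <- 1:4
  p <- c(0.5, 0.8, 1.1, 0.2, 10, 120, 200, 300, 1.3, 2.1)
  g <- fitObjective(p, dec, pw$ref@energies, basis, mode = "full")$gradient
  h <- 1e-6
  fd <- vapply(seq_along(p), function(q) {
    pp <- p; pm <- p
    pp[q] <- pp[q] + h; pm[q] <- pm[q] - h
    (fitObjective(pp, dec, pw$ref@energies, basis, "full")$value -
       fitObjective(pm, dec, pw$ref@energies, basis, "full")$value) / (2 * h)
  }, 0)
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-6)
})

test_that("noiseless single-component targets are recovered for every basis periodicity", {
  gammas <- c(60, 180, 120, 240)
  for (n in 1:4) {
    pw <- probeWithTruth(2.5, n, gammas[n])
    fit <- suppressWarnings(fitTorsion(pw$fx$topology, pw$key, pw$ref,
                                       fitSpec(), pw$fx$conformation))
    comp <- fit$result@components
    hit <- comp[comp$n == n, ]
    expect_equal(nrow(hit), 1L)
    expect_lt(abs(hit$vn - 2.5), 1e-3)
    expect_lt(angleDiff(hit$gamma, gammas[n]), 1)
    expect_lt(fit$result@rmseFinal, 1e-3)
    ## spurious amplitudes on the other periodicities stay negligible
    expect_lt(max(c(0, comp$vn[comp$n != n])), 0.05)
  }
})

test_that("with phases frozen the fit equals the normal-equations solution", {
  pw <- probeWithTruth(1.8, 3, 0)
  dec <- torsionsmith:::profileDecomposition(pw$fx$topology, pw$key,
                                             pw$ref@geometries)
  Vlin <- linearAmplitudeSolution(dec, pw$ref@energies, 3L, gamma = 0,
                                  scee = 1.2, scnb = 2)
  spec <- fitSpec(mode = "torsion_only", basis = 3, maxOuter = 1)
  fit <- suppressWarnings(fitTorsion(pw$fx$topology, pw$key, pw$ref, spec,
                                     pw$fx$conformation))
  expect_lt(abs(fit$result@components$vn - Vlin), 1e-6)
})

test_that("a reference equal to the initial MM profile leaves parameters unchanged", {
  fx <- makeFixture("torsion_probe")
  key <- makeTorsionKey(fx$topology, 1:4)
  ref <- runScan(scanBackendMM(), fx$topology, fx$conformation, key,
                 makeGrid(20))
  fit <- suppressWarnings(fitTorsion(fx$topology, key, ref, fitSpec(),
                                     fx$conformation))
  comp <- fit$result@components
  expect_lt(abs(comp$vn[comp$n == 3] - 1.0), 1e-3)
  expect_identical(fit$result@cycles, 1L)
  expect_lt(fit$result@rmseFinal, 1e-6)
})

test_that("torsion_only mode never touches phases or 1-4 scaling", {
  pw <- probeWithTruth(2.1, 3, 0)
  spec <- fitSpec(mode = "torsion_only", basis = 3)
  fit <- suppressWarnings(fitTorsion(pw$fx$topology, pw$key, pw$ref, spec,
                                     pw$fx$conformation))
  comp <- fit$result@components
  init <- torsions(pw$fx$topology)
  expect_identical(comp$gamma, init$gamma[1])
  expect_identical(comp$scee, init$scee[1])
  expect_identical(comp$scnb, init$scnb[1])
  expect_lt(abs(comp$vn - 2.1), 1e-3)
})

test_that("noisy references are recovered within the Monte-Carlo band", {
  fx <- makeFixture("torsion_probe")
  key <- makeTorsionKey(fx$topology, 1:4)
  sigma <- 0.1
  errs <- vapply(1:8, function(seed) {
    ref <- syntheticReference(data.frame(vn = 3, n = 2, gamma = 180),
                              makeGrid(20), sigma = sigma, seed = seed)
    fit <- suppressWarnings(fitTorsion(fx$topology, key, ref,
                                       fitSpec(seed = seed),
                                       fx$conformation))
    comp <- fit$result@components
    comp$vn[comp$n == 2] - 3
  }, 0)
  ## mean error within a few standard errors of the per-profile noise
  expect_lt(abs(mean(errs)), 4 * sigma / sqrt(18))
  expect_lt(max(abs(errs)), 0.2)
})

test_that("independent per-torsion fits merge order-invariantly", {
  fx <- makeFixture("two_region")
  cand <- enumerateCandidates(fx$topology)
  sig <- pruneTorsions(fx$topology, cand, rep(90, length(cand)))
  ## one torsion per distinct atom-type quadruple (same-type torsions are
  ## legitimately coupled through the shared parameters)
  types <- vapply(sig, function(k) k$typeQuad, "")
  sig <- sig[!duplicated(types)][1:2]
  refs <- list()
  for (k in sig)
    refs[[k$typeQuad]] <- runScan(scanBackendMM(), fx$topology,
                                  fx$conformation, k, makeGrid(30))
  spec <- fitSpec(maxOuter = 1)
  fwd <- suppressWarnings(fitAll(fx$topology, sig, refs, spec,
                                 fx$conformation))
  rev2 <- suppressWarnings(fitAll(fx$topology, rev(sig), refs, spec,
                                  fx$conformation))
  expect_equal(torsions(fwd$topology), torsions(rev2$topology),
               tolerance = 1e-10)
  expect_setequal(names(fwd$results), names(rev2$results))
  expect_error(suppressWarnings(fitAll(fx$topology, sig, list(), spec,
                                       fx$conformation)),
               "no reference profile")
})

test_that("Boltzmann-averaged charges reduce correctly and conserve total charge", {
  ## identical sets come back unchanged
  q <- c(0.2, -0.5, 0.3)
  expect_equal(boltzmannAverageCharges(list(q, q), c(0.4, 0.6)), q)
  ## two sets with equal weights: the arithmetic mean
  expect_equal(boltzmannAverageCharges(list(c(0.1, -0.1), c(0.3, -0.3)),
                                       c(0.5, 0.5)), c(0.2, -0.2))
  ## arbitrary weighted case against a direct-summation oracle
  set.seed(8)
  sets <- lapply(1:4, function(k) { v <- rnorm(6); v - mean(v) + 0.05 })
  w <- boltzmannWeights(c(0, 0.4, 1.1, 2.7))
  avg <- boltzmannAverageCharges(sets, w)
  oracle <- rep(0, 6)
  for (k in 1:4) oracle <- oracle + w[k] * sets[[k]]
  expect_equal(avg, oracle, tolerance = 1e-12)
  expect_equal(sum(avg), 0.05 * 6, tolerance = 1e-6)
  ## mismatched totals are rejected
  bad <- sets
  bad[[2]] <- bad[[2]] + 0.01
  expect_error(boltzmannAverageCharges(bad, w), "total molecular charge")
  ## integrates with CentroidSet weights
  fx <- makeFixture("butane_like")
  cen <- new("CentroidSet",
             conformations = rep(list(fx$conformation), 3),
             deltaE = c(0, 1, 2), weights = boltzmannWeights(c(0, 1, 2)),
             ids = 1:3)
  cs <- makeChargeSets(fx$topology, 3, seed = 4)
  avg2 <- boltzmannAverageCharges(cs, cen)
  expect_equal(sum(avg2), sum(atoms(fx$topology)$charge),
               tolerance = 1e-6)
})
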