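test_that("conformer generation is seeded, deterministic, and backend-pluggable", {
  fx <- makeFixture("butane_like")
  e1 <- generateConformers(fx$topology, fx$conformation, 5, seed = 9)
  e2 <- generateConformers(fx$topology, fx$conformation, 5, seed = 9)
  expect_identical(conformations(e1), conformations(e2))
  e3 <- generateConformers(fx$topology, fx$conformation, 5, seed = 10)
  expect_false(identical(conformations(e1), conformations(e3)))
  ## fixture backend passes geometries through untouched
  pre <- list(fx$conformation, fx$conformation + 0.1)
  ef <- generateConformers(fx$topology, fx$conformation, 99,
                           backend = "fixture", fixtures = pre)
  expect_identical(conformations(ef), pre)
  expect_error(generateConformers(fx$topology, fx$conformation, 5,
                                  backend = "fixture"),
               "fixture backend")
})

test_that("a rigid molecule yields geometrically identical conformers", {
  fx <- makeFixture("rigid_ring")
  ens <- generateConformers(fx$topology, fx$conformation, 4, seed = 2)
  for (q in 2:4)
    expect_lt(heavyAtomRMSD(fx$topology, conformations(ens)[[q]],
                            conformations(ens)[[1]]), 0.1)
})

test_that("minimization lowers (or keeps) every conformer energy and keeps order", {
  fx <- makeFixture("butane_like")
  ens <- generateConformers(fx$topology, fx$conformation, 6, seed = 4)
  before <- vapply(conformations(ens), function(cc)
    unname(totalEnergy(fx$topology, cc)["total"]), 0)
  mins <- suppressWarnings(minimizeEnsemble(fx$topology, ens,
                                            convergence = 1e-3))
  expect_true(all(energies(mins) <= before + 1e-9))
  ## fixture backend returns tabled energies verbatim
  tab <- c(5, 1, 3, 2, 4, 0)
  mf <- minimizeEnsemble(fx$topology, ens, backend = "fixture",
                         energies = tab)
  expect_identical(energies(mf), tab)
  ## a failing conformer is dropped with index bookkeeping
  flaky <- local({
    k <- 0L
    function(top, conf) {
      k <<- k + 1L
      if (k == 2L) stop("backend failure")
      list(conformation = conf, energy = k)
    }
  })
  md <- suppressWarnings(minimizeEnsemble(fx$topology, ens,
                                          backend = flaky))
  expect_length(conformations(md), 5L)
  expect_identical(attr(conformations(md), "kept"), c(1L, 3:6))
})

test_that("clustering groups conformers like the exhaustive Ward oracle", {
  fx <- makeFixture("butane_like")
  quad <- c(2L, 3L, 4L, 5L)
  angs <- c(59, 60, 61, 179, 180, 181)
  confs <- lapply(angs, function(a)
    setDihedral(fx$topology, fx$conformation, quad, a))
  en <- c(0, 0.05, 0.1, 2.0, 2.05, 2.1)
  ens <- new("ConformerEnsemble", conformations = confs, energies = en,
             backend = "fixture", seed = 1L)
  cen <- clusterCentroids(fx$topology, ens)
  memb <- attr(cen, "membership")
  expect_identical(unname(memb[1:3] == memb[1]), rep(TRUE, 3))
  expect_identical(unname(memb[4:6] == memb[4]), rep(TRUE, 3))
  expect_false(memb[1] == memb[4])
  ## exhaustive 2-cluster Ward-criterion oracle on the same features
  ref <- confs[[which.min(en)]]
  rmsd <- vapply(confs, function(cc) heavyAtomRMSD(fx$topology, cc, ref), 0)
  dE <- en - min(en)
  l2 <- function(v) v / sqrt(sum(v^2))
  feat <- cbind(l2(rmsd), l2(dE))
  bestSS <- Inf; bestPart <- NULL
  for (mask in 1:31) {
    g1 <- which(bitwAnd(mask, 2^(0:5)) > 0)
    g2 <- setdiff(1:6, g1)
    ss <- sum(scale(feat[g1, , drop = FALSE], scale = FALSE)^2) +
      sum(scale(feat[g2, , drop = FALSE], scale = FALSE)^2)
    if (ss < bestSS) { bestSS <- ss; bestPart <- g1 }
  }
  part1 <- which(memb == memb[1])
  expect_true(setequal(part1, bestPart) ||
                setequal(part1, setdiff(1:6, bestPart)))
  ## centroids are the lowest-energy members and deltaE starts at 0
  expect_equal(min(deltaE(cen)), 0)
  expect_equal(deltaE(cen), c(0, 2.0), tolerance = 1e-9)
})

test_that("degenerate feature columns degrade gracefully", {
  fx <- makeFixture("butane_like")
  quad <- c(2L, 3L, 4L, 5L)
  confs <- lapply(c(60, 61, 180, 181), function(a)
    setDihedral(fx$topology, fx$conformation, quad, a))
  ## all energies equal: clustering driven purely by the RMSD feature
  ens <- new("ConformerEnsemble", conformations = confs,
             energies = rep(1, 4), backend = "fixture", seed = 1L)
  cen <- clusterCentroids(fx$topology, ens)
  memb <- attr(cen, "membership")
  expect_true(memb[1] == memb[2] && memb[3] == memb[4] &&
                memb[1] != memb[3])
  ## all conformers identical: a single cluster with centroid member 1
  same <- new("ConformerEnsemble",
              conformations = rep(list(fx$conformation), 3),
              energies = c(0.5, 0.5, 0.5), backend = "fixture", seed = 1L)
  cs <- clusterCentroids(fx$topology, same)
  expect_length(conformations(cs), 1L)
  expect_identical(cs@ids, 1L)
})

test_that("the energy window is boundary-inclusive, keeps the minimum, and is idempotent", {
  fx <- makeFixture("butane_like")
  confs <- rep(list(fx$conformation), 4)
  cen <- new("CentroidSet", conformations = confs,
             deltaE = c(0, 1.2, 3.5, 3.6),
             weights = boltzmannWeights(c(0, 1.2, 3.5, 3.6)),
             ids = 1:4)
  kept <- filterByEnergyWindow(cen, 3.5)
  expect_length(conformations(kept), 3L)
  expect_equal(deltaE(kept), c(0, 1.2, 3.5))
  expect_equal(sum(weights(kept)), 1)
  again <- filterByEnergyWindow(kept, 3.5)
  expect_equal(deltaE(again), deltaE(kept))
  ## infinite window keeps everything; single centroid always survives
  expect_length(conformations(filterByEnergyWindow(cen, Inf)), 4L)
  single <- new("CentroidSet", conformations = confs[1], deltaE = 0,
                weights = 1, ids = 1L)
  expect_length(conformations(filterByEnergyWindow(single, 0.1)), 1L)
})

test_that("Boltzmann weights follow the closed form and its limits", {
  expect_equal(boltzmannWeights(c(0, 0, 0)), rep(1 / 3, 3))
  ## direct exponential evaluation oracle at 298 K
  w <- boltzmannWeights(c(0, 0.5924), 298)
  kT <- 0.0019872041 * 298
  expect_equal(w, c(1, exp(-0.5924 / kT)) / (1 + exp(-0.5924 / kT)),
               tolerance = 1e-12)
  expect_equal(round(w, 3), c(0.731, 0.269))
  ## an infinitely unfavourable centroid carries no weight
  expect_equal(boltzmannWeights(c(0, 1e6))[2], 0)
  ## invariance to a constant shift of all energies
  expect_equal(boltzmannWeights(c(0, 1.3, 2.2) + 17),
               boltzmannWeights(c(0, 1.3, 2.2)))
})
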