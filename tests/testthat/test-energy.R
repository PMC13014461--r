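test_that("total energy matches the naive double-loop oracle on seeded fixtures", {
  for (seed in 1:20) {
    fx <- randomFixture(seed)
    e <- totalEnergy(fx$topology, fx$conformation)
    o <- oracleEnergy(fx$topology, fx$conformation)
    expect_lt(max(abs(e[names(o)] - o)), 1e-10)
  }
})

test_that("analytic gradient matches central finite differences", {
  worst <- 0
  for (seed in 1:20) {
    fx <- randomFixture(seed)
    g <- energyGradient(fx$topology, fx$conformation)
    fd <- fdGradient(fx$topology, fx$conformation)
    worst <- max(worst, max(abs(g - fd)) / max(abs(fd)))
    ## net force on an isolated molecule vanishes (relative to the force
    ## scale, which the steeper random fixtures push to ~1e5)
    expect_lt(max(abs(colSums(g))) / max(1, max(abs(g))), 1e-11)
  }
  expect_lt(worst, 1e-6)
})

test_that("single-term limiting cases take their closed-form values", {
  mk <- function(torsions = NULL, charges = c(0, 0), eps = c(0, 0),
                 natom = 2, bonds = data.frame(i = 1, j = 2, kb = 300,
                                               l0 = 1.5)) {
    atoms <- data.frame(name = paste0("C", 1:natom), element = "C",
                        type = "c3", charge = charges, mass = 12,
                        rminHalf = 1.9, epsilon = eps)
    moleculeTopology(atoms, bonds,
                     data.frame(i = integer(), j = integer(),
                                k = integer(), ka = numeric(),
                                theta0 = numeric()), torsions)
  }
  ## bond at equilibrium length
  top <- mk()
  conf <- matrix(c(0, 0, 0, 1.5, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(unname(totalEnergy(top, conf)["bond"]), 0)
  ## isolated LJ pair at its minimum distance: energy -eps_ij
  atoms <- data.frame(name = c("A", "B"), element = "C", type = "c3",
                      charge = 0, mass = 12, rminHalf = 1.9,
                      epsilon = 0.12)
  ljTop <- moleculeTopology(atoms,
                            data.frame(i = integer(), j = integer(),
                                       kb = numeric(), l0 = numeric()),
                            data.frame(i = integer(), j = integer(),
                                       k = integer(), ka = numeric(),
                                       theta0 = numeric()), NULL)
  conf <- matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(unname(totalEnergy(ljTop, conf)["lj"]), -0.12,
               tolerance = 1e-12)
  ## single torsion component at its phase endpoints
  fx <- makeFixture("torsion_probe")
  top <- setTorsionComponents(fx$topology,
                              makeTorsionKey(fx$topology, 1:4),
                              data.frame(vn = 2, n = 1, gamma = 0,
                                         scee = 1.2, scnb = 2))
  c0 <- setDihedral(top, fx$conformation, 1:4, 0)
  c180 <- setDihedral(top, fx$conformation, 1:4, 180)
  expect_equal(unname(totalEnergy(top, c0)["torsion"]), 2, tolerance = 1e-9)
  expect_equal(unname(totalEnergy(top, c180)["torsion"]), 0,
               tolerance = 1e-9)
})

test_that("energy is invariant under rigid translation and rotation", {
  fx <- randomFixture(3)
  e0 <- totalEnergy(fx$topology, fx$conformation)["total"]
  shifted <- sweep(fx$conformation, 2, c(11, -4, 2.5), `+`)
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rotated <- fx$conformation %*% R
  expect_lt(abs(totalEnergy(fx$topology, shifted)["total"] - e0), 1e-9)
  expect_lt(abs(totalEnergy(fx$topology, rotated)["total"] - e0), 1e-9)
  g <- energyGradient(fx$topology, fx$conformation)
  gs <- energyGradient(fx$topology, shifted)
  expect_equal(g, gs, tolerance = 1e-9)
})

test_that("pure-n torsion term is periodic with period 360/n", {
  fx <- makeFixture("torsion_probe")
  for (n in 1:4) {
    top <- setTorsionComponents(fx$topology,
                                makeTorsionKey(fx$topology, 1:4),
                                data.frame(vn = 1.7, n = n, gamma = 35,
                                           scee = 1.2, scnb = 2))
    base <- 20
    e0 <- totalEnergy(top, setDihedral(top, fx$conformation, 1:4,
                                       base))["torsion"]
    for (k in 1:3) {
      ek <- totalEnergy(top, setDihedral(top, fx$conformation, 1:4,
                                         base + k * 360 / n))["torsion"]
      expect_equal(unname(ek), unname(e0), tolerance = 1e-9)
    }
  }
})

test_that("doubling scee exactly halves the 1-4 Coulomb component", {
  fx <- makeFixture("torsion_probe")
  atoms <- fx$topology@atoms
  atoms$charge <- c(0.3, -0.1, -0.1, -0.1)
  atoms$epsilon <- 0
  mk <- function(scee) moleculeTopology(
    atoms, fx$topology@bonds, fx$topology@angles,
    data.frame(i = 1, j = 2, k = 3, l = 4, vn = 1, n = 3, gamma = 0,
               scee = scee, scnb = 2))
  e1 <- totalEnergy(mk(1.2), fx$conformation)["coulomb"]
  e2 <- totalEnergy(mk(2.4), fx$conformation)["coulomb"]
  expect_equal(unname(e2), unname(e1) / 2, tolerance = 1e-12)
})

test_that("restrained minimization honours its contract", {
  fx <- makeFixture("butane_like")
  quad <- c(2L, 3L, 4L, 5L)
  ## pre-minimized input restrained at its own dihedral is a fixed point
  m0 <- restrainedMinimize(fx$topology, fx$conformation)
  cur <- dihedralAngle(m0$conformation, quad)
  m1 <- restrainedMinimize(fx$topology, m0$conformation,
                           list(dihedralRestraint(quad, cur)))
  expect_lt(sqrt(mean((m1$conformation - m0$conformation)^2)), 1e-4)
  expect_true(m1$converged)
  expect_lt(m1$maxGradient, 1e-4)
  ## driving the torsion from 60 to 0 lands within the restraint slack
  c60 <- setDihedral(fx$topology, fx$conformation, quad, 60)
  m2 <- restrainedMinimize(fx$topology, c60,
                           list(dihedralRestraint(quad, 0)))
  expect_lt(angleDiff(dihedralAngle(m2$conformation, quad), 0), 0.5 + 2)
  ## a zero-force-constant restraint is a no-op
  m3 <- restrainedMinimize(fx$topology, c60,
                           list(dihedralRestraint(quad, 0, k = 0)))
  m4 <- restrainedMinimize(fx$topology, c60)
  expect_equal(m3$conformation, m4$conformation, tolerance = 1e-8)
  ## a verified local minimum is stationary
  expect_lt(max(abs(energyGradient(fx$topology, m0$conformation))), 1e-4)
})

test_that("coincident nonbonded atoms raise a singularity error", {
  fx <- makeFixture("butane_like")
  conf <- fx$conformation
  conf[6, ] <- conf[1, ]  # atoms 1 and 6 are five bonds apart (full pair)
  expect_error(totalEnergy(fx$topology, conf), "singularity")
})
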