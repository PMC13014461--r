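test_that("candidate enumeration matches brute-force path counting", {
  fx <- makeFixture("butane_like")
  cand <- enumerateCandidates(fx$topology)
  quads <- vapply(cand, function(k) paste(sort(k$quad[2:3]), collapse = "-"),
                  "")
  expect_length(cand, 3L)
  expect_true(any(vapply(cand, function(k)
    all(sort(k$quad) == 1:4) || all(sort(k$quad) == 2:5) ||
      all(sort(k$quad) == 3:6), TRUE)))
  ## brute-force count on seeded random trees: one candidate per 3-bond path
  for (seed in 1:5) {
    fy <- randomFixture(seed, natom = 7)
    bd <- bonds(fy$topology)
    D <- oracleDistances(7, bd)
    adj <- lapply(1:7, function(v) c(bd$j[bd$i == v], bd$i[bd$j == v]))
    nPaths <- 0
    for (r in seq_len(nrow(bd))) {
      j <- bd$i[r]; k <- bd$j[r]
      for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j))
        if (i != l) nPaths <- nPaths + 1
    }
    expect_length(enumerateCandidates(fy$topology), nPaths)
  }
})

test_that("an ethane-like molecule only offers H-C-C-H candidates", {
  atoms <- rbind(
    data.frame(name = c("C1", "C2"), element = "C", type = "c3",
               charge = -0.3, mass = 12.01, rminHalf = 1.9, epsilon = 0.1),
    data.frame(name = paste0("H", 1:6), element = "H", type = "hc",
               charge = 0.1, mass = 1.008, rminHalf = 1.49,
               epsilon = 0.016))
  bonds <- data.frame(i = c(1, 1, 1, 1, 2, 2, 2),
                      j = c(2, 3, 4, 5, 6, 7, 8),
                      kb = c(300, rep(340, 6)),
                      l0 = c(1.53, rep(1.09, 6)))
  top <- moleculeTopology(atoms, bonds,
                          data.frame(i = integer(), j = integer(),
                                     k = integer(), ka = numeric(),
                                     theta0 = numeric()), NULL)
  cand <- enumerateCandidates(top)
  expect_length(cand, 9L)
  expect_true(all(vapply(cand, function(k) k$typeQuad == "hc-c3-c3-hc",
                         TRUE)))
})

test_that("wrapped dispersion handles the branch cut and matches a pairwise oracle", {
  expect_equal(wrappedDispersion(c(170, -170)), 20)
  expect_equal(wrappedDispersion(c(0, 180)), 180)
  expect_equal(wrappedDispersion(42), 0)
  set.seed(13)
  for (rep in 1:10) {
    ang <- runif(sample(3:8, 1), -180, 180)
    mx <- 0
    for (a in seq_along(ang)) for (b in seq_along(ang)) {
      d <- abs(ang[a] - ang[b])
      mx <- max(mx, min(d, 360 - d))
    }
    expect_equal(wrappedDispersion(ang), mx, tolerance = 1e-12)
  }
})

test_that("longest heavy chain agrees with exhaustive search and tie rules", {
  expect_identical(longestHeavyChain(makeFixture("butane_like")$topology),
                   1:6)
  ## star-shaped molecule: diameter path, deterministic under the tie rule
  atoms <- data.frame(name = paste0("C", 1:5), element = "C", type = "c3",
                      charge = 0, mass = 12, rminHalf = 1.9, epsilon = 0.1)
  bonds <- data.frame(i = c(1, 1, 1, 1), j = 2:5, kb = 300, l0 = 1.5)
  star <- moleculeTopology(atoms, bonds,
                           data.frame(i = integer(), j = integer(),
                                      k = integer(), ka = numeric(),
                                      theta0 = numeric()), NULL)
  expect_identical(longestHeavyChain(star), c(2L, 1L, 3L))
  ## ring-only molecule: longest simple path visits all ring atoms
  ringChain <- longestHeavyChain(makeFixture("rigid_ring")$topology)
  expect_length(ringChain, 6L)
  expect_identical(ringChain[1], 1L)
})

test_that("pruning applies the strict cutoff, terminal, ring and dedup rules", {
  fx <- makeFixture("butane_like")
  cand <- enumerateCandidates(fx$topology)
  central <- which(vapply(cand, function(k) all(k$bond == c(3, 4)), TRUE))
  disp <- rep(0, length(cand))
  ## boundary case: dispersion exactly at the cutoff is excluded
  disp[central] <- 30
  expect_length(pruneTorsions(fx$topology, cand, disp, cutoff = 30), 0L)
  disp[central] <- 30.1
  expect_length(pruneTorsions(fx$topology, cand, disp, cutoff = 30), 1L)
  ## terminal-atom torsions drop unless the flag is disabled
  disp <- rep(50, length(cand))
  sig <- pruneTorsions(fx$topology, cand, disp)
  expect_length(sig, 1L)
  expect_identical(sig[[1]]$bond, c(3L, 4L))
  sigAll <- pruneTorsions(fx$topology, cand, disp, excludeTerminal = FALSE)
  expect_length(sigAll, 3L)  # one per central bond after dedup
  ## ring torsions are excluded regardless of dispersion
  rr <- makeFixture("rigid_ring")
  rc <- enumerateCandidates(rr$topology)
  expect_length(pruneTorsions(rr$topology, rc, rep(179, length(rc))), 0L)
})

test_that("pruning is monotone in the cutoff and order-independent", {
  fx <- makeFixture("two_region")
  cand <- enumerateCandidates(fx$topology)
  set.seed(5)
  disp <- runif(length(cand), 0, 120)
  prev <- Inf
  for (cut in c(10, 30, 60, 90)) {
    n <- length(pruneTorsions(fx$topology, cand, disp, cutoff = cut))
    expect_lte(n, prev)
    prev <- n
  }
  perm <- sample(seq_along(cand))
  a <- pruneTorsions(fx$topology, cand, disp, cutoff = 20)
  b <- pruneTorsions(fx$topology, cand[perm], disp[perm], cutoff = 20)
  expect_identical(lapply(a, `[[`, "quad"), lapply(b, `[[`, "quad"))
  ## every survivor sits on a rotatable central bond: not a ring bond,
  ## both ends non-terminal heavy atoms
  rb <- torsionsmith:::ringBonds(fx$topology)
  term <- torsionsmith:::terminalHeavyAtoms(fx$topology)
  for (k in a) {
    expect_false(any(rb$i == k$bond[1] & rb$j == k$bond[2]))
    expect_false(any(k$bond %in% term))
  }
})

test_that("backbone-connected torsions are exactly those on chain edges", {
  fx <- makeFixture("two_region")
  chain <- longestHeavyChain(fx$topology)
  cand <- enumerateCandidates(fx$topology)
  sig <- pruneTorsions(fx$topology, cand, rep(90, length(cand)))
  bb <- backboneConnected(sig, chain)
  edges <- paste(pmin(chain[-length(chain)], chain[-1]),
                 pmax(chain[-length(chain)], chain[-1]))
  for (k in sig) {
    onChain <- paste(k$bond[1], k$bond[2]) %in% edges
    expect_identical(onChain, any(vapply(bb, function(b)
      identical(b$quad, k$quad), TRUE)))
  }
  expect_length(backboneConnected(sig, chain[1]), 0L)
})
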