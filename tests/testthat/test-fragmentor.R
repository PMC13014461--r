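sigTorsions <- function(fx, disp = 90) {
  cand <- enumerateCandidates(fx$topology)
  pruneTorsions(fx$topology, cand, rep(disp, length(cand)))
}

test_that("torsion regions are connected components under shared-atom adjacency", {
  fx <- makeFixture("two_region")
  sig <- sigTorsions(fx)
  regions <- partitionRegions(fx$topology, sig)
  expect_length(regions, 2L)
  ## adjacent torsions sharing an atom fall in one region
  fb <- makeFixture("butane_like")
  sb <- pruneTorsions(fb$topology, enumerateCandidates(fb$topology),
                      rep(90, 3), excludeTerminal = FALSE)
  expect_length(partitionRegions(fb$topology, sb), 1L)
  ## a single torsion forms a singleton region
  expect_length(partitionRegions(fb$topology, sb[1]), 1L)
  ## every significant torsion lands in exactly one region
  all1 <- unlist(lapply(regions, function(r)
    vapply(r$torsions, function(k) paste(k$quad, collapse = ","), "")))
  expect_identical(sort(all1),
                   sort(vapply(sig, function(k)
                     paste(k$quad, collapse = ","), "")))
  expect_false(anyDuplicated(all1) > 0)
})

test_that("the fragmentation decision follows the region and size rules", {
  fx <- makeFixture("two_region")
  dec <- decideFragmentation(fx$topology, sigTorsions(fx))
  expect_true(dec$fragment)
  ## no significant torsions: nothing to fragment
  dec0 <- decideFragmentation(fx$topology, list())
  expect_false(dec0$fragment)
  ## one region covering most of a small molecule: no gain
  fb <- makeFixture("butane_like")
  decb <- decideFragmentation(fb$topology, sigTorsions(fb))
  expect_false(decb$fragment)
})

test_that("cleavage avoids rings, protected functional groups, and near-region bonds", {
  fx <- makeFixture("amide_chain")
  ## region around the C6-C7 bond torsion (far side of the amide)
  sig <- Filter(function(k) all(k$bond == c(6, 7)),
                pruneTorsions(fx$topology,
                              enumerateCandidates(fx$topology),
                              rep(90, length(enumerateCandidates(fx$topology))),
                              excludeTerminal = FALSE))
  expect_gte(length(sig), 1L)
  region <- partitionRegions(fx$topology, sig[1])[[1]]
  cl <- selectCleavageBonds(fx$topology, region)
  prot <- torsionsmith:::protectedBonds(fx$topology)
  for (r in seq_len(nrow(cl)))
    expect_false(paste(min(cl$i[r], cl$j[r]), max(cl$i[r], cl$j[r])) %in%
                   prot)
  ## amide C-N (4-5) and C=O (4-9) are protected
  expect_true("4 5" %in% prot)
  expect_true("4 9" %in% prot)
  ## ring bonds are never cleavage sites
  ft <- makeFixture("two_region")
  sig2 <- sigTorsions(ft)
  regions <- partitionRegions(ft$topology, sig2)
  rb <- torsionsmith:::ringBonds(ft$topology)
  for (rg in regions) {
    cl2 <- selectCleavageBonds(ft$topology, rg)
    for (r in seq_len(nrow(cl2)))
      expect_false(any(rb$i == min(cl2$i[r], cl2$j[r]) &
                         rb$j == max(cl2$i[r], cl2$j[r])))
  }
})

test_that("fragments are methyl-capped with bijective atom maps", {
  fx <- makeFixture("two_region")
  sig <- sigTorsions(fx)
  regions <- partitionRegions(fx$topology, sig)
  seen <- character()
  for (q in seq_along(regions)) {
    cl <- selectCleavageBonds(fx$topology, regions[[q]])
    fs <- buildFragment(fx$topology, fx$conformation, regions[[q]], cl,
                        sprintf("f%d", q))
    at <- atoms(fs@topology)
    ## caps: exactly one carbon plus three hydrogens per cleaved bond
    expect_length(fs@map$caps, 4L * nrow(cl))
    capEl <- at$element[fs@map$caps]
    expect_equal(sum(capEl == "C"), nrow(cl))
    expect_equal(sum(capEl == "H"), 3L * nrow(cl))
    ## atom map composes to the identity and covers all non-cap atoms
    expect_false(anyDuplicated(fs@map$pairs[, 1]) > 0)
    expect_false(anyDuplicated(fs@map$pairs[, 2]) > 0)
    expect_setequal(c(fs@map$pairs[, 1], fs@map$caps),
                    seq_len(nrow(at)))
    ## mapped atoms inherit parent parameters exactly
    expect_equal(at$charge[fs@map$pairs[, 1]],
                 atoms(fx$topology)$charge[fs@map$pairs[, 2]])
    ## region torsions present via the map
    for (k in regions[[q]]$torsions) {
      fk <- mapKeyToFragment(k, fs@map, fs@topology)
      expect_identical(fk$typeQuad, k$typeQuad)
      seen <- c(seen, paste(k$quad, collapse = ","))
    }
    ## heavy-atom count never exceeds the parent's
    expect_lte(sum(at$element != "H"),
               sum(atoms(fx$topology)$element != "H"))
    ## fragment valences are chemically complete: capped fragment minimizes
    res <- suppressWarnings(restrainedMinimize(fs@topology,
                                               fs@conformation,
                                               convergence = 1e-2))
    expect_true(all(is.finite(res$conformation)))
    ## re-running the fragmentation decision on the fragment is a fixed point
    fkeys <- lapply(regions[[q]]$torsions, mapKeyToFragment, map = fs@map,
                    fragmentTopology = fs@topology)
    expect_false(decideFragmentation(fs@topology, fkeys)$fragment)
  }
  ## every significant torsion appears in exactly one fragment
  expect_setequal(seen, vapply(sig, function(k)
    paste(k$quad, collapse = ","), ""))
  expect_false(anyDuplicated(seen) > 0)
})

test_that("with no legal cleavage the fragment is the whole molecule", {
  fb <- makeFixture("butane_like")
  sig <- sigTorsions(fb)
  region <- partitionRegions(fb$topology, sig)[[1]]
  cl <- selectCleavageBonds(fb$topology, region)
  expect_equal(nrow(cl), 0L)
  fs <- buildFragment(fb$topology, fb$conformation, region, cl, "whole")
  expect_equal(nrow(atoms(fs@topology)), nrow(atoms(fb$topology)))
  expect_length(fs@map$caps, 0L)
  expect_identical(fs@map$pairs[, 1], fs@map$pairs[, 2])
})
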