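test_that("toy landscapes are deterministic given a seed and validate their parameters", {
  m1 <- makeToyLandscape(8, sharpness = 3, seed = 5)
  m2 <- makeToyLandscape(8, sharpness = 3, seed = 5)
  expect_identical(m1@logPssm, m2@logPssm)
  m3 <- makeToyLandscape(8, sharpness = 3, seed = 6)
  expect_false(identical(m1@logPssm, m3@logPssm))
  expect_error(makeToyLandscape(1), "LRef")
  expect_error(makeToyLandscape(8, sharpness = -1), "sharpness")
  expect_error(makeToyLandscape(8, alphabetSubset = "A"), "alphabetSubset")
})

test_that("sharpness limits: flat landscape scores the alphabet size, sharp consensus approaches 1", {
  flat <- makeToyLandscape(10, sharpness = 1e-9, seed = 1)
  s <- randomSeq(10)
  expect_equal(ppValue(pseudoPerplexity(ofsProfiles(flat, s), s)), 20,
               tolerance = 1e-3)
  flat4 <- makeToyLandscape(6, sharpness = 0, seed = 1, alphabetSubset = AB4)
  s4 <- randomSeq(6, AB4)
  expect_equal(ppValue(pseudoPerplexity(ofsProfiles(flat4, s4), s4)), 4,
               tolerance = 1e-3)
  sharp <- makeToyLandscape(10, sharpness = 60, seed = 1)
  cons <- consensusSequence(sharp)
  expect_lt(ppValue(pseudoPerplexity(ofsProfiles(sharp, cons), cons)), 1.01)
})

test_that("length deviations from the reference are penalised", {
  s <- consensusSequence(toySingle)
  ppRef <- ppValue(pseudoPerplexity(ofsProfiles(toySingle, s), s))
  short <- substr(s, 1, nchar(s) - 2)
  ppShort <- ppValue(pseudoPerplexity(ofsProfiles(toySingle, short), short))
  expect_gt(ppShort, ppRef)
})

test_that("endpoint pairs hit the requested divergence and stay under the viability ceiling", {
  cases <- list(list(m = toyCorridor, d = 0.5), list(m = toyCorridor, d = 0.4),
                list(m = toyCorridor3, d = 0.25), list(m = toySingle, d = 0.25))
  for (cs in cases) {
    pr <- sampleEndpointPair(cs$m, divergence = cs$d, seed = 3)
    L <- dim(cs$m@logPssm)[1]
    expect_lte(abs(alignedHamming(pr$source, pr$target) - cs$d * L), 1)
    expect_true(all(pr$pp <= 6))
    pr2 <- sampleEndpointPair(cs$m, divergence = cs$d, seed = 3)
    expect_identical(pr2$source, pr$source)
    expect_identical(pr2$target, pr$target)
  }
  # a mid-blend divergence on a two-family landscape lands in the canyon
  expect_error(sampleEndpointPair(toyCorridor, divergence = 0.25, seed = 3),
               "ceiling")
  expect_error(sampleEndpointPair(toyCorridor, divergence = 0), "divergence")
  # an impossibly sharp two-family blend exceeds the ceiling and says so
  expect_error(sampleEndpointPair(makeToyLandscape(6, sharpness = 40, seed = 2),
                                  divergence = 1, seed = 1, ceiling = 1.1),
               "ceiling")
})

test_that("the enumerable universe has the right node and arc structure", {
  m2 <- makeToyLandscape(3, sharpness = 1, seed = 1,
                         alphabetSubset = c("A", "C"))
  u <- enumerateUniverse(m2, LMax = 3, alphabetSubset = c("A", "C"), LMin = 3)
  expect_length(u$nodes, 8L)
  expect_true(all(igraph::degree(u$graph) == 3))
  uIndel <- enumerateUniverse(m2, LMax = 3, alphabetSubset = c("A", "C"),
                              LMin = 2)
  expect_length(uIndel$nodes, 12L)
  expect_error(enumerateUniverse(m2, LMax = 30, alphabetSubset = AB4,
                                 guard = 1e6),
               "guard")
})

test_that("the bottleneck oracle lower-bounds every explicit path", {
  u <- enumerateUniverse(toyUniverseModel, LMax = 4, alphabetSubset = AB4,
                         LMin = 3)
  pair <- sampleEndpointPair(toyUniverseModel, divergence = 0.5, seed = 2)
  b <- bottleneckOptimum(u, pair$source, pair$target)
  expect_gte(b$value, max(pair$pp) - 1e-12)
  expect_identical(b$path[1], pair$source)
  expect_identical(b$path[length(b$path)], pair$target)
  # the oracle's own witness path attains the optimum
  witness <- vapply(b$path, function(s) u$pp[match(s, u$nodes)], numeric(1))
  expect_equal(max(witness), b$value, tolerance = 1e-12)
  # any random interpolation through the universe can only do worse or equal
  for (s in 1:5) {
    p <- randomInterpolation(pair$source, pair$target, seed = s)
    mx <- max(vapply(unname(as.character(pathSteps(p))), function(x) {
      i <- match(x, u$nodes)
      if (is.na(i)) Inf else u$pp[i]
    }, numeric(1)))
    expect_gte(mx, b$value - 1e-12)
  }
  expect_error(bottleneckOptimum(u, "WWWW", pair$target), "not in")
})

test_that("shipped tier fixtures match their manifest and regenerate bit-identically", {
  dirn <- system.file("extdata", "tiers", package = "protpath")
  man <- jsonlite::read_json(file.path(dirn, "manifest.json"))
  for (nm in names(man$tiers)) {
    t <- man$tiers[[nm]]
    ss <- readProteinFasta(file.path(dirn, paste0(nm, ".fasta")))
    a <- as.character(ss[[1]]); b <- as.character(ss[[2]])
    expect_identical(alignedHamming(a, b), as.integer(t$alignedHamming))
    expect_equal(percentIdentity(a, b), t$percentIdentity, tolerance = 1e-6)
    m <- makeToyLandscape(man$landscape$LRef, sharpness = man$landscape$sharpness,
                          seed = t$seed, nComponents = man$landscape$nComponents,
                          componentDivergence = min(1, t$divergence + 0.06))
    pr <- sampleEndpointPair(m, divergence = t$divergence, seed = t$seed,
                             ceiling = 6)
    expect_identical(pr$source, a)
    expect_identical(pr$target, b)
    expect_equal(unname(pr$pp), as.numeric(unlist(t$pp)), tolerance = 1e-6)
  }
})
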