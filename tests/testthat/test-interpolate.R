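test_that("random interpolation degenerates correctly and is deterministic per seed", {
  p0 <- randomInterpolation("ACDE", "ACDE", seed = 1)
  expect_identical(pathLength(p0), 0L)
  p1 <- randomInterpolation("AC", "GC", seed = 1)
  expect_identical(unname(as.character(pathSteps(p1))), c("AC", "GC"))
  pa <- randomInterpolation("ACDEFGHIKL", "ADDEFYHIKM", seed = 9)
  pb <- randomInterpolation("ACDEFGHIKL", "ADDEFYHIKM", seed = 9)
  expect_identical(as.character(pathSteps(pa)), as.character(pathSteps(pb)))
})

test_that("random-path step count equals the aligned hamming distance (property, incl. indels)", {
  set.seed(2)
  for (rep in 1:60) {
    a <- randomSeq(sample(4:14, 1))
    b <- randomSeq(sample(4:14, 1))
    p <- randomInterpolation(a, b, seed = rep)
    expect_identical(pathLength(p), alignedHamming(a, b))
    steps <- unname(as.character(pathSteps(p)))
    expect_identical(steps[1], a)
    expect_identical(steps[length(steps)], b)
    expect_true(validatePath(p))
  }
})

test_that("exhaustive order enumeration yields n! distinct paths", {
  ps <- enumerateInterpolationOrders("ACDEFG", "AYDEFW")
  expect_length(ps, 2L)  # 2 differing columns -> 2 orders
  ps <- enumerateInterpolationOrders("ACDEFG", "AYDKFW")
  expect_length(ps, 6L)
  keys <- vapply(ps, function(p)
    paste(as.character(pathSteps(p)), collapse = ">"), character(1))
  expect_identical(anyDuplicated(keys), 0L)
  expect_error(enumerateInterpolationOrders("ACDEFGHIKL", "YYYYYYYYYY"),
               "orders")
})

test_that("proposeMoves honours the move mix and proposal distributions", {
  prof <- ofsProfiles(toySingle, "ACDEFGHI")
  expect_identical(nrow(proposeMoves(prof, "ACDEFGHI", 0)), 0L)
  expect_error(proposeMoves(prof, "ACDEFGHI", -1), ">= 0")
  # one-hot substitution rows force the sampled residue
  sub <- matrix(1e-13, 8, 20)
  sub[, match("G", aaAlphabet())] <- 1
  oneG <- protpath:::mkProfiles(sub / rowSums(sub), matrix(1 / 20, 9, 20),
                                "s", "m", "ofs")
  set.seed(1)
  mv <- proposeMoves(oneG, "ACDEFHIK", 50, moveMix = c(1, 0, 0))  # no G in seq
  expect_true(all(mv$kind == "substitution"))
  expect_true(all(mv$residue == "G"))
})

test_that("deletion positions are sampled uniformly (chi-square at alpha 0.01)", {
  prof <- ofsProfiles(toySingle, "ACDEFGHIKL")
  set.seed(1)
  mv <- proposeMoves(prof, "ACDEFGHIKL", 1e4, moveMix = c(0, 0, 1))
  expect_true(all(mv$kind == "deletion"))
  counts <- tabulate(mv$position, nbins = 10)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("beam search returns the zero-step path when source equals target", {
  res <- beamSearchInterpolation(toySingle, "ACDE", "ACDE")
  expect_length(res, 1L)
  expect_identical(pathLength(res[[1]]), 0L)
})

test_that("beam search completes valid paths that end at the target, deterministically", {
  pair <- sampleEndpointPair(toyCorridor3, divergence = 0.25, seed = 3)
  cfg <- beamConfig(beamWidth = 2, poolSize = 30, fitnessSlack = 3, seed = 11)
  res <- beamSearchInterpolation(toyCorridor3, pair$source, pair$target, cfg)
  expect_gt(length(res), 0L)
  for (p in res) {
    expect_true(validatePath(p))
    steps <- unname(as.character(pathSteps(p)))
    expect_identical(steps[1], pair$source)
    expect_identical(steps[length(steps)], pair$target)
  }
  res2 <- beamSearchInterpolation(toyCorridor3, pair$source, pair$target, cfg)
  expect_identical(lapply(res, function(p) as.character(pathSteps(p))),
                   lapply(res2, function(p) as.character(pathSteps(p))))
  d <- attr(res, "diagnostics")
  expect_true(all(c("bestProximity", "stepsRun", "ppCeiling") %in% names(d)))
})

test_that("a hopeless budget yields an empty result with diagnostics, not an error", {
  pair <- sampleEndpointPair(toyCorridor, divergence = 0.5, seed = 3)
  cfg <- beamConfig(beamWidth = 1, poolSize = 2, maxSteps = 2, seed = 1,
                    fitnessSlack = 3)
  res <- beamSearchInterpolation(toyCorridor, pair$source, pair$target, cfg)
  expect_length(res, 0L)
  expect_false(is.null(attr(res, "diagnostics")$bestProximity))
})

test_that("beam intermediates beat the random baseline's median bottleneck on a distance-3 pair", {
  pair <- sampleEndpointPair(toyCorridor3, divergence = 0.25, seed = 3)
  expect_identical(alignedHamming(pair$source, pair$target), 3L)
  res <- beamSearchInterpolation(toyCorridor3, pair$source, pair$target,
                                 beamConfig(beamWidth = 3, poolSize = 50,
                                            fitnessSlack = 3, seed = 7))
  expect_gt(length(res), 0L)
  beamBest <- min(vapply(res, function(p)
    max(tracePath(toyCorridor3, p)$pp), numeric(1)))
  randMax <- vapply(1:100, function(s)
    max(tracePath(toyCorridor3,
                  randomInterpolation(pair$source, pair$target, seed = s))$pp),
    numeric(1))
  expect_lt(beamBest, stats::median(randMax))
})

test_that("ensembles are reproducible and stochastic across seeds", {
  pair <- sampleEndpointPair(toyCorridor3, divergence = 0.25, seed = 3)
  cfg <- beamConfig(beamWidth = 1, poolSize = 30, fitnessSlack = 3, seed = 0)
  e1 <- generateEnsemble(toyCorridor3, pair$source, pair$target, cfg, nPaths = 4)
  e2 <- generateEnsemble(toyCorridor3, pair$source, pair$target, cfg, nPaths = 4)
  expect_identical(lapply(e1$paths, function(p) as.character(pathSteps(p))),
                   lapply(e2$paths, function(p) as.character(pathSteps(p))))
  expect_identical(length(e1$traces), length(e1$paths))
  expect_identical(nrow(e1$log), 4L)
  keys <- vapply(e1$paths, function(p)
    paste(as.character(pathSteps(p)), collapse = ">"), character(1))
  expect_gte(length(unique(keys)), 2L)
})
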