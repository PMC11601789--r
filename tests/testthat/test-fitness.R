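test_that("uniform landscape yields uniform profiles under both estimators", {
  m0 <- makeToyLandscape(6, sharpness = 0, seed = 1)
  s <- "ACDEFG"
  for (prof in list(ofsProfiles(m0, s), maskedMarginalProfiles(m0, s))) {
    expect_equal(dim(substitutionProfile(prof)), c(6L, 20L))
    expect_equal(dim(insertionProfile(prof)), c(7L, 20L))
    expect_true(max(abs(substitutionProfile(prof) - 1 / 20)) < 1e-9)
  }
  expect_equal(ppValue(pseudoPerplexity(ofsProfiles(m0, s), s)), 20,
               tolerance = 1e-9)
})

test_that("single-family toy profiles equal the closed-form PSSM conditionals", {
  # with one component and L = LRef, leave-one-out weights cancel and the
  # conditional at position i is exactly the PSSM row
  s <- consensusSequence(toySingle)
  prof <- ofsProfiles(toySingle, s)
  expected <- exp(toySingle@logPssm[, , 1])
  expect_equal(unname(substitutionProfile(prof)), unname(expected),
               tolerance = 1e-9)
  # insertion rows: centered placement of the PSSM over length L + 1 plus the
  # documented uniform mixing - recomputed here from the documented formula
  L <- nchar(s); LRef <- dim(toySingle@logPssm)[1]
  lam <- 1 - exp(-toySingle@indelPenalty * 1)
  base <- matrix(1 / 20, L + 1, 20)
  o <- ((L + 1) - LRef) %/% 2
  base[o + seq_len(LRef), ] <- exp(toySingle@logPssm[, , 1])
  expected_ins <- (1 - lam) * base + lam / 20
  expect_equal(unname(insertionProfile(prof)), unname(expected_ins),
               tolerance = 1e-9)
})

test_that("OFS readout equals masked-marginal scan on the toy backend (oracle equivalence)", {
  set.seed(3)
  for (m in list(toySingle, toyCorridor)) {
    for (rep in 1:5) {
      s <- randomSeq(sample(5:14, 1))
      po <- ofsProfiles(m, s)
      pm <- maskedMarginalProfiles(m, s)
      expect_lt(max(abs(substitutionProfile(po) - substitutionProfile(pm))), 1e-6)
      expect_lt(max(abs(insertionProfile(po) - insertionProfile(pm))), 1e-6)
      expect_true(all(abs(rowSums(substitutionProfile(po)) - 1) < 1e-6))
      expect_true(all(abs(rowSums(insertionProfile(po)) - 1) < 1e-6))
    }
  }
})

test_that("pseudo-perplexity closed forms: one-hot 1, uniform 20, halves 2", {
  onehot <- function(s) {
    idx <- match(strsplit(s, "")[[1]], aaAlphabet())
    sub <- matrix(1e-13, nchar(s), 20); sub[cbind(seq_len(nchar(s)), idx)] <- 1
    sub <- sub / rowSums(sub)
    ins <- matrix(1 / 20, nchar(s) + 1, 20)
    protpath:::mkProfiles(sub, ins, "s", "m", "ofs")
  }
  expect_equal(ppValue(pseudoPerplexity(onehot("ACDE"), "ACDE")), 1,
               tolerance = 1e-9)
  unif <- protpath:::mkProfiles(matrix(1 / 20, 4, 20), matrix(1 / 20, 5, 20),
                                "s", "m", "ofs")
  expect_equal(ppValue(pseudoPerplexity(unif, "ACDE")), 20, tolerance = 1e-12)
  half <- matrix((1 - 0.5) / 19, 2, 20)
  half[cbind(1:2, match(c("A", "C"), aaAlphabet()))] <- 0.5
  halfprof <- protpath:::mkProfiles(half, matrix(1 / 20, 3, 20), "s", "m", "ofs")
  expect_equal(ppValue(pseudoPerplexity(halfprof, "AC")), 2, tolerance = 1e-12)
  expect_error(pseudoPerplexity(halfprof, "ACD"), "length")
})

test_that("pseudo-perplexity is always >= 1 and zero probabilities are clamped", {
  set.seed(8)
  for (rep in 1:20) {
    L <- sample(2:12, 1)
    prof <- randomProfiles(L, seed = rep)
    s <- randomSeq(L)
    expect_gte(ppValue(pseudoPerplexity(prof, s)), 1)
  }
  z <- matrix(1 / 19, 1, 20)
  z[1, match("A", aaAlphabet())] <- 0
  zprof <- protpath:::mkProfiles(z, matrix(1 / 20, 2, 20), "s", "m", "ofs")
  expect_warning(sc <- pseudoPerplexity(zprof, "A"), "clamped")
  expect_identical(sc@nClamped, 1L)
  expect_equal(ppValue(sc), 1e12, tolerance = 1e-6)
})

test_that("segment scoring uses full-sequence profiles and obeys the geometric-mean identity", {
  s <- consensusSequence(toyCorridor)
  prof <- ofsProfiles(toyCorridor, s)
  whole <- pseudoPerplexity(prof, s)
  expect_equal(ppValue(segmentPseudoPerplexity(prof, s, c(1, nchar(s)))),
               ppValue(whole), tolerance = 1e-12)
  expect_equal(ppValue(segmentPseudoPerplexity(prof, s,
                                               IRanges::IRanges(3, 7))),
               exp(mean(perPositionNLL(whole)[3:7])), tolerance = 1e-12)
  expect_error(segmentPseudoPerplexity(prof, s, c(5, 99)), "out of range")
  expect_error(segmentPseudoPerplexity(prof, s, c(7, 3)), "out of range")
  # geometric-mean identity on random profiles, to 1e-9
  set.seed(5)
  for (rep in 1:20) {
    L <- sample(4:16, 1)
    rp <- randomProfiles(L, seed = 100 + rep)
    sq <- randomSeq(L)
    cut <- sample(seq_len(L - 1), 1)
    ppA <- ppValue(segmentPseudoPerplexity(rp, sq, c(1, cut)))
    ppB <- ppValue(segmentPseudoPerplexity(rp, sq, c(cut + 1, L)))
    ppF <- ppValue(pseudoPerplexity(rp, sq))
    expect_equal(ppF, (ppA^cut * ppB^(L - cut))^(1 / L), tolerance = 1e-9)
  }
})

test_that("substituting the argmax residue never increases its position's NLL", {
  set.seed(17)
  for (rep in 1:15) {
    s <- randomSeq(sample(4:10, 1))
    prof <- ofsProfiles(toyCorridor, s)
    i <- sample(nchar(s), 1)
    row <- substitutionProfile(prof)[i, ]
    best <- aaAlphabet()[which.max(row)]
    s2 <- applyEdit(s, if (best == substr(s, i, i))
      newEdit("substitution", i, best) else newEdit("substitution", i, best))
    nllOld <- perPositionNLL(pseudoPerplexity(prof, s))[i]
    expect_lte(-log(max(row)), nllOld + 1e-12)
  }
})

test_that("residue embeddings are deterministic one-hot + relative position", {
  e <- residueEmbeddings(toySingle, "ACDAC")
  expect_equal(dim(e), c(5L, 21L))
  expect_equal(unname(e[1, match("A", aaAlphabet())]), 1)
  expect_equal(sum(e[, 1:20]), 5)
  expect_equal(e[, 21], (1:5) / 5)
  expect_identical(e, residueEmbeddings(toySingle, "ACDAC"))
  # permuting the sequence changes the positional channel pairing
  e2 <- residueEmbeddings(toySingle, "CACDA")
  expect_false(identical(e[, 1:20], e2[, 1:20]))
})

test_that("profiles serialize to TSV with 20 probability columns", {
  prof <- ofsProfiles(toySingle, "ACDEFG")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeProfilesTsv(prof, f)
  tab <- read.delim(f, check.names = FALSE)
  expect_identical(colnames(tab), c("position", aaAlphabet()))
  expect_equal(unname(as.matrix(tab[, -1])), unname(substitutionProfile(prof)),
               tolerance = 1e-12)
})
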