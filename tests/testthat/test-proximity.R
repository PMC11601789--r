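test_that("alignment reconstructs both inputs and never emits gap/gap columns", {
  set.seed(4)
  for (rep in 1:25) {
    a <- randomSeq(sample(1:15, 1))
    b <- randomSeq(sample(1:15, 1))
    aln <- alignPair(a, b)
    expect_false(any(is.na(aln@aIdx) & is.na(aln@bIdx)))
    expect_identical(aln@aIdx[!is.na(aln@aIdx)], seq_len(nchar(a)))
    expect_identical(aln@bIdx[!is.na(aln@bIdx)], seq_len(nchar(b)))
  }
})

test_that("identity alignment of identical sequences is all matches", {
  aln <- alignPair("ACDE", "ACDE")
  expect_length(aln@aIdx, 4L)
  expect_false(anyNA(c(aln@aIdx, aln@bIdx)))
  aln2 <- alignPair("AC", "ACD")
  expect_length(aln2@aIdx, 3L)
  expect_identical(sum(is.na(aln2@aIdx)), 1L)
})

test_that("production DP equals the reference DP on small instances (exhaustive oracle)", {
  set.seed(12)
  for (rep in 1:120) {
    a <- randomSeq(sample(1:12, 1), AB4)
    b <- randomSeq(sample(1:12, 1), AB4)
    S <- refBlosumScoreMatrix(a, b)
    expect_equal(alignPair(a, b)@score, refAlignScore(S), tolerance = 1e-9,
                 label = paste("pair", a, b))
  }
})

test_that("production DP agrees with Biostrings pairwiseAlignment (independent library oracle)", {
  set.seed(21)
  for (rep in 1:40) {
    a <- randomSeq(sample(3:20, 1))
    b <- randomSeq(sample(3:20, 1))
    ours <- alignPair(a, b)@score
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    theirs <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = e$BLOSUM62, gapOpening = 10, gapExtension = 1,
      type = "global"))
    expect_equal(ours, theirs, tolerance = 1e-9, label = paste(a, b))
  }
})

test_that("aligned hamming distance: zero iff equal, plain hamming when gapless", {
  expect_identical(alignedHamming("ACDE", "ACDE"), 0L)
  expect_identical(alignedHamming("ACDE", "AGDE"), 1L)
  set.seed(31)
  for (rep in 1:30) {
    L <- sample(4:12, 1)
    a <- randomSeq(L)
    b <- randomSeq(L)
    aln <- alignPair(a, b)
    if (!anyNA(c(aln@aIdx, aln@bIdx))) {
      expect_identical(alignedHamming(a, b), charHamming(a, b))
    }
    expect_identical(alignedHamming(a, b) == 0L, a == b)
  }
})

test_that("percent identity matches column counting", {
  expect_equal(percentIdentity("ACDE", "ACDE"), 100)
  expect_equal(percentIdentity("AAAA", "CCCC"), 0)
  expect_equal(percentIdentity("ACDE", "ACDF"), 75)
})

test_that("proximity is zero exactly at the target in both modes", {
  m <- toySingle
  set.seed(41)
  for (rep in 1:10) {
    t <- randomSeq(sample(3:10, 1))
    expect_equal(proximityTo(t, t, "identity"), 0)
    expect_equal(proximityTo(t, t, "embedding", m), 0, tolerance = 1e-9)
    c1 <- applyEdit(t, newEdit("substitution", 1,
                               setdiff(aaAlphabet(), substr(t, 1, 1))[1]))
    expect_gt(proximityTo(c1, t, "identity"), 0)
    expect_gt(proximityTo(c1, t, "embedding", m), 0)
  }
  expect_error(alignPair("ACD", "ACD", "embedding"), "requires a model")
})

test_that("embedding-mode ranking of candidates matches identity-mode ranking on toy embeddings", {
  target <- "ACDEFGHIKL"
  cands <- c("ACDEFGHIKM", "ACDEFGHWKM", "ACDEFGWWKM")
  ri <- rank(vapply(cands, proximityTo, numeric(1), target = target,
                    mode = "identity"))
  re <- rank(vapply(cands, proximityTo, numeric(1), target = target,
                    mode = "embedding", model = toySingle))
  expect_identical(ri, re)
})

test_that("alignments serialize as gapped FASTA and column TSV", {
  aln <- alignPair("ACDE", "ACE")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeAlignment(aln, fa, "fasta")
  lines <- readLines(fa)
  expect_length(lines, 4L)
  expect_identical(nchar(lines[2]), nchar(lines[4]))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeAlignment(aln, tsv, "tsv")
  tab <- read.delim(tsv)
  expect_identical(nrow(tab), length(aln@aIdx))
})
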