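# Shared fixtures and independent reference oracles used across the suite.

AB4 <- c("A", "C", "D", "G")

randomSeq <- function(L, alphabet = aaAlphabet()) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# Independent quadratic-time reference DP for global affine-gap alignment
# (score only). Deliberately written as a plain three-matrix fill, separate
# from the package's C++ implementation; a gap of length k costs
# open + k * ext, matching the package convention.
refAlignScore <- function(S, open = 10, ext = 1) {
  n <- nrow(S); m <- ncol(S)
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - i * ext
  for (j in seq_len(m)) Y[1, j + 1] <- -open - j * ext
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- S[i, j] + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             X[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

refBlosumScoreMatrix <- function(a, b) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  e$BLOSUM62[ca, cb, drop = FALSE]
}

# plain character-compare hamming distance for equal-length strings
charHamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# shared toy fixtures (constructed once per test run)
toySingle <- makeToyLandscape(8, sharpness = 3, seed = 42)
toyCorridor <- makeToyLandscape(12, sharpness = 4, seed = 7, nComponents = 2,
                                componentDivergence = 0.5)
# family divergence matched to the distance-3 pairs some tests request
toyCorridor3 <- makeToyLandscape(12, sharpness = 4, seed = 7, nComponents = 2,
                                 componentDivergence = 0.25)
toyUniverseModel <- makeToyLandscape(4, sharpness = 3, seed = 5,
                                     nComponents = 2,
                                     componentDivergence = 0.5,
                                     alphabetSubset = AB4)

randomProfiles <- function(L, seed = 1) {
  withr::with_seed(seed, {
    s <- matrix(stats::runif(L * 20), L, 20)
    i <- matrix(stats::runif((L + 1) * 20), L + 1, 20)
    protpath:::mkProfiles(s / rowSums(s), i / rowSums(i), "rand", "rand", "ofs")
  })
}
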