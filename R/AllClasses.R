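#' @importClassesFrom Biostrings AAStringSet
NULL

#' Virtual base class for fitness backends
#'
#' A backend turns a protein sequence into per-position substitution and
#' insertion distributions and per-residue embeddings. Backends must be
#' deterministic (no dropout, no sampling). The shipped backends are the
#' closed-form [ToyLandscape-class] and its masked-oracle variant; an
#' ESM2-class neural backend satisfies the same interface but is not bundled
#' (selecting it raises a "backend unavailable" error).
#'
#' @slot alphabetOrder the fixed 20-letter column ordering used by every
#'   profile matrix
#' @slot embeddingDim dimensionality of residue embeddings
#' @export
setClass("FitnessModel", representation("VIRTUAL",
  alphabetOrder = "character",
  embeddingDim  = "integer"
))

#' Closed-form toy fitness landscape
#'
#' A mixture of K position-weight-matrix "families" over the 20-letter
#' alphabet. Per-position conditionals are computed with leave-one-out
#' component weights, so the distribution at a position never depends on the
#' residue occupying it: the single-pass (OFS) readout and the masked-marginal
#' scan coincide exactly, which pins the estimator plumbing in tests.
#' Sequences whose length deviates from the reference length are scored
#' against a centered placement of the PSSM window with per-residue mixing
#' toward the uniform distribution, so indels carry a fitness cost.
#' Embeddings are one-hot residue channels plus a relative-position channel.
#'
#' Construct with [makeToyLandscape()].
#'
#' @slot logPssm `L_ref x 20 x K` array of per-family log-probabilities
#' @slot weights mixture weights, length K, summing to 1
#' @slot temperature flattens (> 1) or sharpens (< 1) the final conditionals
#' @slot indelPenalty rate of the length-deviation penalty (per residue of
#'   deviation from the reference length)
#' @slot id backend identifier recorded in all outputs
#' @export
setClass("ToyLandscape", contains = "FitnessModel", representation(
  logPssm      = "array",
  weights      = "numeric",
  temperature  = "numeric",
  indelPenalty = "numeric",
  id           = "character"
))

setValidity("ToyLandscape", function(object) {
  d <- dim(object@logPssm)
  if (length(d) != 3L || d[2] != 20L)
    return("logPssm must be an L_ref x 20 x K array")
  if (length(object@weights) != d[3] ||
      abs(sum(object@weights) - 1) > 1e-9 || any(object@weights <= 0))
    return("weights must be positive and sum to 1 (one per component)")
  p <- exp(object@logPssm)
  if (max(abs(apply(p, c(1, 3), sum) - 1)) > 1e-6)
    return("each PSSM row must be a proper distribution")
  if (object@temperature <= 0) return("temperature must be > 0")
  if (object@indelPenalty < 0) return("indelPenalty must be >= 0")
  TRUE
})

#' Per-position mutation profiles of one sequence
#'
#' Row-stochastic substitution (`L x 20`) and insertion (`(L + 1) x 20`)
#' distributions estimated by either the single-pass OFS readout
#' ([ofsProfiles()]) or the masked-marginal scan
#' ([maskedMarginalProfiles()]). Rows sum to 1; columns follow
#' [aaAlphabet()]. These are the proposal distributions of the beam search
#' and the basis of the pseudo-perplexity fitness score.
#'
#' @slot substitution `L x 20` row-stochastic matrix
#' @slot insertion `(L + 1) x 20` row-stochastic matrix
#' @slot sequenceId label of the profiled sequence
#' @slot modelId backend that produced the profiles
#' @slot estimator `"ofs"` or `"masked"`
#' @export
setClass("MutationProfiles", representation(
  substitution = "matrix",
  insertion    = "matrix",
  sequenceId   = "character",
  modelId      = "character",
  estimator    = "character"
))

setValidity("MutationProfiles", function(object) {
  s <- object@substitution; i <- object@insertion
  if (ncol(s) != 20L || ncol(i) != 20L)
    return("profile matrices must have 20 columns")
  if (nrow(i) != nrow(s) + 1L)
    return("insertion profile must have L + 1 rows for an L-row substitution profile")
  if (any(s < 0) || any(i < 0)) return("profile entries must be >= 0")
  if (max(abs(rowSums(s) - 1)) > 1e-6 || max(abs(rowSums(i) - 1)) > 1e-6)
    return("every profile row must sum to 1 (tolerance 1e-6)")
  TRUE
})

#' Pseudo-perplexity fitness score
#'
#' `ppValue(x)` is `exp(mean(perPositionNLL(x)))`, the exponential of the mean
#' per-position negative log-probability of the sequence's own residues under
#' its substitution profile. Lower values mean higher predicted fitness; 1 is
#' the floor (profile certain of every residue). `nClamped` counts positions
#' where a zero probability was clamped to the 1e-12 floor before the log.
#'
#' @slot pseudoPerplexity scalar, >= 1 for any proper profile
#' @slot perPositionNLL negative log-probabilities in nats, one per scored
#'   position
#' @slot positions 1-based positions scored (the whole sequence or a segment)
#' @slot nClamped number of floor-clamped positions
#' @slot modelId backend provenance
#' @export
setClass("FitnessScore", representation(
  pseudoPerplexity = "numeric",
  perPositionNLL   = "numeric",
  positions        = "integer",
  nClamped         = "integer",
  modelId          = "character"
))

#' Global pairwise alignment of two protein sequences
#'
#' Produced by [alignPair()]: a Needleman-Wunsch-style global alignment with
#' affine gaps. `aIdx`/`bIdx` give, per alignment column, the 1-based index
#' into each sequence or `NA` for a gap; no column is gap/gap and the non-NA
#' entries of each vector enumerate `1..L` in order, so both inputs are
#' reconstructible from the columns.
#'
#' @slot a,b the aligned sequences (character)
#' @slot aIdx,bIdx per-column indices (`NA` = gap)
#' @slot score alignment score under the recorded parameters
#' @slot params scoring configuration (mode, gap open/extend, matrix id)
#' @export
setClass("PairAlignment", representation(
  a      = "character",
  b      = "character",
  aIdx   = "integer",
  bIdx   = "integer",
  score  = "numeric",
  params = "list"
))

setValidity("PairAlignment", function(object) {
  if (length(object@aIdx) != length(object@bIdx))
    return("aIdx and bIdx must have one entry per column")
  if (any(is.na(object@aIdx) & is.na(object@bIdx)))
    return("gap/gap columns are not allowed")
  ai <- object@aIdx[!is.na(object@aIdx)]
  bi <- object@bIdx[!is.na(object@bIdx)]
  if (!identical(ai, seq_len(nchar(object@a))) ||
      !identical(bi, seq_len(nchar(object@b))))
    return("column indices must enumerate every residue of both sequences in order")
  TRUE
})

#' A single-residue mutational path
#'
#' An ordered list of protein sequences from a source to a target in which
#' adjacent entries differ by exactly one admissible move (substitution,
#' insertion or deletion), together with the edit applied at each step.
#' Constructed by [newPath()], [randomInterpolation()] or
#' [beamSearchInterpolation()]; check with [validatePath()].
#'
#' @slot steps `AAStringSet`, one record per intermediate (ids encode the
#'   step index)
#' @slot edits `data.frame` with columns `step`, `kind`, `position`,
#'   `residue`; row i transforms step i into step i + 1. Positions are
#'   1-based; an insertion at position p inserts before p (`L + 1` appends).
#' @slot metadata provenance list (strategy, seed, config, backend id)
#' @export
setClass("MutationPath", representation(
  steps    = "AAStringSet",
  edits    = "data.frame",
  metadata = "list"
))

setValidity("MutationPath", function(object) {
  v <- validatePath(object)
  if (isTRUE(v)) TRUE else paste(attr(v, "violations"), collapse = "; ")
})

#' Beam-search configuration
#'
#' Hyperparameters of the stochastic beam search. The defaults (see
#' [beamConfig()]) are desk-scale choices; none are dictated by the method
#' itself.
#'
#' @slot beamWidth partial paths kept per step
#' @slot poolSize candidate edits sampled per beam entry per step
#' @slot fitnessSlack multiplicative viability tolerance: a candidate passes
#'   if its pseudo-perplexity is at most `fitnessSlack` times the larger
#'   endpoint pseudo-perplexity
#' @slot maxSteps step budget; `NA` means 4 x the aligned hamming distance
#' @slot moveMix probabilities of proposing a substitution / insertion /
#'   deletion, summing to 1
#' @slot seed integer seed for proposal sampling (the only stochastic part)
#' @slot proximityMode `"identity"` or `"embedding"` alignment scoring for
#'   the distance-to-target ranking
#' @slot estimator profile estimator, `"ofs"` or `"masked"`
#' @export
setClass("BeamConfig", representation(
  beamWidth     = "integer",
  poolSize      = "integer",
  fitnessSlack  = "numeric",
  maxSteps      = "integer",
  moveMix       = "numeric",
  seed          = "integer",
  proximityMode = "character",
  estimator     = "character"
))

setValidity("BeamConfig", function(object) {
  if (object@beamWidth < 1L) return("beamWidth must be positive")
  if (object@poolSize < 1L) return("poolSize must be positive")
  if (object@fitnessSlack < 0) return("fitnessSlack must be >= 0")
  if (!is.na(object@maxSteps) && object@maxSteps < 1L)
    return("maxSteps must be positive")
  if (length(object@moveMix) != 3L || any(object@moveMix < 0) ||
      abs(sum(object@moveMix) - 1) > 1e-9)
    return("moveMix must be 3 non-negative probabilities summing to 1")
  if (!object@proximityMode %in% c("identity", "embedding"))
    return("proximityMode must be 'identity' or 'embedding'")
  if (!object@estimator %in% c("ofs", "masked"))
    return("estimator must be 'ofs' or 'masked'")
  TRUE
})
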