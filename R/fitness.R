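# Mutation-profile estimation (single-pass OFS readout and masked-marginal
# scan) and the pseudo-perplexity fitness score.

PROB_FLOOR <- 1e-12

# logits (rows x 20) -> row-stochastic matrix restricted to the 20 letters
logitsToProfile <- function(logits) {
  if (ncol(logits) != 20L)
    stop("backend must return logits over the 20-letter alphabet", call. = FALSE)
  m <- apply(logits, 1L, max)
  p <- exp(sweep(logits, 1L, m, "-"))
  rowNormalize(p)
}

#' Estimate mutation profiles with the One Fell Swoop readout
#'
#' Reads the substitution profile out of ONE unmasked forward pass: at each
#' position the model's logits are restricted and renormalised to the
#' 20-letter alphabet. This is the economical alternative to the
#' masked-marginal scan ([maskedMarginalProfiles()]), which needs one masked
#' pass per position. The insertion profile estimator is switchable:
#' `"ofs"` (default) reads all L + 1 insertion-slot distributions from a
#' single pass, `"masked"` runs one masked pass per slot.
#'
#' @param model a [FitnessModel-class] backend
#' @param seq protein sequence
#' @param insertionEstimator `"ofs"` or `"masked"`
#' @param sequenceId label recorded in the result
#' @return a [MutationProfiles-class]
#' @export
ofsProfiles <- function(model, seq, insertionEstimator = c("ofs", "masked"),
                        sequenceId = "seq") {
  insertionEstimator <- match.arg(insertionEstimator)
  seq <- asProteinSequence(seq)
  sub <- logitsToProfile(tokenLogits(model, seq))
  if (nrow(sub) != nchar(seq))
    stop("backend returned ", nrow(sub), " rows for a length-", nchar(seq),
         " sequence", call. = FALSE)
  ins <- if (insertionEstimator == "ofs") {
    logitsToProfile(insertionLogits(model, seq))
  } else {
    t(vapply(seq_len(nchar(seq) + 1L), function(j)
      logitsToProfile(maskedInsertionLogits(model, seq, j))[1L, ],
      numeric(20L)))
  }
  mkProfiles(sub, ins, sequenceId, modelId(model), "ofs")
}

#' Estimate mutation profiles with the masked-marginal scan
#'
#' The reference scheme: substitution row i is the renormalised softmax of
#' the model's logits at position i when that position is masked (L forward
#' passes); insertion row j likewise with a mask inserted at slot j (L + 1
#' passes). Serves as the brute-force oracle for the OFS readout.
#'
#' @inheritParams ofsProfiles
#' @return a [MutationProfiles-class]
#' @export
maskedMarginalProfiles <- function(model, seq, sequenceId = "seq") {
  seq <- asProteinSequence(seq)
  L <- nchar(seq)
  sub <- t(vapply(seq_len(L), function(i)
    logitsToProfile(maskedTokenLogits(model, seq, i))[1L, ], numeric(20L)))
  ins <- t(vapply(seq_len(L + 1L), function(j)
    logitsToProfile(maskedInsertionLogits(model, seq, j))[1L, ], numeric(20L)))
  mkProfiles(sub, ins, sequenceId, modelId(model), "masked")
}

mkProfiles <- function(sub, ins, sequenceId, modelId, estimator) {
  dimnames(sub) <- list(NULL, AA_STANDARD_20)
  dimnames(ins) <- list(NULL, AA_STANDARD_20)
  new("MutationProfiles", substitution = sub, insertion = ins,
      sequenceId = sequenceId, modelId = modelId, estimator = estimator)
}

# estimator switch used throughout the search code
profilesFor <- function(model, seq, estimator = c("ofs", "masked"),
                        sequenceId = "seq") {
  estimator <- match.arg(estimator)
  if (estimator == "ofs") ofsProfiles(model, seq, sequenceId = sequenceId)
  else maskedMarginalProfiles(model, seq, sequenceId = sequenceId)
}

#' @export
setMethod("substitutionProfile", "MutationProfiles", function(x) x@substitution)

#' @export
setMethod("insertionProfile", "MutationProfiles", function(x) x@insertion)

setMethod("show", "MutationProfiles", function(object) {
  cat(sprintf("MutationProfiles for '%s' (%d positions, model %s, estimator %s)\n",
              object@sequenceId, nrow(object@substitution), object@modelId,
              object@estimator))
})

#' Pseudo-perplexity of a sequence under its substitution profile
#'
#' The fitness scalar: `exp` of the mean per-position negative
#' log-probability of the sequence's own residues under the per-position
#' substitution distributions. A lower value indicates a higher predicted
#' fitness; 1 is attained only when the profile is certain of every residue,
#' and a uniform profile gives the alphabet size (20). Probabilities below
#' 1e-12 are clamped to that floor before the log and counted in `nClamped`.
#'
#' @param profiles [MutationProfiles-class] computed for exactly this sequence
#' @param seq the sequence the profiles were computed for
#' @return a [FitnessScore-class]
#' @export
#' @examples
#' m <- makeToyLandscape(6, sharpness = 2, seed = 1)
#' s <- consensusSequence(m)
#' ppValue(pseudoPerplexity(ofsProfiles(m, s), s))
pseudoPerplexity <- function(profiles, seq) {
  seq <- asProteinSequence(seq)
  L <- nchar(seq)
  if (nrow(profiles@substitution) != L)
    stop("profile has ", nrow(profiles@substitution),
         " rows but sequence has length ", L, call. = FALSE)
  scoreSegment(profiles, seq, seq_len(L))
}

#' Pseudo-perplexity restricted to a segment
#'
#' Same formula as [pseudoPerplexity()] over only the positions in `segment`,
#' using the full-sequence profiles (the segment is not excised and
#' re-scored). Used to follow the local fitness of individual domains along
#' a path.
#'
#' @inheritParams pseudoPerplexity
#' @param segment an `IRanges` of width 1 range, or `c(start, end)` (1-based,
#'   closed), within `[1, L]`
#' @return a [FitnessScore-class]
#' @export
segmentPseudoPerplexity <- function(profiles, seq, segment) {
  seq <- asProteinSequence(seq)
  L <- nchar(seq)
  if (nrow(profiles@substitution) != L)
    stop("profile/sequence length mismatch", call. = FALSE)
  if (is(segment, "IRanges")) {
    if (length(segment) != 1L) stop("segment must be a single range", call. = FALSE)
    from <- IRanges::start(segment); to <- IRanges::end(segment)
  } else {
    if (length(segment) != 2L) stop("segment must be c(start, end)", call. = FALSE)
    from <- as.integer(segment[1L]); to <- as.integer(segment[2L])
  }
  if (is.na(from) || is.na(to) || from < 1L || to > L || from > to)
    stop("segment [", from, ", ", to, "] out of range for length ", L,
         call. = FALSE)
  scoreSegment(profiles, seq, from:to)
}

scoreSegment <- function(profiles, seq, positions) {
  idx <- aaIndex(seqChars(seq))[positions]
  p <- profiles@substitution[cbind(positions, idx)]
  nClamped <- sum(p < PROB_FLOOR)
  if (nClamped > 0L) {
    warning(nClamped, " position(s) clamped to the ", PROB_FLOOR,
            " probability floor", call. = FALSE)
    p <- pmax(p, PROB_FLOOR)
  }
  nll <- -log(p)
  new("FitnessScore", pseudoPerplexity = exp(mean(nll)), perPositionNLL = nll,
      positions = as.integer(positions), nClamped = as.integer(nClamped),
      modelId = profiles@modelId)
}

#' @export
setMethod("ppValue", "FitnessScore", function(x) x@pseudoPerplexity)

#' @export
setMethod("perPositionNLL", "FitnessScore", function(x) x@perPositionNLL)

setMethod("show", "FitnessScore", function(object) {
  cat(sprintf("FitnessScore: pseudo-perplexity %.4f over %d positions (model %s)\n",
              object@pseudoPerplexity, length(object@perPositionNLL),
              object@modelId))
  if (object@nClamped > 0L)
    cat(" ", object@nClamped, "position(s) clamped at the probability floor\n")
})

#' Write / read mutation profiles as TSV
#'
#' One row per position: `position`, then the 20 probability columns in
#' [aaAlphabet()] order. Substitution and insertion profiles go to separate
#' files.
#'
#' @param profiles a [MutationProfiles-class]
#' @param file output path
#' @param which `"substitution"` or `"insertion"`
#' @return `file`, invisibly
#' @export
writeProfilesTsv <- function(profiles, file, which = c("substitution", "insertion")) {
  which <- match.arg(which)
  m <- slot(profiles, which)
  df <- data.frame(position = seq_len(nrow(m)), m, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
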