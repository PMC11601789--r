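#' @import methods
NULL

#' Model backend generics
#'
#' A fitness backend must be deterministic and expose three capabilities:
#' per-position logits from one unmasked pass over the whole sequence
#' ([tokenLogits()] and [insertionLogits()]), logits at a single masked
#' position or insertion slot ([maskedTokenLogits()],
#' [maskedInsertionLogits()]), and per-residue embeddings
#' ([residueEmbeddings()]). Profiles and scores are built on top of these by
#' [ofsProfiles()], [maskedMarginalProfiles()] and [pseudoPerplexity()].
#'
#' @param model A [FitnessModel-class] backend.
#' @param seq A protein sequence (character scalar or `AAString`).
#' @param pos 1-based residue position.
#' @param slot 1-based insertion slot; slot `j` inserts before position `j`,
#'   `L + 1` appends.
#' @return `tokenLogits`: an `L x 20` matrix of log-scores;
#'   `insertionLogits`: `(L + 1) x 20`; the masked variants one row each;
#'   `residueEmbeddings`: an `L x D` numeric matrix;
#'   `modelId`: a character scalar identifying the backend.
#' @name backend-generics
NULL

#' @rdname backend-generics
#' @export
setGeneric("tokenLogits", function(model, seq) standardGeneric("tokenLogits"))

#' @rdname backend-generics
#' @export
setGeneric("maskedTokenLogits", function(model, seq, pos)
  standardGeneric("maskedTokenLogits"))

#' @rdname backend-generics
#' @export
setGeneric("insertionLogits", function(model, seq)
  standardGeneric("insertionLogits"))

#' @rdname backend-generics
#' @export
setGeneric("maskedInsertionLogits", function(model, seq, slot)
  standardGeneric("maskedInsertionLogits"))

#' @rdname backend-generics
#' @export
setGeneric("residueEmbeddings", function(model, seq)
  standardGeneric("residueEmbeddings"))

#' @rdname backend-generics
#' @export
setGeneric("modelId", function(model) standardGeneric("modelId"))

#' @describeIn MutationProfiles-class the `L x 20` substitution profile
#' @export
setGeneric("substitutionProfile", function(x) standardGeneric("substitutionProfile"))

#' @describeIn MutationProfiles-class the `(L + 1) x 20` insertion profile
#' @export
setGeneric("insertionProfile", function(x) standardGeneric("insertionProfile"))

#' @describeIn FitnessScore-class the scalar pseudo-perplexity of a score object
#' @param x object
#' @export
setGeneric("ppValue", function(x) standardGeneric("ppValue"))

#' @describeIn FitnessScore-class per-position negative log-probabilities (nats)
#' @export
setGeneric("perPositionNLL", function(x) standardGeneric("perPositionNLL"))

#' @describeIn MutationPath-class the ordered step sequences as an `AAStringSet`
#' @export
setGeneric("pathSteps", function(x) standardGeneric("pathSteps"))

#' @describeIn MutationPath-class the edit records (`data.frame`: step, kind,
#'   position, residue)
#' @export
setGeneric("pathEdits", function(x) standardGeneric("pathEdits"))
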