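# Distance-to-target machinery: global pairwise alignment (identity scoring
# or embedding-weighted column scores), aligned hamming distance, percent
# identity, and the proximity measure used to steer the beam search.

#' @importFrom Rcpp evalCpp
#' @useDynLib protpath, .registration = TRUE
NULL

blosumEnv <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(blosumEnv$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosumEnv$m <- e$BLOSUM62[AA_STANDARD_20, AA_STANDARD_20]
  }
  blosumEnv$m
}

# Embedding cosine similarity mapped onto a BLOSUM-comparable dynamic range,
# so the same affine gap penalties are meaningful in both modes.
EMB_SCALE <- 12
EMB_SHIFT <- -4

#' Global pairwise alignment
#'
#' Needleman-Wunsch-style global alignment with affine gaps (a gap of length
#' k costs `gapOpen + k * gapExtend`). In `identity` mode columns are scored
#' with BLOSUM62; in `embedding` mode column (i, j) is scored by the cosine
#' similarity of the two residues' model embeddings, linearly rescaled to the
#' BLOSUM62 dynamic range (`12 * cos - 4`). Traceback ties break
#' deterministically: diagonal, then gap in the second sequence, then gap in
#' the first.
#'
#' @param a,b protein sequences
#' @param mode `"identity"` or `"embedding"`
#' @param model a [FitnessModel-class]; required for embedding mode
#' @param gapOpen,gapExtend affine gap parameters (defaults 10 and 1)
#' @return a [PairAlignment-class]
#' @export
#' @examples
#' aln <- alignPair("ACDE", "ACDF")
#' percentIdentity("ACDE", "ACDF")  # 75
alignPair <- function(a, b, mode = c("identity", "embedding"), model = NULL,
                      gapOpen = 10, gapExtend = 1) {
  mode <- match.arg(mode)
  a <- asProteinSequence(a); b <- asProteinSequence(b)
  if (mode == "identity") {
    S <- blosum62()[aaIndex(seqChars(a)), aaIndex(seqChars(b)), drop = FALSE]
    matrixId <- "BLOSUM62"
  } else {
    if (is.null(model)) stop("embedding mode requires a model", call. = FALSE)
    ea <- residueEmbeddings(model, a)
    eb <- residueEmbeddings(model, b)
    num <- ea %*% t(eb)
    cosine <- num / (sqrt(rowSums(ea^2)) %o% sqrt(rowSums(eb^2)))
    S <- EMB_SCALE * cosine + EMB_SHIFT
    matrixId <- sprintf("embedding-cosine(%s)*%g%+g", modelId(model),
                        EMB_SCALE, EMB_SHIFT)
  }
  r <- .needleAffine(S, gapOpen, gapExtend)
  new("PairAlignment", a = a, b = b, aIdx = r$aIdx, bIdx = r$bIdx,
      score = r$score,
      params = list(mode = mode, gapOpen = gapOpen, gapExtend = gapExtend,
                    matrix = matrixId))
}

alignmentColumns <- function(aln) {
  ca <- ifelse(is.na(aln@aIdx), "-", seqChars(aln@a)[aln@aIdx])
  cb <- ifelse(is.na(aln@bIdx), "-", seqChars(aln@b)[aln@bIdx])
  data.frame(column = seq_along(ca), a = ca, b = cb,
             aIdx = aln@aIdx, bIdx = aln@bIdx, stringsAsFactors = FALSE)
}

setMethod("show", "PairAlignment", function(object) {
  cols <- alignmentColumns(object)
  cat(sprintf("PairAlignment (%s): %d columns, score %.2f, identity %.1f%%\n",
              object@params$mode, nrow(cols), object@score,
              100 * mean(cols$a == cols$b)))
  w <- min(nrow(cols), 60L)
  cat(" ", paste(cols$a[seq_len(w)], collapse = ""), "\n",
      " ", paste(cols$b[seq_len(w)], collapse = ""), "\n", sep = "")
})

#' Aligned hamming distance
#'
#' The number of alignment columns that are not identical matches (mismatch
#' columns plus gap columns) in the global alignment of `a` and `b`. This is
#' the step count of the random interpolation strategy.
#'
#' @inheritParams alignPair
#' @return non-negative integer
#' @export
alignedHamming <- function(a, b, mode = c("identity", "embedding"),
                           model = NULL) {
  cols <- alignmentColumns(alignPair(a, b, mode, model))
  sum(cols$a != cols$b)
}

#' Percent identity of two sequences
#'
#' `100 *` identical match columns `/` total alignment columns of the global
#' alignment; not rounded.
#'
#' @inheritParams alignPair
#' @return numeric in `[0, 100]`
#' @export
percentIdentity <- function(a, b, mode = c("identity", "embedding"),
                            model = NULL) {
  cols <- alignmentColumns(alignPair(a, b, mode, model))
  100 * sum(cols$a == cols$b) / nrow(cols)
}

#' Distance from a candidate to the target
#'
#' A non-negative proximity score that is 0 exactly when the candidate equals
#' the target (for the bundled backends); smaller means closer. In
#' `identity` mode it is the aligned hamming distance; in `embedding` mode it
#' is the target's maximal self-alignment score minus the candidate-target
#' alignment score. Not required to be symmetric.
#'
#' @param candidate,target protein sequences
#' @inheritParams alignPair
#' @return non-negative numeric
#' @export
proximityTo <- function(candidate, target, mode = c("identity", "embedding"),
                        model = NULL) {
  mode <- match.arg(mode)
  if (mode == "identity") return(as.numeric(alignedHamming(candidate, target)))
  self <- alignPair(target, target, "embedding", model)@score
  self - alignPair(candidate, target, "embedding", model)@score
}

#' Write an alignment as gapped FASTA or a column TSV
#'
#' @param aln a [PairAlignment-class]
#' @param file output path
#' @param format `"fasta"` (two gapped records) or `"tsv"` (one row per
#'   column: column, a, b, aIdx, bIdx)
#' @return `file`, invisibly
#' @export
writeAlignment <- function(aln, file, format = c("fasta", "tsv")) {
  format <- match.arg(format)
  cols <- alignmentColumns(aln)
  if (format == "fasta") {
    writeLines(c(">a", paste(cols$a, collapse = ""),
                 ">b", paste(cols$b, collapse = "")), file)
  } else {
    utils::write.table(cols, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}
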