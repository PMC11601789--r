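# Sequence, edit and path primitives plus FASTA I/O.

#' @importFrom Biostrings AAString AAStringSet readAAStringSet writeXStringSet
#' @importFrom S4Vectors metadata
NULL

EDIT_KINDS <- c("substitution", "insertion", "deletion")

#' Validate and normalise a protein sequence
#'
#' Accepts a character scalar, `AAString` or length-1 `AAStringSet` and
#' returns the plain uppercase residue string after checking it is non-empty
#' and drawn from the 20-letter alphabet. Non-canonical letters (X, B, Z, U,
#' O, gaps) are rejected, never silently mapped: every profile in the package
#' is defined over exactly 20 letters.
#'
#' @param x sequence input
#' @return character scalar of residues
#' @export
#' @examples
#' asProteinSequence("ACDE")
asProteinSequence <- function(x) {
  if (is(x, "AAStringSet")) {
    if (length(x) != 1L) stop("expected exactly one sequence", call. = FALSE)
    x <- as.character(x[[1L]])
  } else if (is(x, "AAString")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("sequence must be a single character string", call. = FALSE)
  x <- toupper(x)
  if (nchar(x) < 1L) stop("sequence must have length >= 1", call. = FALSE)
  aaIndex(seqChars(x))  # errors on non-canonical residues
  x
}

#' Construct a single edit record
#'
#' An edit is one atomic move: a substitution or deletion at a 1-based
#' position of the sequence it applies to, or an insertion before position
#' `position` (so `position = L + 1` appends). Applying an edit always
#' changes the Levenshtein distance to the pre-edit sequence by exactly 1.
#'
#' @param kind `"substitution"`, `"insertion"` or `"deletion"`
#' @param position 1-based position
#' @param residue replacement / inserted residue; must be absent for deletions
#' @return one-row `data.frame` with columns `kind`, `position`, `residue`
#' @export
newEdit <- function(kind, position, residue = NA_character_) {
  kind <- match.arg(kind, EDIT_KINDS)
  position <- as.integer(position)
  if (is.na(position) || position < 1L)
    stop("position must be a positive integer", call. = FALSE)
  if (kind == "deletion") {
    if (!is.na(residue)) stop("deletion takes no residue", call. = FALSE)
  } else {
    if (is.na(residue) || nchar(residue) != 1L)
      stop(kind, " needs a single residue letter", call. = FALSE)
    aaIndex(residue)
  }
  data.frame(kind = kind, position = position,
             residue = as.character(residue), stringsAsFactors = FALSE)
}

#' Apply one edit to a sequence
#'
#' @param seq protein sequence (any form accepted by [asProteinSequence()])
#' @param edit one-row edit `data.frame` from [newEdit()]
#' @return the edited sequence (character scalar); the input is unchanged
#' @export
#' @examples
#' applyEdit("ACD", newEdit("deletion", 2))      # "AD"
#' applyEdit("AC", newEdit("insertion", 3, "D")) # "ACD"
applyEdit <- function(seq, edit) {
  seq <- asProteinSequence(seq)
  L <- nchar(seq)
  kind <- edit$kind[1L]; pos <- edit$position[1L]; res <- edit$residue[1L]
  switch(kind,
    substitution = {
      if (pos > L) stop("substitution position ", pos,
                        " out of range for length ", L, call. = FALSE)
      aaIndex(res)
      paste0(substr(seq, 1L, pos - 1L), res, substr(seq, pos + 1L, L))
    },
    insertion = {
      if (pos > L + 1L) stop("insertion position ", pos,
                             " out of range for length ", L, call. = FALSE)
      aaIndex(res)
      paste0(substr(seq, 1L, pos - 1L), res, substr(seq, pos, L))
    },
    deletion = {
      if (pos > L) stop("deletion position ", pos,
                        " out of range for length ", L, call. = FALSE)
      if (L == 1L) stop("cannot delete the only residue", call. = FALSE)
      paste0(substr(seq, 1L, pos - 1L), substr(seq, pos + 1L, L))
    },
    stop("unknown edit kind: ", kind, call. = FALSE)
  )
}

# the edit that undoes `edit` applied to `seq`
inverseEdit <- function(seq, edit) {
  seq <- asProteinSequence(seq)
  kind <- edit$kind[1L]; pos <- edit$position[1L]
  switch(kind,
    substitution = newEdit("substitution", pos, substr(seq, pos, pos)),
    insertion    = newEdit("deletion", pos),
    deletion     = newEdit("insertion", pos, substr(seq, pos, pos))
  )
}

emptyEdits <- function() {
  data.frame(step = integer(), kind = character(), position = integer(),
             residue = character(), stringsAsFactors = FALSE)
}

#' Construct a mutational path
#'
#' @param steps character vector (or `AAStringSet`) of step sequences, source
#'   first, target last
#' @param edits `data.frame` of edits (columns `kind`, `position`, `residue`),
#'   one fewer row than there are steps; a `step` column is added/overwritten
#' @param sourceId id used to label the FASTA records (`{sourceId}|step{k}`)
#' @param metadata free-form provenance list
#' @return a [MutationPath-class] object (validity-checked)
#' @export
newPath <- function(steps, edits = emptyEdits(), sourceId = "path",
                    metadata = list()) {
  steps <- vapply(as.character(steps), asProteinSequence, character(1L),
                  USE.NAMES = FALSE)
  if (nrow(edits) > 0L) {
    edits <- data.frame(step = seq_len(nrow(edits)), kind = edits$kind,
                        position = as.integer(edits$position),
                        residue = as.character(edits$residue),
                        stringsAsFactors = FALSE)
  } else edits <- emptyEdits()
  ss <- AAStringSet(steps)
  names(ss) <- sprintf("%s|step%04d", sourceId, seq_along(steps) - 1L)
  new("MutationPath", steps = ss, edits = edits,
      metadata = c(metadata, list(sourceId = sourceId)))
}

#' Validate the path invariants
#'
#' Checks that there is at least one step, that applying `edits[i]` to step i
#' reproduces step i + 1, and that adjacent steps sit at Levenshtein distance
#' exactly 1. Never raises: returns `TRUE`, or `FALSE` carrying a
#' machine-readable `violations` attribute (character vector).
#'
#' @param path a [MutationPath-class]
#' @return logical scalar with attribute `violations` when `FALSE`
#' @export
validatePath <- function(path) {
  steps <- unname(as.character(path@steps))
  edits <- path@edits
  bad <- character()
  if (length(steps) < 1L) bad <- c(bad, "path must contain at least one step")
  if (nrow(edits) != max(length(steps) - 1L, 0L))
    bad <- c(bad, sprintf("expected %d edits for %d steps, found %d",
                          max(length(steps) - 1L, 0L), length(steps), nrow(edits)))
  n <- min(nrow(edits), max(length(steps) - 1L, 0L))
  for (i in seq_len(n)) {
    got <- tryCatch(applyEdit(steps[i], edits[i, , drop = FALSE]),
                    error = function(e) conditionMessage(e))
    if (!identical(got, steps[i + 1L]))
      bad <- c(bad, sprintf("edit %d does not transform step %d into step %d",
                            i, i - 1L, i))
    else if (utils::adist(steps[i], steps[i + 1L])[1L] != 1L)
      bad <- c(bad, sprintf("steps %d and %d are not at edit distance 1",
                            i - 1L, i))
  }
  if (length(bad) == 0L) TRUE else structure(FALSE, violations = bad)
}

#' @describeIn newPath number of edits (steps minus one)
#' @param x,object a `MutationPath`
#' @export
pathLength <- function(x) nrow(x@edits)

#' @export
setMethod("pathSteps", "MutationPath", function(x) x@steps)

#' @export
setMethod("pathEdits", "MutationPath", function(x) x@edits)

setMethod("show", "MutationPath", function(object) {
  s <- as.character(object@steps)
  cat(sprintf("MutationPath: %d steps (%d edits)\n source: %s (%d aa)\n target: %s (%d aa)\n",
              length(s), nrow(object@edits),
              substr(s[1L], 1L, 40L), nchar(s[1L]),
              substr(s[length(s)], 1L, 40L), nchar(s[length(s)])))
  strat <- object@metadata$strategy
  if (!is.null(strat)) cat(" strategy:", strat, "\n")
})

## ---- FASTA / TSV I/O -------------------------------------------------------

#' Read protein sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that additionally
#' enforces the 20-letter alphabet, naming the offending record and character.
#'
#' @param file path to a FASTA file
#' @return `AAStringSet`
#' @export
readProteinFasta <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file, call. = FALSE)
  ss <- tryCatch(readAAStringSet(file),
                 error = function(e) stop("malformed FASTA '", file, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(ss) == 0L) stop("no records in FASTA: ", file, call. = FALSE)
  for (i in seq_along(ss)) {
    ch <- seqChars(toupper(as.character(ss[[i]])))
    miss <- setdiff(unique(ch), AA_STANDARD_20)
    if (length(miss) > 0L)
      stop("record '", names(ss)[i], "' contains non-canonical residue(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  ss
}

#' Write protein sequences to FASTA
#'
#' @param seqs `AAStringSet` or named character vector
#' @param file output path
#' @return `file`, invisibly
#' @export
writeProteinFasta <- function(seqs, file) {
  if (!is(seqs, "AAStringSet")) {
    nm <- names(seqs) %||% paste0("seq", seq_along(seqs))
    seqs <- AAStringSet(setNames(vapply(seqs, asProteinSequence, character(1L),
                                        USE.NAMES = FALSE), nm))
  }
  writeXStringSet(seqs, file, width = 60L)
  invisible(file)
}

#' Write a path as FASTA + edits TSV
#'
#' Emits `<prefix>.fasta` (one record per step, ids `{sourceId}|step{k:04d}`,
#' ordered by step) and `<prefix>.edits.tsv` (columns `step`, `kind`,
#' `position`, `residue`; 1-based positions).
#'
#' @param path a [MutationPath-class]
#' @param dir output directory (created if needed)
#' @param prefix file name stem
#' @return character vector of the two files written, invisibly
#' @export
writePathFiles <- function(path, dir, prefix = "path") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  tsv <- file.path(dir, paste0(prefix, ".edits.tsv"))
  writeXStringSet(path@steps, fa, width = 60L)
  utils::write.table(path@edits, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, edits = tsv))
}

#' Read back a path written by [writePathFiles()]
#'
#' @param fasta,edits the two files
#' @return a validated [MutationPath-class]
#' @export
readPathFiles <- function(fasta, edits) {
  ss <- readProteinFasta(fasta)
  ed <- utils::read.table(edits, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "integer",
                                         "character"))
  sourceId <- sub("\\|step[0-9]+$", "", names(ss)[1L])
  newPath(as.character(ss), ed[, c("kind", "position", "residue")],
          sourceId = sourceId)
}
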