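# Download-gated real-protein fixtures. The package's reference endpoint
# pairs are UniProt entries; nothing here is bundled, so these helpers need
# either network access or a pre-populated cache directory of
# "<accession>.fasta" files.

UNIPROT_PAIRS <- list(
  distant     = c("P21866", "P10958"),  # response-regulator pair, ~18% identity
  speculative = c("P00344", "P37062")   # LDH / NADH-peroxidase pair, ~12% identity
)

#' Fetch a UniProt sequence (download-gated)
#'
#' Looks for `<accession>.fasta` in `cacheDir` first; otherwise downloads it
#' from the UniProt REST service and caches it. Fails with a clear error when
#' offline and not cached.
#'
#' @param accession UniProt accession, e.g. `"P21866"`
#' @param cacheDir directory for cached FASTA files
#' @return `AAStringSet` with one record
#' @export
fetchUniprot <- function(accession,
                         cacheDir = file.path(tempdir(), "protpath-uniprot")) {
  stopifnot(grepl("^[A-Z0-9]+$", accession))
  dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(cacheDir, paste0(accession, ".fasta"))
  if (!file.exists(dest)) {
    url <- paste0("https://rest.uniprot.org/uniprotkb/", accession, ".fasta")
    ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                   error = function(e) -1L, warning = function(w) -1L)
    if (!identical(ok, 0L) || !file.exists(dest) || file.size(dest) == 0L) {
      unlink(dest)
      stop("could not fetch UniProt ", accession,
           " (offline?); place ", accession, ".fasta in ", cacheDir,
           call. = FALSE)
    }
  }
  readProteinFasta(dest)
}

#' Identity report for a reference endpoint pair
#'
#' Fetches (or reads from cache) one of the package's reference UniProt
#' pairs, aligns it, and reports the percent identity and the longest run of
#' contiguous identical alignment columns with its residue string.
#'
#' @param pair `"distant"` (P21866/P10958) or `"speculative"`
#'   (P00344/P37062), or a character vector of two accessions
#' @param cacheDir cache directory passed to [fetchUniprot()]
#' @return list with `accessions`, `percentIdentity`, `longestRun`,
#'   `longestRunSeq`, `alignment` (a [PairAlignment-class])
#' @export
uniprotPairIdentity <- function(pair = c("distant", "speculative"),
                                cacheDir = file.path(tempdir(),
                                                     "protpath-uniprot")) {
  acc <- if (length(pair) == 2L && all(grepl("^[A-Z0-9]{6,10}$", pair))) pair
         else UNIPROT_PAIRS[[match.arg(pair)]]
  a <- as.character(fetchUniprot(acc[1L], cacheDir)[[1L]])
  b <- as.character(fetchUniprot(acc[2L], cacheDir)[[1L]])
  aln <- alignPair(a, b, "identity")
  cols <- alignmentColumns(aln)
  same <- cols$a == cols$b
  r <- rle(same)
  runLen <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  runSeq <- ""
  if (runLen > 0L) {
    ends <- cumsum(r$lengths)
    i <- which(r$values & r$lengths == runLen)[1L]
    runSeq <- paste(cols$a[(ends[i] - runLen + 1L):ends[i]], collapse = "")
  }
  list(accessions = acc,
       percentIdentity = 100 * sum(same) / nrow(cols),
       longestRun = runLen, longestRunSeq = runSeq, alignment = aln)
}
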