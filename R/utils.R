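# Internal helpers shared across modules.

#' The 20-letter amino-acid alphabet, in fixed alphabetical order
#'
#' All mutation profiles are L x 20 matrices whose columns follow this
#' ordering. Non-canonical letters (X, B, Z, U, O) are rejected everywhere.
#'
#' @return Character vector of length 20.
#' @export
aaAlphabet <- function() AA_STANDARD_20

AA_STANDARD_20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# residue letters -> 1..20 indices; stops naming the offending character
aaIndex <- function(chars) {
  idx <- match(chars, AA_STANDARD_20)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "),
         " (alphabet is the 20 standard amino acids)", call. = FALSE)
  }
  idx
}

seqChars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Evaluate `expr` under a private Mersenne-Twister stream seeded with `seed`,
# restoring the caller's RNG state afterwards. All stochastic code in the
# package funnels through this so runs are reproducible byte-for-byte.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-normalize a non-negative matrix; guards all-zero rows
rowNormalize <- function(m) {
  s <- rowSums(m)
  if (any(s <= 0)) stop("cannot normalize a zero row", call. = FALSE)
  m / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
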