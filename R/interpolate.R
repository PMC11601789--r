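# Path generation: the random-order interpolation control and the stochastic
# beam search over single-residue edits.

#' Construct a beam-search configuration
#'
#' @param beamWidth partial paths kept per step (default 5)
#' @param poolSize candidate edits sampled per beam entry per step (default 50)
#' @param fitnessSlack multiplicative viability tolerance above the larger
#'   endpoint pseudo-perplexity (default 1.05: intermediates may exceed the
#'   worse endpoint by 5 percent)
#' @param maxSteps step budget; `NA` (default) means 4 x the aligned hamming
#'   distance of the endpoints
#' @param moveMix proposal probabilities for substitution / insertion /
#'   deletion (default 0.8, 0.1, 0.1)
#' @param seed integer seed for proposal sampling
#' @param proximityMode `"identity"` or `"embedding"`
#' @param estimator profile estimator, `"ofs"` or `"masked"`
#' @return a validated [BeamConfig-class]
#' @export
beamConfig <- function(beamWidth = 5, poolSize = 50, fitnessSlack = 1.05,
                       maxSteps = NA, moveMix = c(0.8, 0.1, 0.1), seed = 1,
                       proximityMode = c("identity", "embedding"),
                       estimator = c("ofs", "masked")) {
  new("BeamConfig", beamWidth = as.integer(beamWidth),
      poolSize = as.integer(poolSize), fitnessSlack = as.numeric(fitnessSlack),
      maxSteps = as.integer(maxSteps), moveMix = as.numeric(moveMix),
      seed = as.integer(seed), proximityMode = match.arg(proximityMode),
      estimator = match.arg(estimator))
}

setMethod("show", "BeamConfig", function(object) {
  cat(sprintf(paste0("BeamConfig: width %d, pool %d, slack %.3g, maxSteps %s, ",
                     "moveMix %.2f/%.2f/%.2f, seed %d, %s proximity, %s estimator\n"),
              object@beamWidth, object@poolSize, object@fitnessSlack,
              ifelse(is.na(object@maxSteps), "auto", object@maxSteps),
              object@moveMix[1L], object@moveMix[2L], object@moveMix[3L],
              object@seed, object@proximityMode, object@estimator))
})

configSignature <- function(config) {
  paste(config@beamWidth, config@poolSize, config@fitnessSlack,
        config@maxSteps, paste(config@moveMix, collapse = ","), config@seed,
        config@proximityMode, config@estimator, sep = "|")
}

# The fixed column plan of the endpoint alignment: one entry per
# non-identical column, with the target content of that column.
columnPlan <- function(aln) {
  cols <- alignmentColumns(aln)
  cols[cols$a != cols$b, , drop = FALSE]
}

# Execute the column plan in the given order. State = per-column residue
# occupancy, so indel positions re-index automatically as columns fill and
# empty (per-step positional bookkeeping over the ORIGINAL alignment).
runColumnPlan <- function(aln, plan, order) {
  cols <- alignmentColumns(aln)
  res <- ifelse(cols$a == "-", NA_character_, cols$a)
  steps <- paste(res[!is.na(res)], collapse = "")
  edits <- emptyEdits()
  for (c0 in plan$column[order]) {
    before <- sum(!is.na(res[seq_len(c0 - 1L)]))
    ca <- cols$a[c0]; cb <- cols$b[c0]
    if (ca != "-" && cb != "-") {
      e <- newEdit("substitution", before + 1L, cb)
      res[c0] <- cb
    } else if (ca == "-") {
      e <- newEdit("insertion", before + 1L, cb)
      res[c0] <- cb
    } else {
      e <- newEdit("deletion", before + 1L)
      res[c0] <- NA_character_
    }
    cur <- paste(res[!is.na(res)], collapse = "")
    if (nchar(cur) == 0L)
      stop("edit order empties the sequence; no valid path in this order",
           call. = FALSE)
    steps <- c(steps, cur)
    edits <- rbind(edits, cbind(step = nrow(edits) + 1L, e))
  }
  list(steps = steps, edits = edits)
}

#' Random-order interpolation between two sequences
#'
#' The control strategy: align the pair once, collect every non-identical
#' alignment column as one pending edit (mismatch = substitution,
#' gap-in-source = insertion, gap-in-target = deletion), and apply them in a
#' uniformly random order, re-indexing positions after each indel. The path
#' therefore always has exactly `alignedHamming(source, target)` steps and
#' ends at the target.
#'
#' @param source,target protein sequences
#' @param mode alignment mode for the endpoint alignment
#' @param seed integer seed for the order draw (ignored when `order` given)
#' @param model backend, required for embedding mode
#' @param order optional explicit permutation of the pending edits
#' @return a validated [MutationPath-class]
#' @export
randomInterpolation <- function(source, target, mode = c("identity", "embedding"),
                                seed = 1, model = NULL, order = NULL) {
  mode <- match.arg(mode)
  source <- asProteinSequence(source); target <- asProteinSequence(target)
  if (source == target)
    return(newPath(source, metadata = list(strategy = "random", seed = seed)))
  aln <- alignPair(source, target, mode, model)
  plan <- columnPlan(aln)
  if (is.null(order)) order <- withSeed(seed, sample.int(nrow(plan)))
  stopifnot(length(order) == nrow(plan))
  r <- runColumnPlan(aln, plan, order)
  newPath(r$steps, r$edits[, c("kind", "position", "residue")],
          metadata = list(strategy = "random", seed = seed, mode = mode,
                          order = order))
}

#' Enumerate every edit order of the interpolation between two endpoints
#'
#' Exhaustively generates the random strategy's path for each permutation of
#' the pending edits. For endpoints differing at n aligned columns this
#' yields n! paths (e.g. 5 differing columns give 120 distinct 5-step
#' paths). Guarded: refuses when n! exceeds `maxOrders`.
#'
#' @inheritParams randomInterpolation
#' @param maxOrders refusal threshold on n! (default 720)
#' @return list of [MutationPath-class] objects
#' @export
enumerateInterpolationOrders <- function(source, target,
                                         mode = c("identity", "embedding"),
                                         model = NULL, maxOrders = 720) {
  mode <- match.arg(mode)
  source <- asProteinSequence(source); target <- asProteinSequence(target)
  aln <- alignPair(source, target, mode, model)
  plan <- columnPlan(aln)
  n <- nrow(plan)
  if (factorial(n) > maxOrders)
    stop("would enumerate ", factorial(n), " orders (> ", maxOrders, ")",
         call. = FALSE)
  perms <- allPermutations(n)
  lapply(seq_len(nrow(perms)), function(i)
    randomInterpolation(source, target, mode, model = model,
                        order = perms[i, ]))
}

allPermutations <- function(n) {
  if (n == 0L) return(matrix(integer(), 1L, 0L))
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Sample candidate edits from a sequence's mutation profiles
#'
#' Draws `n` edits i.i.d.: the kind by `moveMix`; substitutions at a uniform
#' position with the replacement drawn from that position's substitution
#' row, excluding the current residue (if the row has no mass elsewhere the
#' replacement is uniform over the other 19 letters); insertions at a
#' uniform slot with the residue drawn from the slot's insertion row;
#' deletions at a uniform position. Deletions are proposed as substitutions
#' when the sequence has length 1. Duplicates are allowed. Uses the current
#' RNG state: seed via `withSeed()` or `set.seed()` around the call.
#'
#' @param profiles [MutationProfiles-class] of `seq`
#' @param seq the sequence the profiles belong to
#' @param n number of edits (>= 0)
#' @param moveMix probabilities of substitution / insertion / deletion
#' @return `data.frame` of edits (columns `kind`, `position`, `residue`)
#' @export
proposeMoves <- function(profiles, seq, n, moveMix = c(0.8, 0.1, 0.1)) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  seq <- asProteinSequence(seq)
  L <- nchar(seq)
  if (nrow(profiles@substitution) != L)
    stop("profiles do not match the sequence", call. = FALSE)
  if (n == 0L) return(emptyEdits()[, c("kind", "position", "residue")])
  idx <- aaIndex(seqChars(seq))
  kinds <- sample.int(3L, n, replace = TRUE, prob = moveMix)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    k <- kinds[i]
    if (k == 3L && L == 1L) k <- 1L
    if (k == 1L) {
      pos <- sample.int(L, 1L)
      p <- profiles@substitution[pos, ]
      p[idx[pos]] <- 0
      if (sum(p) < 1e-12) p <- replace(rep(1, 20L), idx[pos], 0)
      res <- AA_STANDARD_20[sample.int(20L, 1L, prob = p)]
      out[[i]] <- newEdit("substitution", pos, res)
    } else if (k == 2L) {
      slot <- sample.int(L + 1L, 1L)
      res <- AA_STANDARD_20[sample.int(20L, 1L, prob = profiles@insertion[slot, ])]
      out[[i]] <- newEdit("insertion", slot, res)
    } else {
      out[[i]] <- newEdit("deletion", sample.int(L, 1L))
    }
  }
  do.call(rbind, out)
}

#' Stochastic beam search for a fitness-preserving path
#'
#' Maintains a beam of partial paths from the source. Each step and for each
#' beam entry, mutation profiles of the current sequence are recomputed,
#' `poolSize` candidate edits are sampled from them ([proposeMoves()]), and
#' every candidate is scored by its own pseudo-perplexity and its proximity
#' to the target. Candidates pass the viability filter if their
#' pseudo-perplexity is at most `fitnessSlack` times the larger endpoint
#' pseudo-perplexity; if none pass, the lowest-scoring candidates are
#' retained so the search never stalls silently. Survivors are ranked
#' lexicographically by (proximity, pseudo-perplexity, sequence string) and
#' the best `beamWidth` kept. A candidate equal to the target freezes as a
#' completed path. The search stops once `beamWidth` paths complete or the
#' step budget runs out. Sampling is the only stochastic element; selection
#' is deterministic given the candidates, so identical inputs, config and
#' seed reproduce the result byte-for-byte.
#'
#' @param model a [FitnessModel-class]
#' @param source,target protein sequences
#' @param config a [BeamConfig-class]
#' @return list of completed [MutationPath-class] objects (possibly empty),
#'   with attribute `diagnostics` (best proximity reached, steps run,
#'   endpoint pseudo-perplexities). Never raises on zero completions.
#' @export
beamSearchInterpolation <- function(model, source, target,
                                    config = beamConfig()) {
  validObject(config)
  source <- asProteinSequence(source); target <- asProteinSequence(target)
  meta <- list(strategy = "beam", seed = config@seed,
               config = configSignature(config), modelId = modelId(model))
  if (source == target) {
    out <- list(newPath(source, metadata = meta))
    attr(out, "diagnostics") <- list(bestProximity = 0, stepsRun = 0L)
    return(out)
  }
  est <- config@estimator
  ppOf <- function(s) ppValue(pseudoPerplexity(profilesFor(model, s, est), s))
  ppSource <- ppOf(source); ppTarget <- ppOf(target)
  ceiling <- config@fitnessSlack * max(ppSource, ppTarget)
  maxSteps <- if (is.na(config@maxSteps)) {
    4L * alignedHamming(source, target, config@proximityMode, model)
  } else config@maxSteps
  proxOf <- function(s) proximityTo(s, target, config@proximityMode, model)

  completed <- list()
  bestProx <- proxOf(source)
  stepsRun <- 0L
  withSeed(config@seed, {
    beam <- list(list(seq = source, steps = source, edits = emptyEdits()))
    for (step in seq_len(maxSteps)) {
      stepsRun <- step
      cand <- list()
      for (entry in beam) {
        prof <- profilesFor(model, entry$seq, est)
        moves <- proposeMoves(prof, entry$seq, config@poolSize, config@moveMix)
        for (r in seq_len(nrow(moves))) {
          newSeq <- tryCatch(applyEdit(entry$seq, moves[r, , drop = FALSE]),
                             error = function(e) NULL)
          if (is.null(newSeq)) next
          if (!is.null(cand[[newSeq]])) next  # dedupe, keep first occurrence
          cand[[newSeq]] <- list(seq = newSeq, parent = entry,
                                 edit = moves[r, , drop = FALSE])
        }
      }
      if (length(cand) == 0L) next
      seqs <- vapply(cand, `[[`, character(1L), "seq")
      pp <- vapply(seqs, ppOf, numeric(1L))
      prox <- vapply(seqs, proxOf, numeric(1L))
      viable <- pp <= ceiling
      keep <- if (any(viable)) which(viable) else
        order(pp)[seq_len(min(config@beamWidth, length(pp)))]
      ord <- keep[order(prox[keep], pp[keep], seqs[keep])]
      bestProx <- min(bestProx, prox[ord[1L]])
      newBeam <- list()
      for (j in ord) {
        e <- cand[[j]]
        entry <- list(seq = e$seq,
                      steps = c(e$parent$steps, e$seq),
                      edits = rbind(e$parent$edits,
                                    cbind(step = nrow(e$parent$edits) + 1L,
                                          e$edit)))
        if (e$seq == target) {
          completed[[length(completed) + 1L]] <- newPath(
            entry$steps, entry$edits[, c("kind", "position", "residue")],
            metadata = meta)
          if (length(completed) >= config@beamWidth) break
        } else if (length(newBeam) < config@beamWidth) {
          newBeam[[length(newBeam) + 1L]] <- entry
        }
      }
      if (length(completed) >= config@beamWidth || length(newBeam) == 0L) break
      beam <- newBeam
    }
  })
  attr(completed, "diagnostics") <- list(
    bestProximity = bestProx, stepsRun = stepsRun,
    ppSource = ppSource, ppTarget = ppTarget, ppCeiling = ceiling)
  completed
}

#' Generate an ensemble of beam-search paths
#'
#' Runs [beamSearchInterpolation()] with seeds `seed, seed + 1, ...` and
#' aggregates the completed paths with their traces. A seed that fails or
#' completes nothing is recorded and skipped, never propagated as an error.
#'
#' @inheritParams beamSearchInterpolation
#' @param nPaths number of seeded runs (>= 1)
#' @param segments optional named segment list forwarded to [tracePath()]
#' @return list with `paths` (list of [MutationPath-class]), `traces` (list
#'   of per-path trace `DataFrame`s), `log` (per-seed outcome
#'   `data.frame`)
#' @export
generateEnsemble <- function(model, source, target, config = beamConfig(),
                             nPaths = 10, segments = NULL) {
  if (nPaths < 1L) stop("nPaths must be >= 1", call. = FALSE)
  paths <- list(); traces <- list()
  log <- data.frame(seed = integer(), completed = integer(),
                    note = character())
  for (k in seq_len(nPaths)) {
    sk <- config@seed + k - 1L
    ck <- config; ck@seed <- as.integer(sk)
    res <- tryCatch(beamSearchInterpolation(model, source, target, ck),
                    error = function(e) structure(list(),
                      diagnostics = list(note = conditionMessage(e))))
    note <- if (length(res) == 0L) "no completion" else ""
    log <- rbind(log, data.frame(seed = sk, completed = length(res),
                                 note = note))
    for (p in res) {
      paths[[length(paths) + 1L]] <- p
      traces[[length(traces) + 1L]] <-
        tracePath(model, p, segments = segments,
                  mode = config@proximityMode, estimator = config@estimator)
    }
  }
  list(paths = paths, traces = traces, log = log)
}
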