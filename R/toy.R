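# Closed-form toy fitness landscape: a mixture of position-weight-matrix
# families with leave-one-out conditionals, plus fixture generators and the
# exhaustively enumerable edit universe used as an exact search oracle.

#' Build a toy fitness landscape
#'
#' Constructs a [ToyLandscape-class]: `nComponents` position weight matrices
#' of reference length `LRef` over the 20-letter alphabet (optionally with
#' essentially all mass restricted to `alphabetSubset`), drawn from seeded
#' Gaussian logits scaled by `sharpness`. `sharpness = 0` gives the uniform
#' landscape (every sequence scores the alphabet size); large `sharpness`
#' concentrates each row on one consensus residue, driving the consensus
#' sequence's pseudo-perplexity toward 1. With two or more components, later
#' components redraw a seeded fraction `componentDivergence` of positions
#' from component 1, creating distinct sequence "families" whose blends score
#' poorly under every component — the fitness canyon that separates random
#' interpolation from beam search.
#'
#' Per-position conditionals weight each component by the leave-one-out
#' likelihood of the rest of the sequence, so the distribution at a position
#' never depends on the residue occupying it and the single-pass OFS readout
#' equals the masked-marginal scan exactly.
#'
#' @param LRef reference (family) length, >= 2
#' @param sharpness non-negative logit scale
#' @param seed integer seed (the landscape is deterministic given it)
#' @param nComponents number of PSSM families in the mixture
#' @param componentDivergence fraction of positions redrawn in components
#'   2..K
#' @param alphabetSubset optional character vector of letters to which the
#'   families restrict their mass (used for enumerable universes)
#' @param indelPenalty per-residue length-deviation penalty rate; conditional
#'   rows of a length-L sequence are mixed toward uniform with weight
#'   `1 - exp(-indelPenalty * |L - LRef|)`
#' @param temperature flattens (> 1) or sharpens (< 1) the final conditionals
#' @return a [ToyLandscape-class]
#' @export
#' @examples
#' m <- makeToyLandscape(8, sharpness = 3, seed = 42)
#' consensusSequence(m)
makeToyLandscape <- function(LRef, sharpness = 3, seed = 1, nComponents = 1,
                             componentDivergence = 0.5, alphabetSubset = NULL,
                             indelPenalty = 0.3, temperature = 1) {
  LRef <- as.integer(LRef)
  if (is.na(LRef) || LRef < 2L) stop("LRef must be >= 2", call. = FALSE)
  if (sharpness < 0) stop("sharpness must be >= 0", call. = FALSE)
  if (nComponents < 1L) stop("need at least one component", call. = FALSE)
  mask <- rep(0, 20L)
  if (!is.null(alphabetSubset)) {
    keep <- aaIndex(alphabetSubset)
    if (length(keep) < 2L) stop("alphabetSubset needs >= 2 letters", call. = FALSE)
    mask[-keep] <- -40  # ~4e-18 relative mass outside the subset
  }
  logp <- withSeed(seed, {
    arr <- array(0, dim = c(LRef, 20L, nComponents))
    base <- sharpness * matrix(stats::rnorm(LRef * 20L), LRef, 20L)
    arr[, , 1L] <- base
    if (nComponents > 1L) {
      nDiv <- max(1L, round(componentDivergence * LRef))
      for (k in 2:nComponents) {
        lk <- base
        redraw <- sort(sample.int(LRef, nDiv))
        lk[redraw, ] <- sharpness * matrix(stats::rnorm(nDiv * 20L), nDiv, 20L)
        arr[, , k] <- lk
      }
    }
    arr
  })
  for (k in seq_len(nComponents)) {
    lk <- sweep(logp[, , k, drop = FALSE][, , 1L], 2L, -mask, "-")
    m <- apply(lk, 1L, max)
    p <- exp(sweep(lk, 1L, m, "-"))
    logp[, , k] <- log(rowNormalize(p))
  }
  new("ToyLandscape",
      alphabetOrder = AA_STANDARD_20, embeddingDim = 21L,
      logPssm = logp, weights = rep(1 / nComponents, nComponents),
      temperature = temperature, indelPenalty = indelPenalty,
      id = sprintf("toy-L%d-K%d-sh%g-seed%d", LRef, nComponents, sharpness,
                   as.integer(seed)))
}

#' @describeIn makeToyLandscape the argmax sequence of one component's PSSM
#' @param landscape a [ToyLandscape-class]
#' @param component component index
#' @export
consensusSequence <- function(landscape, component = 1L) {
  lp <- landscape@logPssm[, , component]
  paste(AA_STANDARD_20[apply(lp, 1L, which.max)], collapse = "")
}

# Per-position base distributions (L x 20, probabilities) of one component
# for a sequence of length L: centered placement of the PSSM window, uniform
# rows outside it, then uniform mixing by the length-deviation penalty.
# Placement is residue-independent, which keeps the conditionals exactly
# memoryless in the queried position.
toyBaseRows <- function(landscape, L, k) {
  LRef <- dim(landscape@logPssm)[1L]
  p <- matrix(1 / 20, L, 20L)
  if (L <= LRef) {
    o <- (LRef - L) %/% 2L
    p[] <- exp(landscape@logPssm[o + seq_len(L), , k])
  } else {
    o <- (L - LRef) %/% 2L
    p[o + seq_len(LRef), ] <- exp(landscape@logPssm[, , k])
  }
  lam <- 1 - exp(-landscape@indelPenalty * abs(L - LRef))
  (1 - lam) * p + lam / 20
}

applyTemperature <- function(p, temperature) {
  if (temperature == 1) return(p)
  q <- p^(1 / temperature)
  q / sum(q)
}

#' @rdname backend-generics
#' @export
setMethod("modelId", "ToyLandscape", function(model) model@id)

#' @rdname backend-generics
#' @export
setMethod("tokenLogits", "ToyLandscape", function(model, seq) {
  seq <- asProteinSequence(seq)
  idx <- aaIndex(seqChars(seq))
  L <- length(idx)
  K <- length(model@weights)
  logB <- lapply(seq_len(K), function(k) log(toyBaseRows(model, L, k)))
  # leave-one-out component log-weights, one row per position
  v <- vapply(seq_len(K), function(k) logB[[k]][cbind(seq_len(L), idx)],
              numeric(L))
  v <- matrix(v, nrow = L)
  loo <- sweep(-v, 2L, colSums(v) + log(model@weights), "+")  # L x K
  out <- matrix(0, L, 20L)
  for (i in seq_len(L)) {
    w <- exp(loo[i, ] - max(loo[i, ]))
    mix <- rep(0, 20L)
    for (k in seq_len(K)) mix <- mix + w[k] * exp(logB[[k]][i, ])
    out[i, ] <- applyTemperature(mix / sum(mix), model@temperature)
  }
  log(pmax(out, 1e-300))
})

#' @rdname backend-generics
#' @export
setMethod("maskedTokenLogits", "ToyLandscape", function(model, seq, pos) {
  # independent code path from tokenLogits: explicit exclusion of `pos`
  seq <- asProteinSequence(seq)
  idx <- aaIndex(seqChars(seq))
  L <- length(idx)
  if (pos < 1L || pos > L) stop("masked position out of range", call. = FALSE)
  K <- length(model@weights)
  lw <- numeric(K)
  rows <- matrix(0, K, 20L)
  for (k in seq_len(K)) {
    B <- toyBaseRows(model, L, k)
    ll <- 0
    for (j in seq_len(L)) if (j != pos) ll <- ll + log(B[j, idx[j]])
    lw[k] <- log(model@weights[k]) + ll
    rows[k, ] <- B[pos, ]
  }
  w <- exp(lw - max(lw))
  mix <- colSums(rows * w)
  matrix(log(pmax(applyTemperature(mix / sum(mix), model@temperature), 1e-300)),
         nrow = 1L)
})

#' @rdname backend-generics
#' @export
setMethod("insertionLogits", "ToyLandscape", function(model, seq) {
  seq <- asProteinSequence(seq)
  idx <- aaIndex(seqChars(seq))
  L <- length(idx)
  K <- length(model@weights)
  out <- matrix(0, L + 1L, 20L)
  # prefix sums over "residue r sits at position r" vs "shifted to r + 1"
  a <- matrix(0, L, K); b <- matrix(0, L, K)
  Bp <- lapply(seq_len(K), function(k) toyBaseRows(model, L + 1L, k))
  for (k in seq_len(K)) {
    lB <- log(Bp[[k]])
    if (L > 0L) {
      a[, k] <- lB[cbind(seq_len(L), idx)]
      b[, k] <- lB[cbind(seq_len(L) + 1L, idx)]
    }
  }
  ca <- rbind(0, apply(a, 2L, cumsum))       # ca[j, k] = sum of a over r < j
  cb <- rbind(0, apply(b, 2L, cumsum))
  cbTot <- cb[L + 1L, ]
  for (j in seq_len(L + 1L)) {
    lw <- log(model@weights) + ca[j, ] + (cbTot - cb[j, ])
    w <- exp(lw - max(lw))
    mix <- rep(0, 20L)
    for (k in seq_len(K)) mix <- mix + w[k] * Bp[[k]][j, ]
    out[j, ] <- log(pmax(applyTemperature(mix / sum(mix), model@temperature),
                         1e-300))
  }
  out
})

#' @rdname backend-generics
#' @export
setMethod("maskedInsertionLogits", "ToyLandscape", function(model, seq, slot) {
  seq <- asProteinSequence(seq)
  idx <- aaIndex(seqChars(seq))
  L <- length(idx)
  if (slot < 1L || slot > L + 1L) stop("insertion slot out of range", call. = FALSE)
  K <- length(model@weights)
  lw <- numeric(K)
  rows <- matrix(0, K, 20L)
  for (k in seq_len(K)) {
    B <- toyBaseRows(model, L + 1L, k)
    ll <- 0
    for (r in seq_len(L)) {
      pos <- if (r < slot) r else r + 1L
      ll <- ll + log(B[pos, idx[r]])
    }
    lw[k] <- log(model@weights[k]) + ll
    rows[k, ] <- B[slot, ]
  }
  w <- exp(lw - max(lw))
  mix <- colSums(rows * w)
  matrix(log(pmax(applyTemperature(mix / sum(mix), model@temperature), 1e-300)),
         nrow = 1L)
})

#' @rdname backend-generics
#' @export
setMethod("residueEmbeddings", "ToyLandscape", function(model, seq) {
  seq <- asProteinSequence(seq)
  idx <- aaIndex(seqChars(seq))
  L <- length(idx)
  e <- matrix(0, L, 21L)
  e[cbind(seq_len(L), idx)] <- 1
  e[, 21L] <- seq_len(L) / L
  colnames(e) <- c(AA_STANDARD_20, "relpos")
  e
})

setMethod("show", "ToyLandscape", function(object) {
  d <- dim(object@logPssm)
  cat(sprintf("ToyLandscape '%s': LRef %d, %d component(s), temperature %g, indel penalty %g\n",
              object@id, d[1L], d[3L], object@temperature, object@indelPenalty))
})

#' Sample a high-fitness endpoint pair from a toy landscape
#'
#' Returns a source/target pair of reference-length sequences whose aligned
#' divergence matches the requested fraction of columns to within one column
#' and whose pseudo-perplexities sit below a viability ceiling. The source is
#' component 1's consensus. Target positions to change are chosen (seeded)
#' preferentially where the last component's consensus disagrees with the
#' source, so two-family landscapes yield one endpoint per family; remaining
#' positions switch to the next-best residue of the scoring component.
#'
#' For a multi-family landscape, requested divergences far from both 0 and
#' the family divergence force blended targets that sit in the inter-family
#' fitness canyon; those exceed the ceiling and error — by construction, not
#' by accident.
#'
#' @param landscape a [ToyLandscape-class]
#' @param divergence requested fraction of differing columns, in (0, 1]
#' @param seed integer seed
#' @param ceiling viability ceiling on endpoint pseudo-perplexity (default 6,
#'   well below the uniform value of 20)
#' @return list with `source`, `target`, `positions`, `pp` (named endpoint
#'   pseudo-perplexities)
#' @export
sampleEndpointPair <- function(landscape, divergence, seed = 1, ceiling = 6) {
  if (divergence <= 0 || divergence > 1)
    stop("divergence must be in (0, 1]", call. = FALSE)
  L <- dim(landscape@logPssm)[1L]
  K <- length(landscape@weights)
  nDiff <- max(1L, round(divergence * L))
  if (nDiff > L) stop("requested divergence unreachable at LRef ", L, call. = FALSE)
  src <- seqChars(consensusSequence(landscape, 1L))
  srcIdx <- aaIndex(src)
  lpK <- landscape@logPssm[, , K]
  consK <- apply(lpK, 1L, which.max)
  nextBest <- function(lp, i, avoid)
    setdiff(order(lp[i, ], decreasing = TRUE), avoid)[1L]
  tgt <- withSeed(seed, {
    if (K > 1L) {
      # cross-family pair: start from the last component's consensus and
      # nudge the differing-column count to exactly nDiff
      t <- consK
      d0 <- which(t != srcIdx)
      if (nDiff > length(d0)) {
        extra <- sample(setdiff(seq_len(L), d0), nDiff - length(d0))
        for (i in extra) t[i] <- nextBest(lpK, i, srcIdx[i])
      } else if (nDiff < length(d0)) {
        revert <- sample(d0, length(d0) - nDiff)
        t[revert] <- srcIdx[revert]
      }
      t
    } else {
      lp1 <- landscape@logPssm[, , 1L]
      pos <- sample.int(L, nDiff)
      t <- srcIdx
      for (i in pos) t[i] <- nextBest(lp1, i, srcIdx[i])
      t
    }
  })
  source <- paste(src, collapse = "")
  target <- paste(AA_STANDARD_20[tgt], collapse = "")
  pos <- which(tgt != srcIdx)
  pp <- c(source = ppValue(pseudoPerplexity(ofsProfiles(landscape, source), source)),
          target = ppValue(pseudoPerplexity(ofsProfiles(landscape, target), target)))
  if (any(pp > ceiling))
    stop(sprintf("endpoint viability ceiling exceeded (pp = %.2f/%.2f > %g); ",
                 pp[1L], pp[2L], ceiling),
         "lower the divergence or soften the landscape", call. = FALSE)
  list(source = source, target = target, positions = pos, pp = pp)
}

#' Enumerate the full single-edit universe of a small toy landscape
#'
#' Builds the complete graph of sequences over `alphabetSubset` with lengths
#' in `[LMin, LMax]` (nodes) connected by single admissible moves (arcs), with
#' each node's pseudo-perplexity under `landscape`. Supports exact bottleneck
#' (min-max pseudo-perplexity) path queries via [bottleneckOptimum()] —
#' the exhaustive oracle that upper-bounds what any beam search can achieve.
#' Refuses universes above `guard` nodes with a size estimate.
#'
#' @param landscape a [ToyLandscape-class]
#' @param LMax,LMin length range of enumerated sequences (set `LMin = LMax`
#'   for a substitution-only universe)
#' @param alphabetSubset letters spanned by the universe
#' @param guard maximum node count (default 1e6; keep far lower in practice)
#' @return list with `nodes` (character), `pp` (numeric), `edges` (2-column
#'   index matrix), `graph` (igraph)
#' @export
enumerateUniverse <- function(landscape, LMax, alphabetSubset,
                              LMin = LMax, guard = 1e6) {
  ab <- unique(alphabetSubset)
  aaIndex(ab)
  lens <- LMin:LMax
  sizes <- length(ab)^lens
  if (sum(sizes) > guard)
    stop("universe would contain ", sum(sizes), " nodes (> guard ", guard, ")",
         call. = FALSE)
  nodes <- unlist(lapply(lens, function(L) {
    g <- do.call(expand.grid, c(rep(list(ab), L), stringsAsFactors = FALSE))
    do.call(paste0, g)
  }))
  pp <- vapply(nodes, function(s)
    ppValue(pseudoPerplexity(ofsProfiles(landscape, s), s)), numeric(1L),
    USE.NAMES = FALSE)
  d <- utils::adist(nodes)
  edges <- which(d == 1L & upper.tri(d), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(nodes) - igraph::vcount(g)))
  igraph::V(g)$name <- nodes
  list(nodes = nodes, pp = pp, edges = edges, graph = g)
}

#' Exact bottleneck (min-max pseudo-perplexity) path between two nodes
#'
#' The optimum over ALL single-edit paths of the maximum node
#' pseudo-perplexity (endpoints included): the smallest threshold t such that
#' source and target are connected in the subgraph of nodes with
#' pseudo-perplexity <= t. Binary search over the sorted node scores with an
#' igraph connectivity check per probe.
#'
#' @param universe result of [enumerateUniverse()]
#' @param source,target node sequences (must be in the universe)
#' @return list with `value` (the bottleneck optimum) and `path` (one optimal
#'   node sequence)
#' @export
bottleneckOptimum <- function(universe, source, target) {
  si <- match(source, universe$nodes)
  ti <- match(target, universe$nodes)
  if (is.na(si) || is.na(ti))
    stop("source/target not in the enumerated universe", call. = FALSE)
  thr <- sort(unique(universe$pp))
  thr <- thr[thr >= max(universe$pp[si], universe$pp[ti])]
  connectedAt <- function(t) {
    keep <- which(universe$pp <= t)
    sub <- igraph::induced_subgraph(universe$graph, keep)
    s2 <- match(universe$nodes[si], igraph::V(sub)$name)
    t2 <- match(universe$nodes[ti], igraph::V(sub)$name)
    comp <- igraph::components(sub)$membership
    comp[s2] == comp[t2]
  }
  lo <- 1L; hi <- length(thr)
  if (!connectedAt(thr[hi]))
    stop("endpoints are not connected in the universe", call. = FALSE)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (connectedAt(thr[mid])) hi <- mid else lo <- mid + 1L
  }
  tstar <- thr[lo]
  keep <- which(universe$pp <= tstar)
  sub <- igraph::induced_subgraph(universe$graph, keep)
  p <- igraph::shortest_paths(sub,
                              match(universe$nodes[si], igraph::V(sub)$name),
                              match(universe$nodes[ti], igraph::V(sub)$name))
  list(value = tstar, path = igraph::V(sub)$name[p$vpath[[1L]]])
}
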