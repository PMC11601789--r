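---
title: "Fitness-preserving mutational paths between protein sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitness-preserving mutational paths between protein sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protpath)
```

## The problem

Neutral networks — sets of sequences of near-identical fitness connected by
single-residue mutations — are well documented locally, but whether two
*distantly* related proteins can be joined by a chain of viable
single-residue changes is an open question about the global connectivity of
protein sequence space. `protpath` implements a computational version of
that question: given a source and a target protein, find an ordered series
of intermediates, each one substitution, insertion or deletion away from the
last, whose predicted fitness stays as high as the traversal allows.

Three primitives drive the search:

1. **Fitness.** A pluggable sequence model provides, for a sequence of
   length $L$, a per-position substitution distribution ($L \times 20$) and
   an insertion-slot distribution ($(L{+}1) \times 20$). The fitness scalar
   is the *pseudo-perplexity*

   $$\mathrm{PP}(s) = \exp\!\Big(\tfrac1L \sum_{i=1}^{L} -\log p_i(s_i)\Big),$$

   the exponential of the mean negative log-probability the model assigns to
   the sequence's own residues. Lower is fitter; $\mathrm{PP}=1$ means the
   model is certain of every residue and a uniform model gives
   $\mathrm{PP}=20$. Profiles are read out of **one unmasked forward pass**
   (the "One Fell Swoop" readout, `ofsProfiles()`); the classical
   masked-marginal scan (`maskedMarginalProfiles()`, one masked pass per
   position) is retained as the reference estimator.

2. **Proposals.** Candidate mutations are sampled from those same profiles
   (`proposeMoves()`): substitutions at a uniform position with the
   replacement drawn from the position's substitution row, insertions from
   the slot's insertion row, deletions uniformly.

3. **Proximity.** Candidates are steered toward the target with a global
   alignment distance (`proximityTo()`): the aligned hamming distance under
   BLOSUM62 scoring, or an embedding-weighted variant in which column
   $(i,j)$ scores the cosine similarity of the two residues' model
   embeddings.

The search itself (`beamSearchInterpolation()`) is a stochastic beam search:
sampling is random, selection is deterministic. Each step, every beam entry
proposes `poolSize` edits; candidates whose pseudo-perplexity exceeds
`fitnessSlack` times the larger endpoint value are discarded (if none
survive, the least-bad are kept so the search can cross fitness canyons
rather than stall); survivors are ranked lexicographically by (proximity,
pseudo-perplexity, sequence string) and the best `beamWidth` kept. A
candidate equal to the target freezes as a completed path. The
random-order baseline (`randomInterpolation()`) applies the endpoint
alignment's non-matching columns in a random order and therefore always
needs exactly `alignedHamming(source, target)` steps.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `beamWidth` | 5 | partial paths kept per step |
| `poolSize` | 50 | proposals per beam entry per step |
| `fitnessSlack` | 1.05 | viability ceiling, × the larger endpoint PP |
| `maxSteps` | 4 × aligned hamming | step budget |
| `moveMix` | 0.8 / 0.1 / 0.1 | substitution / insertion / deletion proposal rates |
| `proximityMode` | `"identity"` | alignment scoring for the ranking |

None of these are dictated by the method; they are desk-scale defaults,
recorded in every output's provenance. The default slack of 1.05 encodes
"intermediates stay essentially between the endpoint values", which is what
close homolog pairs support. Distant pairs *must* cross a fitness canyon;
for those a larger slack (the analyses here use up to 6) is the honest
configuration — the filter then bounds how deep the canyon may get, and the
minmax analytics report how deep it actually got.

Alignment scoring is BLOSUM62 with affine gaps (open 10, extend 1, a
length-$k$ gap costing $10 + k$), the EMBOSS-style convention, and
deterministic traceback (diagonal, then up, then left). Embedding-mode
column scores are mapped as $12\cos - 4$ so the same gap penalties remain
meaningful.

## The toy world and what a green test establishes

No neural network ships with the package. The test universe
(`makeToyLandscape()`) is a closed-form landscape: a mixture of $K$
position-weight-matrix "families" drawn from seeded Gaussian logits scaled
by `sharpness`. The conditional at position $i$ weights each family by the
leave-one-out likelihood of the *rest* of the sequence:

$$p_i(a \mid s_{-i}) \propto \sum_k w_k \Big(\prod_{j \ne i} B_k(j, s_j)\Big) B_k(i, a).$$

Because the queried position is excluded from the weights, the distribution
at a position never depends on the residue occupying it, so the single-pass
OFS readout and the masked-marginal scan coincide **exactly**. That is a
design choice, not an accident: it lets the suite pin the estimator plumbing
(shapes, renormalisation, masking bookkeeping) with a 1e-6 equality test.
What it deliberately does *not* establish is the quality of the OFS
approximation for a real transformer, where context does depend on the
queried token — that question belongs to the model being wrapped, not to
this package.

Design choices inside the toy world:

* **Indels.** Sequences whose length deviates from the reference length are
  scored against a *centred* placement of the PSSM window, with conditionals
  mixed toward uniform with weight $1 - e^{-\rho\,|L - L_\mathrm{ref}|}$
  (`indelPenalty` $\rho$, default 0.3). A best-scoring placement was
  considered and rejected: the optimal offset would depend on the residue at
  the queried position, silently breaking the exact OFS/masked equivalence
  the tests rely on. Centred placement keeps the model memoryless and
  $O(L)$ while still making indels consequential.
* **The corridor fixture.** A single-PSSM landscape is position-wise
  additive, so every edit order between two viable endpoints scores the
  same — random and beam interpolation would tie, and no fitness canyon can
  exist. A two-family mixture creates the canyon: blends of the two
  consensus sequences are poorly explained by both families. On that fixture
  the random baseline's median bottleneck (max PP along the path) is ~19
  while the beam ensemble's is ~5–6, the qualitative gap the search is
  supposed to produce.
* **Endpoint pairs.** `sampleEndpointPair()` returns family consensus
  sequences nudged to the requested divergence. On a multi-family landscape
  a divergence far from both 0 and the family divergence *necessarily*
  lands in the canyon; the function then fails its viability ceiling loudly
  rather than returning a low-fitness "endpoint".
* **Scale.** Toy fixtures use reference lengths 12–50 and the real-protein
  analyses in the literature run to hundreds of residues and ESM2-scale
  models; everything here is deliberately desk-scale (whole suite in
  minutes, one CPU) and the backend interface (`FitnessModel`) is where a
  real model plugs in.

## Numerical choices

* Probabilities are floored at $10^{-12}$ before logs; clamps are counted
  in the score's `nClamped` field and warned about, never silent.
* Profile rows must sum to 1 within $10^{-6}$ (class validity).
* Segment scores reuse the *full-sequence* profiles restricted to the
  segment — the segment is not excised and re-scored, so segment and whole
  scores satisfy the geometric-mean identity
  $\mathrm{PP}_{\text{full}} = (\mathrm{PP}_A^{|A|}\,\mathrm{PP}_B^{|B|})^{1/(|A|+|B|)}$
  for a disjoint cover, which the tests verify to $10^{-9}$. Whether local
  domain fitness should instead be scored on the excised domain is a
  modelling question; the full-profile convention was chosen because it
  keeps the segment trace consistent with the whole-sequence trace.
* Segments are specified in source coordinates (1-based, closed, the
  R/Bioconductor convention used throughout) and carried through indels by
  tracking each source residue's current position; a segment whose residues
  are all deleted is reported as `NA`.
* All randomness is Mersenne-Twister under explicit integer seeds,
  scoped with an internal seed guard that restores the caller's RNG state;
  identical inputs, config and seed reproduce outputs byte-for-byte.
* Paths of different lengths are compared on a normalised step axis
  (fraction of path completed, linear interpolation) in
  `ensembleSummary()`; with a single trace the grid coincides with its own
  steps, so the summary is exact.
* Beam-search ties break lexicographically (proximity, then PP, then the
  sequence string); DP ties break diagonal-first. Both are arbitrary but
  fixed, for reproducibility.

## The exact oracle and the saturation equality

`enumerateUniverse()` builds the complete single-edit graph over a small
alphabet and length range, and `bottleneckOptimum()` computes the exact
min-max-PP path value by threshold search over node scores with a
connectivity check. Any path's bottleneck — beam-found or not — is bounded
below by this optimum, and the suite asserts it. The converse (beam attains
the optimum) is **not** guaranteed by width alone: selection ranks by
proximity, so even a beam that retains every viable candidate may complete
through a worse-bottleneck path if the viability ceiling allows one. The
saturation test therefore sets the ceiling *at* the oracle optimum: the
search must still complete (completeness under a saturating beam), and any
completed path then has bottleneck equal to the optimum.

## Known limitations

* Pseudo-perplexity is a proxy; even for real language models it is an
  imperfect fitness measure, and the toy landscape only emulates its
  *interface*, not protein statistics (no epistasis beyond the mixture, no
  realistic indel process).
* The ESM2-class backend is an interface, not an implementation: selecting
  it reports "backend unavailable". The two reference UniProt endpoint
  pairs are download-gated for the same reason — nothing third-party is
  bundled.
* The beam search is greedy in proximity; it can fail to complete within
  its step budget (reported as diagnostics, exit code 3 from the CLI) and
  offers no optimality guarantee beyond the oracle bound above.
* `randomInterpolation()` executes a fixed column plan of the original
  endpoint alignment (positions re-indexed after each indel) rather than
  re-aligning every step; this is what makes its step count exactly the
  aligned hamming distance, and it is recorded in the path's metadata.
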