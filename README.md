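# protpath

Generate stepwise single-residue mutational paths between two protein
sequences while keeping the predicted fitness of every intermediate as high
as the traversal allows.

Neutral networks connect sequences of near-identical fitness through single
mutations, but whether *distantly* related proteins — pairs that share
little sequence and sometimes not even a fold — can be joined by such a
chain is a question about the global connectivity of protein sequence
space. `protpath` is a toolkit for asking it computationally: the
intermediates of a path differ by one substitution, insertion or deletion
per step, and their plausibility is scored by a pluggable sequence model.

## The method

For a sequence *s* of length *L*, the model supplies a per-position
substitution distribution (L×20) and an insertion-slot distribution
((L+1)×20), read out of **one** unmasked forward pass (the "One Fell Swoop"
readout, `ofsProfiles()`; the masked-marginal scan is kept as the reference
estimator). The fitness scalar is the **pseudo-perplexity**

PP(s) = exp( (1/L) Σᵢ −log pᵢ(sᵢ) ),

lower = fitter; 1 is the floor and a uniform model scores 20. Three
primitives drive a **stochastic beam search** (`beamSearchInterpolation()`):
the profiles propose candidate mutations, PP filters them against a
viability ceiling (`fitnessSlack` × the larger endpoint PP), and an
alignment-based **proximity** to the target (BLOSUM62 or
embedding-cosine-weighted columns, affine gaps) ranks the survivors. A
**random interpolation** baseline (`randomInterpolation()`) applies the
endpoint alignment's non-matching columns in random order and always needs
exactly `alignedHamming(source, target)` steps. Path analytics
(`tracePath()`, `identityCurve()`, `ensembleSummary()`, `minmaxSelect()`)
reproduce the per-step fitness traces, identity curves and bottleneck
(min-max) path selection numerically.

No model weights are bundled: a closed-form **toy landscape**
(`makeToyLandscape()`) — a mixture of position-weight-matrix families with
leave-one-out conditionals — makes the whole pipeline runnable and testable
offline, including an exhaustively enumerable edit universe with an exact
bottleneck-path oracle (`enumerateUniverse()`, `bottleneckOptimum()`). An
ESM2-class neural backend plugs in through the same `FitnessModel`
interface but is not shipped.

## Worked example

Two protein families joined by a fitness canyon, endpoints five aligned
columns apart:

```r
library(protpath)

land <- makeToyLandscape(12, sharpness = 4, seed = 7, nComponents = 2)
pair <- sampleEndpointPair(land, divergence = 0.4, seed = 3)
pair$source; pair$target        # "ASCGEFIHTAEA" -> "DSCTEFIHWQEC"
round(pair$pp, 3)               # source 1.650, target 1.767
alignedHamming(pair$source, pair$target)   # 5

paths <- beamSearchInterpolation(land, pair$source, pair$target,
          beamConfig(beamWidth = 3, poolSize = 60, fitnessSlack = 6, seed = 1))
length(paths)                   # 3 completed paths
tracePath(land, paths[[1]])
```

The trace of the first completed path (13 steps — the beam may take detours
the 5-step random route cannot afford):

```
 step   pp identity_source identity_target proximity
    0 1.65          100.00           58.33         5
    1 1.85           91.67           66.67         4
  ...
    9 3.35           75.00           75.00         3
   10 9.54           66.67           83.33         2
   11 2.33           58.33           91.67         1
   12 1.77           58.33          100.00         0
```

The path crosses the inter-family canyon briefly (PP peaks at 9.5 on one
step) and lands at the target's own PP. The random baseline from the same
endpoints takes its mandatory 5 steps but peaks at PP ≈ 20.2 — the level of
a sequence the model finds entirely implausible. Step 9 is a chimeric
intermediate: 75% identical to *both* endpoints at once.

A command-line wrapper over the same functions ships in
`inst/cli/protpath.R`:

```sh
Rscript inst/cli/protpath.R interpolate --strategy beam --n-paths 10 \
    --seed 1 --fitness-slack 6 --out run1 source.fasta target.fasta
Rscript inst/cli/protpath.R score --segments nterm=1:60,cterm=61:120 seqs.fasta
Rscript inst/cli/protpath.R analyze --minmax-column pp_cterm --out analysis run1
```

Every run writes a JSON manifest (inputs, seeds, backend, config); reruns
with identical flags are byte-identical on path and trace files.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline demonstration from scratch: the 100-path
random baseline versus a 10-seed beam ensemble on the two-family corridor
fixture (median of each path's maximum pseudo-perplexity), and the beam
search against the exact bottleneck optimum on the fully enumerated
4-letter edit universe, then writes the JSON report to `--out`.
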