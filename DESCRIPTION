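Package: protpath
Title: Fitness-Preserving Mutational Paths Between Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates stepwise single-residue mutational paths (substitutions,
    insertions and deletions) between two protein sequences while keeping the
    predicted fitness of every intermediate as high as the traversal allows.
    Fitness is quantified as the pseudo-perplexity of a sequence under
    per-position substitution profiles read out from a pluggable sequence
    model in a single unmasked forward pass (the One Fell Swoop readout), with
    the masked-marginal scan retained as the reference estimator. A stochastic
    beam search samples candidate mutations from the model's substitution and
    insertion profiles and steers toward the target with an alignment-based
    proximity measure that can weight alignment columns by residue-embedding
    cosine similarity. A random-order interpolation baseline, path analytics
    (fitness traces, per-domain segment scores, identity curves, minmax path
    selection) and a closed-form toy fitness landscape with an exhaustively
    enumerable edit graph make the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    igraph,
    jsonlite,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
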