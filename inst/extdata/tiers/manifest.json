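{
  "description": "Toy-scale endpoint-pair fixtures at three identity tiers (emulating outright / distant / speculative homolog pairs).",
  "generator": "m <- makeToyLandscape(50, sharpness = 3, seed = SEED, nComponents = 2, componentDivergence = DIV + 0.06); sampleEndpointPair(m, divergence = DIV, seed = SEED, ceiling = 6)",
  "landscape": {
    "LRef": 50,
    "sharpness": 3,
    "nComponents": 2
  },
  "tiers": {
    "high": {
      "divergence": 0.64,
      "seed": 41,
      "alignedHamming": 32,
      "percentIdentity": 36,
      "pp": {
        "source": 1.848932,
        "target": 2.777359
      }
    },
    "medium": {
      "divergence": 0.82,
      "seed": 42,
      "alignedHamming": 41,
      "percentIdentity": 19.6078431372549,
      "pp": {
        "source": 1.764619,
        "target": 1.94903
      }
    },
    "low": {
      "divergence": 0.88,
      "seed": 43,
      "alignedHamming": 44,
      "percentIdentity": 16.9811320754717,
      "pp": {
        "source": 1.616887,
        "target": 1.980368
      }
    }
  }
}
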