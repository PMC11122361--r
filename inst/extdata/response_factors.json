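{
  "comment": "Relative molar FID response factors for PMAAs, effective-carbon-number based, keyed by canonical linkage label. 3-Galp, 4-AnGalp and 2,4-AnGalp carry experimentally anchored values; the increment rule covers acetyl-for-methyl substitution at O-2 (+0.05).",
  "entries": {
    "t-Araf": 0.58,
    "t-Xylp": 0.58,
    "2-Xylp": 0.67,
    "3-Xylp": 0.67,
    "4-Xylp": 0.67,
    "2,4-Xylp": 0.75,
    "3,4-Xylp": 0.75,
    "t-Glcp": 0.67,
    "t-Galp": 0.67,
    "2-Manp": 0.75,
    "3-Galp": 0.74,
    "4-Galp": 0.75,
    "6-Galp": 0.75,
    "4-Glcp": 0.75,
    "4-AnGalp": 0.49,
    "2,4-AnGalp": 0.54,
    "2,3-Galp": 0.83,
    "2,4-Galp": 0.83,
    "3,4-Galp": 0.83,
    "3,6-Galp": 0.83,
    "4,6-Galp": 0.83,
    "4,6-Glcp": 0.83,
    "2,3,6-Galp": 0.92,
    "2,4,6-Galp": 0.92,
    "3,4,6-Galp": 0.92,
    "2,3,4,6-Galp": 1.0
  },
  "increment_rules": [
    { "position": 2, "delta": 0.05 }
  ]
}
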