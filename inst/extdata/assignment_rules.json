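{
  "comment": "Default linkage-to-polysaccharide assignment rules, applied in order against the pool of relative linkage percentages. branch_expansion: Floridean starch from the 4,6-Glcp branch point at one branch per `degree` residues, pulling (degree - 1) x branch percent of backbone 4-Glcp out of the cellulose pool (floored at what is available). pair: agarose as 2 x min of its two alternating units, consuming equal shares. sum: plain totals of the listed linkages. sugar: everything left under the listed monosaccharides. Whatever remains falls into the residual bucket.",
  "residual": "other",
  "rules": [
    {
      "name": "floridean_starch",
      "type": "branch_expansion",
      "branch": "4,6-Glcp",
      "backbone": "4-Glcp",
      "degree": 4.8
    },
    {
      "name": "agarose",
      "type": "pair",
      "labels": ["4-AnGalp", "3-Galp"]
    },
    {
      "name": "mixed_linkage_xylan",
      "type": "sum",
      "labels": ["3-Xylp", "4-Xylp", "2,4-Xylp", "3,4-Xylp"]
    },
    {
      "name": "cellulose",
      "type": "sum",
      "labels": ["4-Glcp"]
    },
    {
      "name": "other_galactans",
      "type": "sugar",
      "sugars": ["Gal"],
      "include_anhydro": true
    }
  ]
}
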