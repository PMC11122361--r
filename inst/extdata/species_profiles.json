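{
  "comment": "Synthetic study design: relative linkage compositions (percent) for six red seaweed species, used as ground truth by the chromatogram simulator. Major values follow published FID-based compositions for these species; minor linkages are plausible fill chosen so each profile sums to 100.",
  "profiles": {
    "Palmaria_palmata": {
      "4-Xylp": 54, "3-Xylp": 18, "2,4-Xylp": 1, "3,4-Xylp": 1, "t-Xylp": 1,
      "3-Galp": 4, "4-Galp": 2, "3,4-Galp": 2, "3,6-Galp": 1,
      "4-AnGalp": 2, "2,4-AnGalp": 1,
      "4-Glcp": 5, "4,6-Glcp": 1, "t-Glcp": 1,
      "2-Manp": 3, "t-Araf": 3
    },
    "Gracilariopsis_sp": {
      "3-Galp": 40, "4-AnGalp": 27, "2,4-AnGalp": 1,
      "4-Galp": 2, "2,4-Galp": 1, "3,4-Galp": 1, "4,6-Galp": 3,
      "2,4,6-Galp": 1, "2,3,4,6-Galp": 1, "t-Galp": 1,
      "4-Glcp": 10, "4,6-Glcp": 1,
      "4-Xylp": 3, "3-Xylp": 1, "t-Xylp": 1,
      "2-Manp": 3, "t-Araf": 3
    },
    "Prionitis_sp": {
      "3-Galp": 30, "4-AnGalp": 12, "3,4-Galp": 11, "2,4-Galp": 6,
      "4-Galp": 5, "3,6-Galp": 5, "3,4,6-Galp": 4, "2,3-Galp": 4,
      "4,6-Galp": 2, "2,3,4,6-Galp": 2, "2,4-AnGalp": 1, "2,4,6-Galp": 1,
      "2,3,6-Galp": 1, "t-Xylp": 2, "t-Galp": 1,
      "4-Glcp": 7, "4,6-Glcp": 1,
      "4-Xylp": 2, "3-Xylp": 1,
      "2-Manp": 1, "t-Araf": 1
    },
    "Callophyllis_sp": {
      "4-AnGalp": 16, "3,6-Galp": 15, "2,3-Galp": 7, "3-Galp": 6,
      "3,4-Galp": 4, "2,4,6-Galp": 2, "2,4-AnGalp": 2, "4,6-Galp": 2,
      "2,4-Galp": 3, "2,3,4,6-Galp": 2, "3,4,6-Galp": 2, "4-Galp": 3,
      "2,3,6-Galp": 1,
      "4-Glcp": 15, "4,6-Glcp": 1,
      "4-Xylp": 6, "3-Xylp": 3, "2,4-Xylp": 1,
      "2-Manp": 5, "t-Araf": 4
    },
    "Mastocarpus_papillatus": {
      "3,4-Galp": 46, "4-AnGalp": 22, "2,4-AnGalp": 12,
      "4,6-Galp": 1, "2,4,6-Galp": 1, "3-Galp": 5, "2,3-Galp": 2,
      "4-Glcp": 2, "4,6-Glcp": 1,
      "4-Xylp": 2, "3-Xylp": 1,
      "2-Manp": 3, "t-Araf": 2
    },
    "Mazzaella_splendens": {
      "3,4-Galp": 20, "2,3-Galp": 18, "3-Galp": 12, "4-AnGalp": 10,
      "2,4,6-Galp": 10, "2,4-AnGalp": 8,
      "4,6-Galp": 2, "2,4-Galp": 2, "4-Galp": 3,
      "4-Glcp": 6, "4,6-Glcp": 1,
      "4-Xylp": 3, "3-Xylp": 1, "t-Xylp": 1,
      "2-Manp": 2, "t-Araf": 1
    }
  }
}
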