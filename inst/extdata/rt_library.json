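{
  "comment": "Synthetic retention-time library (minutes) for PMAAs on the simulated 60 m medium-polarity column. Times are invented but monotone with derivative size and acetyl content; they carry no claim of matching a real column. Entries sharing a 'group' co-elute as one peak (symmetric pairs).",
  "entries": [
    { "label": "t-Araf",       "rt": 26.5, "tolerance": 0.15 },
    { "label": "t-Xylp",       "rt": 28.0, "tolerance": 0.15 },
    { "label": "2-Xylp",       "rt": 31.0, "tolerance": 0.15, "group": "xylp-2-4" },
    { "label": "4-Xylp",       "rt": 31.0, "tolerance": 0.15, "group": "xylp-2-4" },
    { "label": "3-Xylp",       "rt": 33.0, "tolerance": 0.15 },
    { "label": "t-Glcp",       "rt": 36.0, "tolerance": 0.15 },
    { "label": "t-Galp",       "rt": 37.5, "tolerance": 0.15 },
    { "label": "2,4-Xylp",     "rt": 39.0, "tolerance": 0.15 },
    { "label": "3,4-Xylp",     "rt": 40.5, "tolerance": 0.15 },
    { "label": "4-AnGalp",     "rt": 42.5, "tolerance": 0.15 },
    { "label": "2-Manp",       "rt": 44.0, "tolerance": 0.15 },
    { "label": "2,4-AnGalp",   "rt": 46.0, "tolerance": 0.15 },
    { "label": "3-Galp",       "rt": 48.0, "tolerance": 0.15 },
    { "label": "4-Galp",       "rt": 50.0, "tolerance": 0.15 },
    { "label": "4-Glcp",       "rt": 52.0, "tolerance": 0.15 },
    { "label": "2,3-Galp",     "rt": 55.0, "tolerance": 0.15 },
    { "label": "2,4-Galp",     "rt": 57.0, "tolerance": 0.15 },
    { "label": "3,4-Galp",     "rt": 59.0, "tolerance": 0.15 },
    { "label": "4,6-Glcp",     "rt": 61.0, "tolerance": 0.15 },
    { "label": "3,6-Galp",     "rt": 63.0, "tolerance": 0.15 },
    { "label": "4,6-Galp",     "rt": 65.0, "tolerance": 0.15 },
    { "label": "2,3,6-Galp",   "rt": 68.0, "tolerance": 0.15, "group": "galp-236-246" },
    { "label": "2,4,6-Galp",   "rt": 68.0, "tolerance": 0.15, "group": "galp-236-246" },
    { "label": "3,4,6-Galp",   "rt": 71.0, "tolerance": 0.15 },
    { "label": "2,3,4,6-Galp", "rt": 75.0, "tolerance": 0.15 }
  ]
}
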