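# pmaatools

Glycosidic linkage analysis of polysaccharides from GC chromatograms of
partially methylated alditol acetates (PMAAs), oriented toward
red-seaweed cell walls: sulfated galactans (agarose, carrageenans with
their 3,6-anhydro-galactose units), mixed-linkage xylans, cellulose and
Floridean starch. The package is for carbohydrate analysts who have FID
and/or EI-MS chromatograms of PMAA preparations and want relative molar
linkage, monosaccharide and polysaccharide compositions, plus PCA-based
sample differentiation — and for method developers who need a simulator
with known ground truth to validate each processing stage.

## What it computes

In methylation analysis, each sugar residue of a polymer becomes a PMAA
whose *O*-methyl positions mark free hydroxyls and whose *O*-acetyl
positions mark C-1, the ring-closure carbon, and every glycosidically
linked (or sulfated) carbon. The package models this chain end to end:

* **Linkage chemistry** — parse shorthand like `4-Glcp`, `t-Xylp`,
  `2,4-AnGalp`; derive substitution patterns and nominal masses (e.g. the
  C-1 deuterated 4-Glcp PMAA at 351 Da); detect chain-reversal symmetric
  pairs (2-Xylp/4-Xylp, 2,3,6-Galp/2,4,6-Galp) and pick deuterium-bearing
  diagnostic EI fragments that distinguish them.
* **Quantitation** — relative molar percentage of linkage *i* is

  * FID basis: `mol_i ∝ area_i / RF_i`, with effective-carbon-number
    response factors `RF` (3-Galp 0.74; 4-AnGalp 0.49, determined from an
    equimolar agarose standard; 2,4-AnGalp 0.54 via the +0.05 O-2
    acetyl-for-methyl increment);
  * TIC basis: `mol_i ∝ area_i / M_i` with nominal masses `M`.

  Co-eluting symmetric pairs share one GC peak; their areas are split in
  proportion to diagnostic extracted-ion chromatogram areas.
* **Roll-ups** — monosaccharide totals, rule-based polysaccharide
  estimates (agarose as `2 × min(4-AnGalp, 3-Galp)`; Floridean starch as
  `4.8 ×` the 4,6-Glcp branch point; mixed-linkage xylan; cellulose from
  remaining 4-Glcp) and diagnostic ratios such as 4-Xylp : 3-Xylp.
* **Chemometrics** — chromatogram normalization to the 4-Glcp anchor peak
  (relative time and abundance both 1 at its apex), resampling to a
  common grid, Z-score standardization (population convention) and PCA by
  SVD with a deterministic sign convention.
* **Simulation** — Gaussian-peak FID/TIC/EIC chromatograms whose areas
  obey the response laws above, with optional TIC suppression of anhydro
  PMAAs (emulating their reduced EI ionization efficiency), Gaussian
  noise, baseline drift and a replicated multi-species study design with
  Dirichlet within-sample variation.

## Worked example

Simulate an agarose-dominated sample, quantify it on both detector bases
and roll the result up:

```r
library(pmaatools)

spec <- simulation_spec(c("3-Galp" = 40, "4-AnGalp" = 27, "4-Glcp" = 33),
                        seed = 1, anhydro_tic_suppression = 0.5)
s <- simulate_sample(spec)
q <- quantify_sample(fid = s$fid, tic = s$tic, eics = s$eics,
                     min_height = 1e-8)
q$fid
#> <composition_table> sample 'synthetic' (FID basis), 3 linkages
#>     label mol_percent  provenance minor
#>    3-Galp          40 direct peak FALSE
#>    4-Glcp          33 direct peak FALSE
#>  4-AnGalp          27 direct peak FALSE

estimate_polysaccharides(q$fid)
#>         agarose       cellulose other_galactans
#>              54              33              13

linkage_ratio(q$fid, "3-Galp", "4-AnGalp")
#> [1] 1.5

compare_detectors(q$fid, q$tic)
#>      label fid_percent tic_percent ratio flagged
#> 3 4-AnGalp          27    15.60694 1.730    TRUE
#> 2   4-Glcp          33    38.15029 0.865   FALSE
#> 1   3-Galp          40    46.24277 0.865   FALSE
```

Reading: the FID-basis table recovers the simulated composition exactly;
pairing the 27% 4-AnGalp with an equal share of 3-Galp gives 54% agarose,
with the excess 3-Galp (the 1.5 : 1 ratio) left in "other galactans"; and
with the TIC anhydro suppression switched on, the anhydro linkage shows
the characteristic FID-over-TIC excess and is flagged.

A command-line wrapper with `simulate`, `quantify`, `report` and `pca`
subcommands ships at `inst/cli/pmaatools.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pmaatools.R",package="pmaatools"))')" \
    simulate --out chroms/ --seed 1
```

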