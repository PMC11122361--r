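---
title: "Methylation-based linkage analysis with pmaatools: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-based linkage analysis with pmaatools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmaatools)
```

## The measurement being modeled

Methylation (linkage) analysis converts each monosaccharide residue of a
polysaccharide into a partially methylated alditol acetate (PMAA).
Permethylation caps every free hydroxyl with a methyl ether;
depolymerization then exposes the formerly linked (or sulfated) oxygens;
reduction opens the ring; peracetylation caps everything newly exposed.
The *O*-acetyl positions of the final derivative therefore read out C-1,
the ring-closure carbon, and every carbon that was glycosidically bonded
or sulfate-substituted in the polymer, while the *O*-methyl positions mark
hydroxyls that were free. GC separates the derivatives; FID or EI-MS
quantifies them; relative molar compositions follow from detector-specific
response laws.

Red-seaweed cell walls add two complications that shape this package.
First, 3,6-anhydro-galactose — the hallmark unit of agarose and of
kappa-family carrageenans — is destroyed by ordinary acid hydrolysis, so
those samples are processed by reductive hydrolysis with an amine borane,
which does **not** install the C-1 deuterium that ordinary borodeuteride
reduction provides. The package encodes this asymmetry: anhydro PMAAs are
modeled non-deuterated, all others C-1 deuterated, and `derivatize()`
refuses a deuterated anhydro derivative. Second, two pairs of linkages
(2-Xylp/4-Xylp and 2,3,6-Galp/2,4,6-Galp) give PMAAs whose substitution
patterns are mirror images under reversal of the alditol chain: without
the deuterium label they are the same molecule, and on the column they
co-elute as one peak in any case. The C-1 label breaks the symmetry in
EI-MS, and extracted-ion chromatograms of label-bearing fragments provide
the molar ratio used to split the shared peak area.

## The chemical model

`parse_linkage()` implements the field's shorthand
(`[t|p1,p2,...]-[An]Sugar[p|f]`). Arabinose defaults to the furanose ring,
all other sugars to pyranose, because that is how these sugars
overwhelmingly occur and how unsuffixed labels are conventionally read.
Positions collide with chemistry where they must: the ring-closure carbon
(C-5 pyranose, C-4 furanose) cannot carry a glycosidic bond, the 3,6
bridge is restricted to pyranose hexoses, and bridge positions cannot be
linked.

Masses are **nominal** (integer) sums over atomic composition. Relative
TIC quantitation divides area by molecular mass; at the precision of that
convention, isotopic fine structure is irrelevant, so monoisotopic masses
would add complexity without changing any result. Three anchor values
with independent hand-derivable compositions are fixed in the tests: the
deuterated 4-Glcp PMAA at 351 Da, the deuterated t-Xylp PMAA at 279 Da,
and the non-deuterated 4-AnGalp PMAA at 304 Da.

`predict_fragments()` uses the single-cleavage primary-fragment
approximation: one backbone C–C bond breaks, either side retains the
charge, and the fragment mass is the plain atom sum of the retained
carbons with their substituents (for the classic example, the C1–C2
fragment of a deuterated 4-linked pentose PMAA computes to m/z 118).
Secondary losses of acetic acid or methanol are deliberately not modeled:
the predictor exists to choose label-discriminating diagnostic ions for
the two symmetric pairs, not to simulate spectra. `diagnostic_ions()`
picks, for each pair member, a C-1 (label-bearing) fragment unique to that
member, maximizing the m/z separation of the two chosen ions. This is a
package design choice — the selection rule is deterministic and tested,
but no claim is made that any particular published workflow used exactly
these ions.

## Response factors

FID response factors follow the effective carbon number (ECN) idea:
molar FID response scales with the effectively combusted carbons, so each
PMAA gets a dimensionless factor and quantitation divides area by it.
The orientation matters and is fixed by a physical anchor: in an
equimolar agarose standard the anhydro peak is the *smaller* one, so the
anhydro factor must be < 1 and moles must be proportional to area /
factor — the opposite convention would halve instead of double the
anhydro share. The shipped library pins the three experimentally anchored
values (3-Galp 0.74; 4-AnGalp 0.49; 2,4-AnGalp 0.54 = 0.49 + 0.05 via the
O-2 acetyl-for-methyl increment rule) and fills the remaining labels with
ECN-derived values — (backbone carbons + acetyl count) / 12, i.e. the
ratio to inositol hexaacetate — rounded to two decimals. The library is
editable JSON; an unknown PMAA raises an error rather than silently
using 1.0, because a silent unit factor would bias every composition in
the table. The low anhydro factors fold in both the detector response and
the partial degradation of anhydro units under harsh permethylation; the
package treats them as opaque calibration constants.

On the TIC basis the package divides by mass only, applying no anhydro
correction. This is deliberate: the FID/TIC discrepancy for anhydro
sugars is a finding to surface, not to hide, and `compare_detectors()`
reports the per-label FID%/TIC% ratio, flagging labels exceeding
1 + threshold (default 0.2).

## Peak processing

Detection operates on an optionally smoothed copy of the trace (moving
average, default 5 points); integration always uses the raw trace.
Apexes are local maxima above `min_height` (default 2% of the trace
maximum); bounds are valley-to-valley — the lowest point between
neighbouring apexes — with an optional fixed `halfwidth` clip. The clip
matters on noisy traces: distant valleys otherwise pull long stretches of
baseline noise into the integral, and a linear baseline drawn through two
noisy endpoints far from the peak corrupts the area. With bounds clipped
to roughly ±6 sigma the truncation is identical for all peaks of equal
width and cancels in the relative composition. Integration is
trapezoidal, above either no baseline or a straight line joining the
trace values at the bounds, clipped at zero.

Retention-time assignment gives each library entry the nearest peak
within its tolerance (default ±0.15 min, per entry). Entries sharing a
co-elution group fan out into a shared peak that the pipeline must split
before quantitation; two peaks inside one entry's window raise an
ambiguity error rather than guessing. The shipped retention-time library
is **synthetic**: monotone, plausibly spaced times for the covered PMAAs.
It carries no claim of matching any real column and exists so that the
simulator and the pipeline agree on a coordinate system; users with real
data supply their own JSON.

One wrinkle discovered in end-to-end testing: diagnostic m/z values can
recur across different co-elution groups (m/z 190 serves one member of
each shipped pair). When several provided EICs carry the requested m/z,
the pipeline integrates each over the shared peak's bounds and keeps the
strongest signal — correct because the other group's trace is flat at
this retention time.

## The simulator and what passing tests mean

`simulate_chromatogram()` renders one Gaussian peak per linkage at its
library retention time with area exactly obeying the detector law
(FID: moles × factor; TIC: moles × mass × suppression for anhydro
labels), plus optional linear baseline drift and additive i.i.d. Gaussian
noise; everything is bitwise-reproducible under the spec seed. Default
peak sigma is 0.08 min, a realistic width for a long capillary column and
narrow enough that the shipped library's 1.5 min spacing separates
neighbours by far more than 6 sigma. The TIC anhydro suppression default
of 0.5 is an illustrative, clearly labeled choice: the real magnitude of
the anhydro EI under-response is not quantified, only its direction.

`simulate_dataset()` draws replicate compositions from a Dirichlet
distribution centered on each species profile with concentration
`profile / within_noise`. The default `within_noise = 0.002` produces
replicate scatter of about one to two percentage points on major
linkages, comparable to duplicate-experiment variation in published
linkage tables. The six shipped species profiles place the printed major
linkage values of the corresponding seaweeds and fill the remainder with
plausible minor linkages so each profile sums to 100; they are synthetic
study conditions, not measurements.

What the simulator does **not** emulate: peak tailing and asymmetry,
retention drift between runs, co-elution beyond the two symmetric pairs,
mass-spectral noise, detector saturation, and derivatization side
products. Passing round-trip tests therefore demonstrates that the
processing chain is self-consistent and unbiased under the stated noise
model — not that vendor-software integration of real chromatograms would
be reproduced. Verified properties include: noiseless
simulate-to-composition round trips recover inputs to well under 0.1
percentage point; with noise at 1% of the tallest peak, the mean bias
over 100 seeds stays under 0.2 percentage points (measured with
`halfwidth = 0.5` min and no baseline, the recommended settings for
flat-baseline traces); shared-peak splits conserve area exactly; and a
simulated equimolar agarose standard returns the 0.49 anhydro response
factor that generated it.

## Composition roll-ups

Polysaccharide estimation is an ordered, user-editable rule table over
the pool of linkage percentages, conserving mass into a residual bucket.
Two rules need interpretation:

* **Floridean starch.** The branch point of the red-algal starch appears
  as 4,6-Glcp, and the assumed average branching degree of 4.8 means one
  branch per 4.8 residues. The package reads this as: starch% = 4.8 ×
  4,6-Glcp%, of which 3.8 × comes out of the 4-Glcp pool (floored at what
  the pool holds), and cellulose is whatever 4-Glcp remains. This
  reproduces the printed pattern of cellulose estimates sitting a little
  below the 4-Glcp percentages.
* **Agarose.** Agarose is a strictly alternating 3-Galp / 4-AnGalp
  polymer, so the estimate is 2 × min of the two units, consuming equal
  shares. Excess 3-Galp (agarophytes typically show a 3-Galp :
  4-AnGalp ratio above 1, e.g. 1.5) deliberately falls into "other
  galactans", since it may belong to sulfated galactans or glycoproteins.

Carrageenan repeat-unit inference (kappa vs iota vs lambda pairings) is
out of scope: linkage analysis destroys sequence information, so those
assignments would be hypotheses, not measurements.

## Chemometrics conventions

Chromatogram normalization divides both axes by the 4-Glcp anchor apex
(time and intensity), after truncating to the 25–110 min analysis
window. The anchor search is deliberately generous (±12% of the anchor's
library time, tallest candidate wins) so that uniformly stretched or
drifted runs still normalize; a trace with no candidate errors out
naming the anchor. Grid resampling is plain linear interpolation onto the
intersection of relative-time ranges, default 2000 points — no smoothing,
so nodes reproduce exactly.

Z-scoring uses the population (n) standard deviation, fixed and
documented for reproducibility; constant columns become all-zero with a
warning. PCA is SVD of the column-centered matrix with a deterministic
sign convention (largest-magnitude loading per component positive).
Identically zero columns are dropped first.

A practical limitation surfaced by testing: Z-scoring a resampled
chromatogram matrix amplifies near-zero columns (grid points in peak
tails), so replicate points in trace-based PCA scatter much more than in
composition-based PCA at the same within-sample noise. The
replicate-proximity property (replicates closer than any between-species
pair) is therefore exercised in the regime where within-sample variation
is well below between-species differences; at the dataset default
`within_noise = 0.002` the property holds for well-separated species but
is not guaranteed for every pair in 2-component score space.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on simulated data:
traces of 4251 points (25–110 min at 0.02 min), up to six species × two
replicates (12 FID + 12 TIC traces plus EICs), and 100-seed noise
ensembles for the statistical recovery checks. These sizes were chosen as
the smallest at which the targeted effects are comfortably resolved.
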