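Package: pmaatools
Title: Glycosidic Linkage Analysis of Polysaccharides from PMAA Chromatograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational workflow for methylation-based glycosidic linkage
    analysis of polysaccharides, with an emphasis on red-seaweed galactans
    (agarose, carrageenans) and mixed-linkage xylans. Parses glycosidic
    linkage shorthand, models partially methylated alditol acetate (PMAA)
    derivatives (substitution patterns, nominal masses, diagnostic electron
    impact fragments), reads and integrates GC-FID and GC-MS chromatograms,
    converts peak areas into relative molar linkage compositions under
    detector-specific response laws (FID effective-carbon-number response
    factors including experimentally anchored 3,6-anhydro-galactose factors;
    TIC area over molecular mass), splits co-eluting symmetric PMAA pairs
    using extracted-ion chromatograms, rolls linkage tables up to
    monosaccharide and polysaccharide compositions, and differentiates
    samples by Z-score standardized principal component analysis of linkage
    tables or normalized chromatograms. A synthetic chromatogram generator
    provides ground-truth data so the entire pipeline can be exercised and
    validated without instrument output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
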