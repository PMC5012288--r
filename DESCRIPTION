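Package: phycoscreen
Title: Screening Microalgae as Biodiesel Feedstock
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for strain-level screening of microalgae as biodiesel
    feedstock. Computes specific growth rates and generation times from
    optical-density or fluorescence time series with automatic selection of
    the exponential window; parses fatty-acid shorthand (CX:Y) nomenclature
    and normalises GC-MS FAME peak tables into compositional profiles;
    derives the standard biodiesel-quality indices (saponification value,
    iodine value, cetane number, degree of unsaturation, long-chain
    saturation factor, cold filter plugging point) and applies the ASTM
    cetane/iodine screen; clusters FAME profiles by Bray-Curtis UPGMA with
    cophenetic validation and species-resampling bootstrap; analyses static
    copper-toxicity bioassays (percent inhibition, no-growth detection,
    between-strain t tests); and provides a small phylogenetics stage for
    aligned 18S rRNA sequences (block-based alignment cleaning,
    neighbour-joining with bootstrap, branch-length phylotype demarcation).
    A synthetic-data generator emulates every input kind so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    phytools,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
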