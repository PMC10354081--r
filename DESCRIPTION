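Package: biomedyn
Title: Assembly Dynamics of Biomes from Dated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the assembly history of a biome from dated,
    range-coded phylogenies across many clades. Fits the
    dispersal-extinction-cladogenesis (DEC) model of geographic range
    evolution with a maximum range-size constraint and time-stratified
    dispersal multipliers, estimates marginal ancestral ranges, classifies
    species-level biogeographic events into dispersals into a focal region
    and in situ diversification events, and characterizes their dynamics
    through time: binned and smoothed event-rate curves built from node-age
    credibility intervals, origination and peak features with bootstrap
    confidence intervals, and piecewise-linear (segmented) regression change
    points selected by BIC. Includes ancestral habitat-state reconstruction
    under a two-state Markov model and a full synthetic-data generator
    (birth-death trees, forward-simulated DEC histories with logged true
    events, habitat histories, and event ensembles from piecewise-constant
    intensities) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
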