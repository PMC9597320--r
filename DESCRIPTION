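Package: ojipscreen
Title: Drought-Stress Screening of Wheat Genotypes from Fast Chlorophyll
    Fluorescence Transients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end screening pipeline for PEG-induced drought experiments
    on winter wheat seedlings. Reads fast chlorophyll a fluorescence (OJIP)
    transients, derives the full JIP-test parameter set (specific and
    phenomenological energy fluxes, quantum yields, performance indices),
    builds double-normalized relative variable fluorescence curves and their
    treatment-minus-control L- and K-band divergences, computes biochemical
    stress indices (cell membrane integrity, relative water content,
    electrolyte leakage, malondialdehyde, proline, photosynthetic pigments),
    screens genotype responses with Hedges bias-corrected effect sizes, and
    classifies genotypes by principal component analysis with direct oblimin
    rotation followed by hierarchical k-means clustering. Includes a
    synthetic-data generator with known ground-truth response archetypes so
    the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Roxygen: list(markdown = TRUE)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    yaml
Suggests:
    car,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
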