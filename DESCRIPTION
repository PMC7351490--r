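Package: dropcult
Title: Droplet-Microfluidic Anaerobic Cultivation Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational companion to droplet-microfluidic cultivation of
    anaerobic gut microbes. Implements image-based colony-density scoring
    ("Wavelet OD": undecimated biorthogonal-3.1 wavelet frame texture features
    with gray-level co-occurrence quantization), threshold-gated droplet
    sorting with a false-positive error bound, Poisson statistics of
    stochastic single-cell encapsulation, a maximum-likelihood filter for
    dead/nonviable-DNA carryover in amplicon sequence variant (ASV) count
    tables, and the community-ecology metrics used to quantify cultivation
    bias (richness, Shannon diversity, rank-abundance, Bray-Curtis
    clustering). Ships seeded synthetic-image and synthetic-community
    generators so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite,
    vegan,
    ape,
    png,
    tiff,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
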