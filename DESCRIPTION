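Package: callphylo
Title: Phylogenetic Signal in Low-Level Acoustic Descriptors of Animal Calls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing whether acoustic similarity of animal
    vocalizations tracks phylogenetic relatedness. Computes five low-level
    spectral and spectro-temporal descriptors (amplitude-modulation
    coefficient of variation, dominant frequency, spectral flux, spectral
    irregularity, spectral flatness) from PCM WAV recordings, removes
    allometric body-size effects by phylogenetic generalized least squares,
    and tests the size-corrected residuals for phylogenetic signal with
    Moran's I, Geary's C, Blomberg's K and Mantel tests against three
    relatedness models (pairwise sequence distances, Abouheif proximities,
    and the Brownian-motion variance-covariance matrix). Includes a
    bootstrap-based forward stepwise selection of multivariate trait
    distances and a synthetic-data generator (Yule trees, Brownian traits,
    Jukes-Cantor sequence evolution, parametric call audio) with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    phytools,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
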