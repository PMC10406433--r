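Package: condenscale
Title: Multiscale Fractal Analysis of Biomolecular Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytical fractal scaling model of biomolecular condensate
    architecture: from per-chain descriptors (interaction valency, compactness,
    intermolecular contact statistics) through the iterative cluster-assembly
    formalism linking valency and volume fraction to the fractal dimension, to
    atomistically decorated fractal aggregate reconstructions. Also provides
    translational diffusion extraction from mean-square displacement with the
    finite-size periodic-boundary correction, Green-Kubo shear viscosity from
    pressure-tensor autocorrelations, FRAP double-exponential recovery fitting
    with half-time extraction, particle circularity, and seeded synthetic-data
    generators with known ground truth for every analysis path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite,
    igraph,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
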