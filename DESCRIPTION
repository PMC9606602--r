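Package: chaosgm
Title: Chaos Analysis of Gray-Matter Topology from Structural MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transforms gray-matter probability volumes into sorted
    intensity-weighted distance spatial series, estimates largest Lyapunov
    exponents by delay embedding and the Rosenstein divergence method,
    reconstructs smoothed voxel-wise lambda maps, computes complex-Morlet
    continuous-wavelet scalograms of the lambda series, and compares groups
    with covariate-adjusted voxel-wise statistics (permutation maxT
    family-wise error control) and Benjamini-Hochberg FDR over point-by-scale
    scalogram grids. Includes a synthetic corrugated-shell phantom generator
    so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
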