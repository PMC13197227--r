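Package: pdtomo
Title: Subtomogram Averaging and Morphometrics of Plasmodesmata Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthetic plasmodesma tomogram generation with ground truth,
    contour-guided particle seeding with pseudo-symmetry expansion onto the
    desmotubule surface, missing-wedge aware constrained and exhaustive
    subtomogram alignment and averaging with Fourier shell correlation,
    cylindrical-unwrap helical lattice analysis (start counting and pitch),
    bead-model density simulation and rigid-body map fitting, and pore
    morphometrics with nonparametric group comparisons. Volumes are read and
    written as MRC2014; particle tables as TSV/STAR-style files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
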