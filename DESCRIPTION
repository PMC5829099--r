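Package: retinalca
Title: Retinal Opponent-Channel Compensation of Longitudinal Chromatic
    Aberration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates how retinal color-coding ganglion cells can
    compensate for the blue-yellow fringes that longitudinal chromatic
    aberration (LCA) produces at luminance edges.  Cone images are passed
    through a wavelength-dependent defocus stage, a first-order gain
    adaptation with local and remote (annular) components, and opponent
    receptive fields: spatially antagonistic type-I L/M cells modelled as
    differences of Gaussians and a spatially coextensive type-II S/(L+M)
    cell.  An inverse transformation reconstructs the perceived LMS image
    from the opponent responses by functional minimization, removing
    chromatic fringes and predicting chromatic assimilation on S-cone ring
    patterns.  Includes synthetic stimulus generators, contrast-profile
    and induction metrics, and an end-to-end pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
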