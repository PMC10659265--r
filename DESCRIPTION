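Package: eidecomp
Title: Compartmental Decomposition of Neuronal Electrical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes the electrical image (EI) of a neuron recorded on a
    high-density multielectrode array into temporally shifted, nonnegatively
    weighted somatic, dendritic and axonal basis waveforms (shifted
    semi-nonnegative matrix factorization with an L2,1 amplitude penalty and
    a Gaussian waveform-shape prior), and provides the downstream inference
    built on the decomposition: soma and dendritic-field localization,
    receptive-field center prediction from spike-triggered averages,
    dendritic-mosaic contouring with a rotation-based significance test, and
    retinal ganglion cell type classification from waveform shapes and
    compartment amplitude norms. Includes a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, jsonlite, yaml, stats, utils, graphics, grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
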