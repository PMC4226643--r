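Package: taxofeat
Title: Image-Based Species Identification with Morphometric Features and a
    Sigmoid Multilayer Perceptron
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for automatic species identification from
    single-specimen photographs. Images are segmented, denoised, binarized,
    and reduced to contour and skeleton rasters; each specimen is then
    described by a fixed 15-dimensional feature vector combining six
    geometric region descriptors (area, perimeter, equivalent diameter,
    compatibility, compactness, solidity), six texture statistics
    (first-order histogram mean and variance plus gray-level co-occurrence
    uniformity, entropy, homogeneity and inertia), and three moment
    invariants (the first Hu invariant and two affine moment invariants).
    Classification uses a from-scratch one-hidden-layer sigmoid multilayer
    perceptron trained by online backpropagation. Includes a stratified
    train/test evaluation harness, a hidden-neuron sweep, and a synthetic
    specimen-image generator with controllable inter-species separation for
    benchmarking without access to museum image collections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
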