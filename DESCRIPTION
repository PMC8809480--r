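Package: icatr
Title: Integrated Correlative Array Tomography Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-acquisition computational pipeline for integrated
    correlative array tomography (iCAT). Detects serial sections on a
    slide overview image by marker-controlled watershed, registers
    fluorescence to electron microscopy tiles through grids of
    cathodoluminescent spots, stitches high-magnification EM montages
    from scale-invariant feature correspondences solved as one sparse
    regularized least-squares system, propagates fluorescence overlays
    through a low-magnification proxy, and aligns serial sections into
    a correlative 3D volume. Ships synthetic acquisition generators with
    known ground truth so every stage can be exercised and validated
    without a microscope.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
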