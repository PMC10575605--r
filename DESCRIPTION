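Package: nrbrt
Title: Non-Reciprocal Broken-Ray Tomography for Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous reconstruction of the intrinsic optical attenuation
    at the excitation and emission wavelengths and of the fluorophore
    concentration in weakly scattering media, from angularly selective
    boundary measurements of fluorescence light. Implements voxelized
    cuboid phantoms with spherical inclusions, broken-ray scan geometry
    with finite-detector geometric factors, a noise-free single-scattering
    forward model, an analog Monte Carlo photon-transport engine with
    fluorescence conversion and acceptance-cone surface scoring, assembly
    of broken-ray-transform data functions with source-detector
    interchange, local inversion via a divergence formula with
    total-variation regularized numerical differentiation, and image
    quality metrics (RMSE, SSIM).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
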