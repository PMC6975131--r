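Package: holoctf
Title: Multi-Energy CTF Phase Retrieval for Inline X-Ray Holotomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and single-step inversion of inline (propagation-based)
    X-ray holograms recorded at multiple photon energies. Implements the
    homogeneous weak-object contrast transfer function (CTF) formalism that
    maps flat-field corrected holograms directly to projected electron
    density, Fresnel diffraction simulation of cone-beam recordings in
    effective parallel-beam coordinates, seeded single-material phantoms for
    validation studies, and the downstream tomography pipeline (sinogram
    conditioning, wavelet-Fourier ring removal, filtered backprojection) with
    threshold-based particle segmentation and per-particle volume and
    electron-density statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
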