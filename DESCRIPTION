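Package: vhisto
Title: Virtual Histology by Propagation-Based Phase-Contrast Micro-CT Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for synchrotron propagation-based
    phase-contrast micro-computed tomography (PhC micro-CT) of paraffin-embedded
    soft-tissue blocks, aimed at 3D virtual histology of breast specimens.
    Provides seeded procedural breast-tissue phantoms with refractive-index
    (delta/beta) material maps, a parallel-beam Fresnel forward model of the
    acquisition (flat fields, dark fields, detector gain structure and photon
    noise), flat-field correction and ring-artifact suppression, single-distance
    TIE-Hom (Paganin) phase retrieval, filtered back projection with Shepp-Logan
    windowing including truncated local-area sinogram padding, post-reconstruction
    de-trending and unsharp masking, quantitative image-quality metrics
    (contrast-to-noise ratio, edge FWHM, ring and cupping scores), and virtual
    slicing with rigid 2D co-registration of histology-like sections to
    reconstructed CT planes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    knitr
Config/testthat/edition: 3
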