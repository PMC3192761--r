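Package: histo3d
Title: Two-Branch 3D Reconstruction of Serial Histological Sections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Digital 3D reconstruction of protein expression and vessel
    branching from ordered stacks of 2D immunohistochemistry section images.
    Implements the two complementary rendering branches used for serial-section
    histology: volumetric rendering (color-channel inversion and recombination
    with an automatically derived alpha channel, followed by front-to-back
    alpha-compositing projection) and segmentation-based surface rendering
    (threshold/manual labeling, 3D connected components with connectivity
    queries against a reference structure, and unsmoothed isosurface meshing).
    Includes landmark-based rigid slice alignment, deterministic replacements
    for the interactive image-editing steps (background whitening, color-range
    noise removal, inversion, resizing, grayscale conversion), and a synthetic
    branching-duct phantom generator with virtual sectioning, stain rendering
    and controlled misalignment for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    yaml,
    tiff,
    png,
    jpeg,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
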