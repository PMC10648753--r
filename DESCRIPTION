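Package: crumbCT
Title: Micro-CT Quantification of Porous Crumb Microstructure During Storage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for characterizing the internal pore structure of steamed
    bread and similar porous foods from X-ray computed tomography volumes.
    Reads headerless 16-bit RAW volumes and image slice stacks, segments the
    crumb matrix by grayscale band or balanced histogram thresholding,
    recovers the interior pore phase by hole filling and mask arithmetic,
    separates pores by morphological ball opening and connected-component
    labeling, and measures per-pore morphometry (volume, triangulated
    isosurface area, Feret length and width, equivalent diameter) together
    with sample porosity and volume. A skeleton-based pore-throat network is
    extracted by distance-ordered homotopic thinning, and storage-series
    statistics (Pearson correlation matrices, moisture-porosity linear fits)
    link microstructure to physicochemical quality indexes. A seeded voxel
    phantom generator produces bun-shaped test volumes with exact ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
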