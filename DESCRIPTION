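Package: mucosurf
Title: Micro-CT Morphometry and Effective Surface Area of Intestinal Mucosa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of micro-CT volumes of small-bowel mucosal
    biopsies. Provides synthetic mucosal phantoms with analytically known
    surface areas, volumetric image input/output (multi-page TIFF and NRRD)
    with voxel-spacing metadata, non-local-means and median denoising with
    threshold segmentation, surface-area estimation inside an orientated
    measurement rectangle by a discretized Crofton formula with 2x2x2
    configuration lookup tables, the effective-surface-area coefficient and
    its replicate statistics, oblique digital sectioning, and villous
    height to crypt depth (VH:CrD) morphometry with the standard
    three-pair averaging and diagnostic cutoff.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    yaml,
    pracma,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite,
    optparse
Config/testthat/edition: 3
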