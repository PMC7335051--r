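Package: cytodisp
Title: Cell-to-Cell Expression Dispersion of Surface Proteins: Gating,
    Dispersion Traits and cis-QTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell protein expression measured by
    flow cytometry across a cohort of cell lines. Implements automated gating
    (saturation bounds, DAPI stain and G1 cell-cycle selection, dynamic density
    gates for size and doublets, cell-size correction, replicate alignment and
    replicate-outlier scoring), dispersion traits (coefficient of variation,
    mean-conditioned CV by local regression, two-component Gaussian mixture
    description of bimodal distributions, line-level averaging and complete
    linkage clustering), clonality calls from CDR3 amplicon read tables, and
    cis-window genetic association of dispersion traits with additive models,
    max-T permutation family-wise error control and Benjamini-Hochberg FDR.
    Ships a synthetic-data generator emulating the measurement structure so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
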