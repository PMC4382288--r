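Package: filamentnoise
Title: Noise and Spatial Correlations of Gene Expression Along Cell Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of cell-to-cell variability of gene
    expression along one-dimensional multicellular filaments, such as
    cyanobacterial filaments carrying a fluorescent reporter. Provides
    per-cell noise measures, bias-corrected spatial autocorrelation on the
    cell lattice with a within-filament permutation correction, histogram
    comparison by Earth Mover's Distance, Kolmogorov-Smirnov distance and a
    two-sample chi-squared statistic with bootstrap standard errors, and
    run-length (cluster-size) statistics of supra-threshold cells with an
    independent-cell Bernoulli null model. Includes a synthetic-data
    generator for filament fluorescence traces and microscopy-like images
    with ground-truth labels, an adaptive-threshold cell segmentation
    routine that orders cells into filaments, and a configurable end-to-end
    pipeline with deterministic seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
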