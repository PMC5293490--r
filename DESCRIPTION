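Package: smedembryo
Title: Spatial Anarchy and Molecular Staging Analyses for Planarian Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two quantitative analyses of planarian (Schmidtea
    mediterranea) embryogenesis. The first is a one-parameter damped-sine
    model for the polar angle of piwi-1+ blastomeres along the embryonic
    oral-aboral axis: density, distribution function, exact rejection
    sampler, bounded maximum-likelihood fitting with a likelihood-ratio
    comparison against the uniform-on-sphere null, and parametric-bootstrap
    standard errors. The second is a molecular-staging enrichment cascade
    for single-embryo RNA-Seq count matrices: TMM scaling, RPKM/CPM
    normalization with ribosomal-RNA handling, a simple negative-binomial
    two-group test with Benjamini-Hochberg adjustment, threshold-cascade
    enrichment calls (pairwise and mixed-stage-reference), per-stage
    signatures and early-embryo-enriched (EEE) transcript classification.
    Synthetic generators for landmarked 3D spot clouds and planted count
    studies make every stage testable without microscopy or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
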