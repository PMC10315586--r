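Package: hibed
Title: Hierarchical Reference-Based Deconvolution of Brain Cell Types from
    DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the proportions of seven brain cell types (GABAergic
    and glutamatergic neurons, astrocytes, microglia, oligodendrocytes,
    endothelial and stromal cells) in bulk DNA methylation profiles by
    hierarchical reference-based deconvolution. Cell-type-specific CpGs are
    selected per hierarchy node with one-vs-rest moderated t-statistics,
    assembled into a four-sub-library reference, and bulk beta-value
    profiles are projected onto the reference by constrained (non-negative,
    sum-bounded) least squares; Layer-2 conditional proportions are weighted
    by Layer-1 group proportions. Includes a synthetic purified-reference
    generator and an in-silico mixture benchmarking framework with
    Pearson/RMSE evaluation, glia-to-neuron and GABA/GLU ratio summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    limma,
    MASS,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
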