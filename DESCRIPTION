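Package: moca
Title: Multiblock Orthogonal Component Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes several blocks of variables measured on the same
    observations into globally joint, locally joint, and unique latent
    components, in the OnPLS/O2PLS family of multiblock methods. Provides
    NIPALS principal component analysis with native missing-value handling
    and jackknife loading confidence intervals, two-block PLS and
    single-response orthogonal PLS engines, a strictness parameter
    controlling how correlated block score vectors must be to count as
    joint variation, block-level redundancy and predictivity metrics for
    descriptor-block selection in QSAR work, a synthetic multiblock data
    generator with planted ground truth, CSV/block-configuration input,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
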