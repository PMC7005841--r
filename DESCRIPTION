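Package: gqyield
Title: Quality-Adjusted Yield and Bioeconomics of Grassland Diversity Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing managed grassland diversity experiments from
    per-cut sward measurements to economic valuation. Provides a synthetic
    generator for a blocked species-richness x management-intensity design,
    forage nutritive-value estimation equations (metabolizable energy, net
    energy for lactation, milk production potential, utilizable crude
    protein), annual aggregation into quality-adjusted yields, a linear
    mixed model for per-management diversity effects with cluster-robust
    inference, functional-form selection, and an itemized cost and milk
    revenue ledger for management and restoration decisions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
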