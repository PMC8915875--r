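Package: scirapr
Title: Structured Reliability and Relevance Appraisal of In Vitro Toxicity Studies
Version: 2.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Offline implementation of the SciRAP (Science in Risk Assessment
    and Policy) instrument for evaluating in vitro toxicity studies. Bundles
    the version 2.0 criteria catalog (24 reporting-quality criteria, 16
    methodological-quality criteria, 4 relevance items), computes the weighted
    SciRAP score and colour-profile readout for single-study evaluations,
    imports and exports evaluation reports, consolidates multi-rater panels
    into rating matrices, classifies per-criterion inter-rater variability
    (consensus / low / moderate / high) under configurable decision rules,
    derives cross-study prioritization tables, and generates seeded synthetic
    rater panels with controlled agreement for testing and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils, grDevices, graphics, tools
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
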