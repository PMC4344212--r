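Package: screenpi
Title: Pathway Impact Scoring for Multi-Readout RNAi Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pathway-level analysis of genome-wide siRNA screens with several
    phenotypic readouts. Raw well intensities are log-transformed, normalized
    to cell viability, corrected for plate-edge artifacts, standardized per
    plate with a robust Z* score (median / 2xMAD), and collapsed from probe
    pools to genes. Gene sets are scored with Net and Absolute Pathway Impact
    (PI) statistics whose significance is assessed against size-matched
    permutation null distributions. Downstream tools build the clustered
    overlap-coefficient landscape of significant pathways, compare pathway
    significance across readouts, and summarize results. A synthetic screen
    generator with planted pathway effects supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
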