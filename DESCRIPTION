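Package: adipoquant
Title: Quantification of Zebrafish Adipose Tissue Reporters and Lipolysis Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying in vivo lipid-droplet reporter imaging and
    high-throughput lipolysis screens. Segments fluorescent adipose tissue in
    multi-channel images of transparent zebrafish after gating out gut and
    gallbladder autofluorescence, quantifies adipose area in pixels and square
    micrometers, converts 96-well glycerol-release absorbances through a
    standard curve, removes plate edge effects with per-position normalization
    factors averaged across plates, calls lipolysis-inhibitor hits at a
    configurable reduction threshold, and summarises longitudinal adiposity
    cohorts (area per standard length) with nonparametric group comparisons and
    flow-cytometry percent-positive gating. A synthetic-data module generates
    every input with known ground truth so the whole pipeline is testable
    without any acquisition hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    EBImage,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
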