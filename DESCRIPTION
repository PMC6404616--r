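Package: phenolscreen
Title: Chemical-Genomic Fitness Screening of Deletion Libraries by Spot-Assay Densitometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative chemical-genomic screens of yeast
    deletion libraries. Digitizes scanned spot-assay plates into per-colony
    integrated densities, computes wild-type-normalized growth score values
    (GSV), classifies strains as sensitive or resistant with replicate
    consensus rules, summarizes cross-compound overlaps by exact set
    arithmetic, clusters log-ratio fitness profiles, tests gene-set
    over-representation with upper-tail hypergeometric probabilities, and
    estimates inhibitory concentrations from dose-response curves. Includes
    a synthetic-data generator (screens, plate images, annotation universes,
    dose-response curves) with known ground truth so every stage is testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr,
    ape,
    tiff,
    minpack.lm,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
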