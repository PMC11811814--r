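Package: dropnox
Title: Single-Cell Droplet NADPH-Oxidase Activity and Secretion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for droplet-microfluidic single-cell assays
    that read out NADPH-oxidase (NOX) activity, antibody secretion, lactate
    secretion and intracellular reactive oxygen species from time-lapse
    fluorescence of picoliter droplets. Implements the percent-signal-loss
    statistic and its median-plus-3-SD control threshold for classifying
    NOX-active droplets, calibrated conversion of bead-relocation and
    lactate-probe intensities into per-cell secretion rates with
    quantitative-range gating, rule-based marker gating of single-cell
    transcriptomes into B-cell subsets and NOX-expressing fractions with
    pathway-modulation scores, and a synthetic-data generator (trace-level
    and rendered image-level) with planted ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
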