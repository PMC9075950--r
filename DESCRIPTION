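Package: lickphys
Title: Analysis of Cerebellar Purkinje-Cell Activity During Rhythmic Licking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing neural spike trains and dendritic calcium
    events recorded during an interval-timing licking task: lick-bout
    segmentation and peri-event lick-rate histograms, Purkinje-cell
    identification from multichannel spike footprints, spike entrainment to
    the lick cycle via circular statistics (mean resultant, Rayleigh test,
    Benjamini-Hochberg screening), detection and classification of ramping
    firing-rate changes around bout initiation and termination, dendritic
    calcium-event ramp analysis, and optogenetic-trial lick metrics.
    Includes a synthetic-session generator with ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
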