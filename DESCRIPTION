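Package: attenscan
Title: Genome-Wide Screening and Quantification of RNA Polymerase II
    Attenuators in Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens gene promoter-proximal regions for signatures of
    premature RNA polymerase II termination (attenuation) in
    Saccharomyces cerevisiae occupancy data. Computes peak enrichment of
    polyadenylation sites and RNA-binding termination factors (Hrp1,
    Nrd1, Nab3) normalized to local Pol II occupancy and to a reference
    NNS-dependent attenuator gene, bins the ratios into a categorical
    heatmap, and flags hybrid-pathway attenuator candidates. Also
    quantifies the downstream readouts used to validate candidates:
    kinetic beta-galactosidase reporter slopes and activities,
    terminator strength, fold-readthrough, culture doubling times, and
    Welch-test significance labels. Ships a seeded synthetic-data
    generator that emits annotation, bedGraph occupancy tracks, BED site
    tracks, kinetic assays and growth curves with known ground truth so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    ggplot2,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
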