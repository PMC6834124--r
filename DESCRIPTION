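Package: mirtriplex
Title: Functional Prediction of MicroRNAs via Secondary Structure, CpG
    Islands, DNA Triplex Sites and Somatic-Event Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An in-silico functional-prediction pipeline for candidate
    microRNAs and their target-gene promoters in colorectal cancer.
    Predicts minimum-free-energy and suboptimal RNA secondary structures
    of mature microRNAs with a nearest-neighbour thermodynamic model,
    scans 600-bp promoter regions for CpG islands with the sliding-window
    observed/expected CpG statistic, searches microRNA-duplex-DNA
    triplex-forming sites under Hoogsteen and reverse-Hoogsteen pairing
    rules with percentile grading against dinucleotide-shuffled
    backgrounds, and assembles stage-specific somatic-event and
    interaction networks from tabular exports. Seeded synthetic-data
    generators plant recoverable structures (hairpins, CpG islands,
    polypurine triplex tracts) so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    rtracklayer,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
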