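Package: utrminer
Title: Promoter Mining, Oligo Library Design and Growth-Phase Expression
    Profiling for Bacterial 5' UTRs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines candidate promoter/5' UTR sequences from an annotated
    bacterial genome, filters them by length, orientation, transcriptional
    evidence and type-IIS restriction sites, designs a capped pool of
    synthesis-ready Golden Gate oligonucleotides, and classifies promoter
    activity across growth phases from dual-fluorophore plate-reader time
    series (media-background correction, GFP biomass normalisation,
    Savitzky-Golay growth-phase detection and differential-activity
    thresholds). Includes seeded synthetic-data generators for annotated
    genomes, read-count tables and reporter growth curves so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
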