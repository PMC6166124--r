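Package: editcascade
Title: Detection and Quantification of A-to-G RNA Editing from RNA-Seq Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of adenosine-to-inosine (read as A-to-G) RNA editing
    sites from RNA-Seq alignments via a staged filter cascade with per-tissue
    cutoff profiles, per-site editing-level quantification, and differential
    editing comparison between cohorts (e.g. healthy versus cardiovascular
    disease). Includes a synthetic-data generator that plants editing sites,
    sequencing-error mismatches and confounders into simulated references,
    reads and base-count tables, so that every stage of the cascade can be
    verified against known ground truth. Also provides small closed-form
    vascular phenotype metrics (circumferential cyclic strain, impedance-based
    contraction percentage).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
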