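Package: rfaligner
Title: Random-Field Alignment of Shallow Read Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Jointly aligns the short reads of a shallow-sequenced read-cloud
    well by modelling the hidden long DNA molecules that generated them as a
    Markov random field. Candidate long molecules are seeded from clustered
    single-hit alignments, an abbreviated reference is cut from the genome, and
    multi-candidate realignments form each read's assignment domain. MAP
    inference over the field yields confident unique placements inside
    segmental duplications, together with calibrated read-level mapping
    qualities, cloud-level quality scores and molecule existence posteriors.
    Includes a well-based read-cloud simulator with truth tracking, a prior
    learner for protocol properties (fragment size, read density, end-marker
    states), a built-in exact mini multi-mapper for desk-scale references, and
    a Baseline/Naive/RFA/Oracle evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
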