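Package: pairnick
Title: Paired Cas9 Nickase Geometry, Sequential-Nicking Viability, and
    Amplicon Junction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing paired SpCas9 nickase
    (D10A/H840A) experiments that convert two single-strand nicks into a
    double-strand break. Locates protospacer/NGG sites on both strands of a
    reference amplicon, computes the cut-site geometry of any site pair
    (inter-nick distance, target overlap, overhang polarity and length,
    including overlapping-target configurations), and classifies whether the
    second nick of an overlapping pair can still be induced under a
    sequential-nicking model with or without the TREX2 3'-5' exonuclease
    (free or fused to the nickase). Also provides an amplicon indel caller
    (end-anchored global alignment with VCF-style left normalisation of
    indels), nick-anchored deletion-spectrum summaries (full-overhang-removal
    percentage, median deletion length, precise-deletion fraction), and a
    seeded synthetic read simulator that emulates empty-vector-like and
    TREX2-like editing outcomes for end-to-end testing.
License: MIT
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
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
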