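Package: cooccupy
Title: Genome-Wide Co-Occupancy Analysis of Transcription Factor ChIP-Seq Summits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the chromatin co-occupancy of a
    sequence-specific transcription factor (GFI1-like) with accessory
    corepressor components (HMG20B- and LSD1-like) from ChIP-seq peak
    calls and binned signal tracks: peak filtering, strength ranking and
    decile cohorts, summit-based co-localization and inter-summit
    distance statistics, consensus-motif positional-probability curves
    around summits with apex and width metrics, knockdown fold-change
    and anchored factor-ratio analyses by strength cohort, nearest-gene
    mapping and a preranked gene-set enrichment engine. Includes a
    synthetic-data generator that plants motif-anchored binding triples
    with known offsets, strengths and knockdown effects for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
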