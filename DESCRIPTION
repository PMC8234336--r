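Package: abcsurvey
Title: Genome-Wide ABC-Transporter Family Survey Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for genome-wide surveys of the
    ATP-binding cassette (ABC) transporter gene family from annotated
    genomes. Identifies family members by conserved-motif and domain
    architecture scanning (Walker A/B, ABC signature, transmembrane helix
    clusters), assigns subfamilies against a labelled reference panel with
    neighbor-joining support, characterizes gene structure and chromosomal
    distribution, classifies duplication types (tandem, proximal,
    dispersed, WGD/segmental) from collinear block chaining, estimates
    Ka/Ks by the Nei-Gojobori method with Jukes-Cantor correction and
    divergence times from a synonymous molecular clock, classifies
    tissue-expression patterns from TPM matrices, and analyzes qPCR stress
    time courses with the 2^-ddCt model and compact-letter significance
    groups. A synthetic-data generator with known ground truth makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    ape,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
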