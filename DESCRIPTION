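Package: termread
Title: Transcription Termination Read-Through Analysis from Strand-Specific Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Calls 3'-extended transcripts (ETs) downstream of small nuclear and
    nucleolar RNA genes from strand-specific per-base coverage using
    orientation-aware stopping rules, quantifies the extension by an
    area-under-coverage ratio, performs self-contained count-based differential
    expression (TMM normalization, common-dispersion negative-binomial exact
    test, Benjamini-Hochberg FDR), constructs antisense annotations, classifies
    transcription-interference candidates at downstream convergent genes, and
    quantifies 3' shifts of RNA polymerase II occupancy between paired ChIP-exo
    tracks. A synthetic-data generator with known ground truth emulates the
    statistical structure every stage assumes, so the whole pipeline is testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), edgeR, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
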