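Package: alnvista
Title: Annotate and Visualize Variants on Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable toolkit for co-locating genetic variants,
    post-translational modifications and interval annotations onto the
    columns of pairwise or multiple sequence alignments. Reads FASTA
    alignments and JSON annotation documents, maps ungapped residue
    positions to alignment columns and back, computes a consensus row,
    detects cross-species co-located (orthologous) variants, and exports
    self-contained interactive HTML as well as static SVG/PNG figures
    under thirteen classic colour schemes. Ships a command-line interface
    and a deterministic synthetic-fixture generator with planted ground
    truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    xml2,
    yaml,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse,
    Biostrings
Config/testthat/edition: 3
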