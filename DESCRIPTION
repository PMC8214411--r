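Package: homoeologr
Title: Homoeolog Inference and Classification for Allopolyploid Subgenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers homoeologous gene pairs between the two subgenomes of an
    allopolyploid genome by bidirectional best hit (BBH) and by a relaxed
    many-to-many criterion with alignment-coverage filtering and an optional
    outgroup "witness of nonhomoeology" check; scores local synteny in gene-order
    windows; classifies pairs into four BBH-by-synteny categories; and compares
    the categories by duplication extent, estimated evolutionary distance,
    protein length, expression breadth and level, and GO term enrichment.
    Includes a truth-labelled synthetic allopolyploid generator (sequences,
    gene order, outgroup, expression, GO annotations) so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
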