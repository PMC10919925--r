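Package: cytonuclear
Title: Cytonuclear Evolution of Organelle-Targeted Genes in Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the evolution of organelle-targeted nuclear
    genes after allopolyploidy, built around the Brassica-style "triangle of U"
    crossing scheme (three diploids, reciprocal allotetraploids sharing one
    parental genome). Types variant sites in allopolyploid organelle genes by
    parental origin and infers the cytoplasmic donor; measures maternal versus
    paternal gene-retention bias across organelle-interaction functional
    categories; detects homoeologous gene conversion both by an
    ortholog-versus-homoeolog similarity quartet rule and by scanning
    genome-diagnostic SNP sites; estimates dN/dS by Nei-Gojobori-style counting
    with Jukes-Cantor correction; and classifies homoeolog expression bias at a
    log2 fold-change threshold. Ships a seeded synthetic-data generator that
    emits a fully labelled triangle-of-U dataset with machine-readable truth
    tables so every detector can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
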