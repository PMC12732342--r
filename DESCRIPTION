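Package: mitochar
Title: Characterization of Small Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the descriptive analysis of annotated animal
    mitochondrial genomes, with defaults tuned to insect (aphid) mitogenomes:
    GenBank/feature-table input, strand-aware coding-sequence extraction under
    the invertebrate mitochondrial genetic code, nucleotide composition and
    AT/GC skew per region and codon position, codon-usage-bias indices (RSCU,
    effective number of codons with Wright's expected curve, PR2 and
    neutrality-plot coordinates), sliding-window nucleotide diversity and
    Nei-Gojobori (1986) Ka/Ks over aligned gene panels, exact repeat search in
    four orientations with tandem-array and control-region decomposition, and
    a seeded synthetic-mitogenome generator so every stage is testable without
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
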