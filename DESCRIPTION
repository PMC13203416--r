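Package: mitochar
Title: Comparative Characterization of Annotated Vertebrate Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative characterization of annotated circular
    vertebrate mitochondrial genomes: base composition and AT/GC-skew
    statistics, codon usage and relative synonymous codon usage (RSCU) under
    the vertebrate mitochondrial genetic code, circular gene-order metrics
    (overlaps, intergenic spacers, start/stop codon audits including
    incomplete stops), mismatch-tolerant dispersed-repeat detection in four
    classes (forward, palindrome, complement, reverse) with a brute-force
    oracle, pairwise Ka/Ks selection-pressure estimation by the
    Nei-Gojobori (1986) site/pathway method with Jukes-Cantor correction,
    maximal-exact-match collinearity anchoring, concatenated protein-guided
    codon alignments for phylogenetics, and a seeded synthetic-mitogenome
    generator that plants ground truth for every downstream statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
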