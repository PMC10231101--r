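Package: mitocomp
Title: Comparative Mitogenomics of Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated animal mitochondrial
    genomes: base-composition and strand-asymmetry (AT/GC skew) statistics,
    gene-junction accounting on the circular genome, start/stop codon
    classification and relative synonymous codon usage (RSCU) under the
    invertebrate mitochondrial genetic code, signed circular gene-order
    extraction and comparison against the ancestral insect arrangement,
    minimal tandem duplication/random loss (TDRL) scenario search with
    recombination (inversion and translocation) classification, and
    control-region tandem-repeat profiling. Includes a seeded synthetic
    mitogenome generator that plants rearrangement events, junction motifs,
    and repeat arrays with a ground-truth manifest, plus GenBank flat-file
    reading and writing for single circular records.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
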