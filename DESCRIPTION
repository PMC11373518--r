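Package: rdnarray
Title: Ribosomal DNA Repeat-Unit Sizing and Annotation from Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures ribosomal RNA gene (rDNA) repeat-unit sizes directly
    from long sequencing reads that span two or more units, summarizes the
    resulting length distributions with kernel-density peak estimates, and
    classifies units into the "normal" (8-20 kb) and "large" (>30 kb) size
    classes observed across amniotes. Also builds majority-rule consensus
    units rotated to the 18S rRNA gene, annotates coding regions and spacers
    (ITS1, 5.8S, ITS2, 28S, IGS), detects tandem sub-repeat arrays inside a
    unit and quantifies how much unit-length variance sub-repeat copy number
    explains, and matches putatively orthologous transposable elements
    between two intergenic spacers by family, order and orientation. A
    synthetic-data module simulates tandem rDNA arrays and noisy long reads
    with complete ground truth so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    graphics,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
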